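#' 2-D image field
#'
#' The carrier type for all solvers in the package: a dense matrix of
#' intensities together with the grid step `spacing` (the same step is used
#' in both directions).  Row index `i` plays the role of the x coordinate in
#' the finite-difference stencils, column index `j` the y coordinate.
#'
#' Multiplicative-noise models divide by the image and take its logarithm,
#' so every solver input must be strictly positive; `image_field()` enforces
#' finiteness and minimum size (3x3, one interior ring for the stencils) and
#' the solvers additionally enforce positivity.
#'
#' @param values numeric matrix of intensities (at least 3x3, all finite).
#' @param spacing grid step `dx = dy` in pixel units; default 10, the
#'   conventional choice for this family of schemes.
#' @param require_positive if `TRUE`, reject non-positive intensities.
#'
#' @return an object of class `image_field` (a list with elements `values`
#'   and `spacing`).
#' @export
image_field <- function(values, spacing = 10, require_positive = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) < 3L || ncol(values) < 3L) {
    stop("image must be at least 3x3 (stencils need one interior ring)",
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("all intensities must be finite", call. = FALSE)
  }
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0) {
    stop("`spacing` must be a single positive number", call. = FALSE)
  }
  if (require_positive && any(values <= 0)) {
    stop("intensities must be strictly positive", call. = FALSE)
  }
  structure(list(values = values, spacing = as.numeric(spacing)),
            class = "image_field")
}

#' @export
print.image_field <- function(x, ...) {
  v <- x$values
  cat(sprintf("<image_field %d x %d, spacing %g, range [%g, %g]>\n",
              nrow(v), ncol(v), x$spacing, min(v), max(v)))
  invisible(x)
}

#' @export
dim.image_field <- function(x) dim(x$values)

#' @export
as.matrix.image_field <- function(x, ...) x$values

#' Coerce to an image field
#' @param x a matrix or `image_field`.
#' @inheritParams image_field
#' @return an `image_field`.
#' @export
as_image_field <- function(x, spacing = 10) {
  if (inherits(x, "image_field")) return(x)
  image_field(as.matrix(x), spacing = spacing)
}

stopifnot_positive_field <- function(g, what = "image") {
  if (any(g$values <= 0)) {
    stop(sprintf("%s must be strictly positive for multiplicative-noise models",
                 what), call. = FALSE)
  }
  invisible(g)
}

same_shape <- function(a, b) identical(dim(a$values), dim(b$values))

#' Read a grayscale image as a strictly positive field
#'
#' Reads PNG, TIFF or plain-text PGM (P2) rasters.  Color input is collapsed
#' to luminance with ITU-R 601 weights.  Pixel values are mapped linearly to
#' `[floor, floor + scale]` so the result is strictly positive, as the
#' multiplicative-noise models require (they divide by the image and take
#' its log).  `scale = 255` reproduces the classical 8-bit range; unit-scale
#' data (`scale = 1`) matches the magnitudes the solver presets are tuned
#' for.
#'
#' @param path file path; format inferred from the extension
#'   (`.png`, `.tif`/`.tiff`, `.pgm`).
#' @param floor positive intensity offset added after rescaling.
#' @param scale width of the target intensity range.
#' @param spacing grid step attached to the field.
#' @return an `image_field` with values in `[floor, floor + scale]`.
#' @export
load_image <- function(path, floor = 1, scale = 255, spacing = 10) {
  if (!is.numeric(floor) || floor <= 0) {
    stop("`floor` must be positive: the multiplicative model is undefined at 0",
         call. = FALSE)
  }
  if (!file.exists(path)) stop("cannot read image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    pgm  = read_pgm(path),
    stop("unsupported raster format: .", ext, call. = FALSE)
  )
  if (length(dim(raw)) == 3L) {
    # ITU-R 601 luminance for color input
    w <- c(0.299, 0.587, 0.114)
    nc <- dim(raw)[3]
    if (nc < 3L) raw <- raw[, , 1L]
    else raw <- w[1] * raw[, , 1] + w[2] * raw[, , 2] + w[3] * raw[, , 3]
  }
  raw <- as.matrix(raw)
  if (nrow(raw) < 3L || ncol(raw) < 3L) {
    stop("image must have at least 3 rows and 3 columns", call. = FALSE)
  }
  rng <- range(raw)
  z <- if (rng[2] > rng[1]) (raw - rng[1]) / (rng[2] - rng[1]) else raw * 0
  image_field(floor + scale * z, spacing = spacing)
}

#' Write an image field as a grayscale raster
#'
#' Values are rescaled linearly onto the container's range (constant fields
#' map to mid-gray).  PNG and TIFF are written through the corresponding
#' packages; `.pgm` writes the plain-text P2 format, convenient for
#' text-only fixtures.
#'
#' @param field an `image_field`.
#' @param path output path; format inferred from the extension.
#' @param bits bit depth for PGM output (8 or 16); PNG/TIFF are written as
#'   their native normalized format.
#' @return `path`, invisibly.
#' @export
save_image <- function(field, path, bits = 8) {
  field <- as_image_field(field)
  v <- field$values
  rng <- range(v)
  z <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0 + 0.5
  ext <- tolower(tools::file_ext(path))
  ok <- tryCatch({
    switch(ext,
      png  = png::writePNG(z, target = path),
      tif  = ,
      tiff = tiff::writeTIFF(z, where = path),
      pgm  = write_pgm(z, path, bits = bits),
      stop("unsupported raster format: .", ext, call. = FALSE)
    )
    TRUE
  }, error = function(e) {
    stop("cannot write image to ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(path)
}

# Plain-text PGM (P2). Tiny hand parser: no installed R package reads PGM,
# and the text variant keeps fixtures human-readable.
read_pgm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\s*#", txt)]
  toks <- scan(text = paste(txt, collapse = " "), what = character(),
               quiet = TRUE)
  if (toks[1] != "P2") stop("only plain-text (P2) PGM is supported",
                            call. = FALSE)
  nums <- as.numeric(toks[-1])
  nc <- nums[1]; nr <- nums[2]; maxval <- nums[3]
  px <- nums[-(1:3)]
  if (length(px) != nr * nc) stop("corrupt PGM: wrong pixel count",
                                  call. = FALSE)
  # PGM is row-major, top row first
  matrix(px / maxval, nrow = nr, ncol = nc, byrow = TRUE)
}

write_pgm <- function(z, path, bits = 8) {
  maxval <- if (bits >= 16) 65535L else 255L
  q <- round(z * maxval)
  lines <- c("P2", sprintf("%d %d", ncol(q), nrow(q)), as.character(maxval),
             apply(q, 1L, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Display an image field with ggplot2
#'
#' @param object an `image_field`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.image_field <- function(object, ...) {
  v <- object$values
  df <- data.frame(
    row = rep(seq_len(nrow(v)), times = ncol(v)),
    col = rep(seq_len(ncol(v)), each = nrow(v)),
    intensity = as.vector(v)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = col, y = row, fill = intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
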