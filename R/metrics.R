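#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 * log10( M*N * max(g_hat)^2 / sum((g_hat - g)^2) )` in dB,
#' where `g_hat` is the reference image and `g` the restored one.  The peak
#' is taken from the reference, so the measure is not symmetric in its
#' arguments; identical images report `Inf`.
#'
#' @param g_hat reference `image_field` (clean image).
#' @param g restored (or noisy) `image_field`, same shape.
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(g_hat, g) {
  g_hat <- as_image_field(g_hat); g <- as_image_field(g)
  if (!same_shape(g_hat, g)) {
    stop("images must have the same shape", call. = FALSE)
  }
  ss <- sum((g_hat$values - g$values)^2)
  if (ss == 0) return(Inf)
  mx <- max(g_hat$values)
  10 * log10(length(g_hat$values) * mx^2 / ss)
}

#' Extract one row of an image as a 1-D profile
#'
#' Line profiles across a fixed row are the standard way to inspect how a
#' restoration treats edges and homogeneous stretches.
#'
#' @param field an `image_field`.
#' @param row_index row to extract (1-based).
#' @return numeric vector of length `ncol(field)`.
#' @export
line_profile <- function(field, row_index) {
  field <- as_image_field(field)
  M <- nrow(field$values)
  if (row_index < 1 || row_index > M) {
    stop(sprintf("row_index must be in [1, %d]", M), call. = FALSE)
  }
  field$values[row_index, ]
}

#' Overlay line profiles from several images
#'
#' @param fields named list of `image_field`s sharing a shape (for example
#'   `list(clean = g, noisy = f, restored = out)`).
#' @param row_index row to extract.
#' @return a ggplot object with one line per image.
#' @export
plot_line_profiles <- function(fields, row_index) {
  stopifnot(length(fields) >= 1, !is.null(names(fields)))
  long <- do.call(rbind, lapply(names(fields), function(nm) {
    p <- line_profile(fields[[nm]], row_index)
    data.frame(position = seq_along(p), intensity = p, series = nm)
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = position, y = intensity,
                                     colour = series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "column", y = "intensity", colour = NULL,
                  title = sprintf("line profile, row %d", row_index)) +
    ggplot2::theme_minimal()
}
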