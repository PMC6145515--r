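#' Deterministic synthetic phantoms
#'
#' Stand-ins for the classical grayscale test scenes used in the speckle
#' denoising literature: piecewise-constant shape images (edges and flat
#' regions), linear ramps (the surface on which TV regularization
#' staircases), and smooth periodic textures.  All generators are
#' deterministic: identical parameters give identical fields.
#'
#' Intensities default to the unit scale (O(0.1)-O(1)) on which the
#' elastica/Weber parameter ranges of [elastica_params()] are meaningful;
#' see the methods vignette.
#'
#' @name phantoms
NULL

#' Piecewise-constant shapes phantom
#'
#' @param M,N grid size (rows, columns).
#' @param shapes list of shape descriptors, each a list with elements
#'   `kind` (`"disk"` or `"rectangle"`), `center` (length-2, row/col),
#'   `size` (radius for disks; length-2 half-sides for rectangles) and
#'   `intensity` (> 0).  Later shapes overwrite earlier ones.
#' @param background background intensity (> 0).
#' @param spacing grid step attached to the field.
#' @return an `image_field`.
#' @rdname phantoms
#' @export
make_shapes_phantom <- function(M, N, shapes = list(), background = 0.4,
                                spacing = 10) {
  if (background <= 0) stop("background intensity must be positive",
                            call. = FALSE)
  v <- matrix(background, M, N)
  ri <- matrix(rep(seq_len(M), N), M, N)
  ci <- matrix(rep(seq_len(N), each = M), M, N)
  for (s in shapes) {
    if (is.null(s$intensity) || s$intensity <= 0) {
      stop("shape intensity must be positive", call. = FALSE)
    }
    kind <- match.arg(s$kind, c("disk", "rectangle"))
    if (kind == "disk") {
      mask <- (ri - s$center[1])^2 + (ci - s$center[2])^2 <= s$size[1]^2
    } else {
      half <- if (length(s$size) == 1L) rep(s$size, 2L) else s$size
      mask <- abs(ri - s$center[1]) <= half[1] & abs(ci - s$center[2]) <= half[2]
    }
    v[mask] <- s$intensity
  }
  image_field(v, spacing = spacing)
}

#' Linear ramp phantom
#'
#' @param low,high intensity at the two ends, `0 < low < high`.
#' @param axis `"columns"` (intensity varies with column index) or `"rows"`.
#' @rdname phantoms
#' @export
make_ramp_phantom <- function(M, N, low = 0.1, high = 1, axis = c("columns", "rows"),
                              spacing = 10) {
  axis <- match.arg(axis)
  if (!(low > 0 && high > low)) {
    stop("need 0 < low < high for a ramp", call. = FALSE)
  }
  if (axis == "columns") {
    v <- matrix(rep(seq(low, high, length.out = N), each = M), M, N)
  } else {
    v <- matrix(rep(seq(low, high, length.out = M), N), M, N)
  }
  image_field(v, spacing = spacing)
}

#' Periodic texture phantom
#'
#' `offset + amplitude * sin(2*pi*i/period) * sin(2*pi*j/period)`; requires
#' `offset - amplitude > 0` so the field stays strictly positive.
#'
#' @param period period in pixels.
#' @param amplitude oscillation amplitude (>= 0).
#' @param offset mean intensity.
#' @rdname phantoms
#' @export
make_texture_phantom <- function(M, N, period = 16, amplitude = 0.3,
                                 offset = 0.5, spacing = 10) {
  if (offset - amplitude <= 0) {
    stop("need offset - amplitude > 0: texture must stay strictly positive",
         call. = FALSE)
  }
  sx <- sin(2 * pi * seq_len(M) / period)
  sy <- sin(2 * pi * seq_len(N) / period)
  v <- offset + amplitude * outer(sx, sy)
  image_field(v, spacing = spacing)
}

#' Standard study phantom
#'
#' The fixed 2-shape scene used by the experiment harnesses and the
#' package's own acceptance runs: a bright disk and a dark rectangle on a
#' mid-gray background.  Scaled versions keep the geometry proportional.
#'
#' @param side grid side length (square field).
#' @param spacing grid step.
#' @return an `image_field`.
#' @export
study_phantom <- function(side = 128, spacing = 10) {
  make_shapes_phantom(
    side, side,
    shapes = list(
      list(kind = "disk", center = round(c(0.36, 0.38) * side),
           size = round(0.18 * side), intensity = 0.9),
      list(kind = "rectangle", center = round(c(0.68, 0.66) * side),
           size = round(c(0.12, 0.16) * side), intensity = 0.15)
    ),
    background = 0.45, spacing = spacing
  )
}
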