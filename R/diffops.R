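#' Min-mod slope limiter
#'
#' `minmod(m, n) = ((sgn m + sgn n)/2) * min(|m|, |n|)`: the smaller-in-
#' magnitude argument when both agree in sign, zero otherwise.  Used to
#' suppress oscillations when averaging one-sided stencils onto half-pixel
#' (face) locations.  Vectorized over its arguments.
#'
#' @param m,n finite numeric vectors (recycled to common length).
#' @return numeric vector.
#' @export
minmod <- function(m, n) {
  if (!all(is.finite(m), is.finite(n))) {
    stop("minmod arguments must be finite", call. = FALSE)
  }
  0.5 * (sign(m) + sign(n)) * pmin(abs(m), abs(n))
}

#' Mirror a field with a one-pixel Neumann ghost ring
#'
#' Ghost values replicate the nearest interior value (zero normal
#' derivative); corners are mirrored in both directions, which is
#' order-independent.
#'
#' @param field an `image_field` or matrix.
#' @return an `image_field` two pixels larger in each dimension.
#' @export
neumann_pad <- function(field) {
  field <- as_image_field(field)
  image_field(cpp_neumann_pad(field$values), spacing = field$spacing)
}

#' Regularized image gradient
#'
#' Central differences over `2*dx` with mirrored ghosts.  The magnitude is
#' the epsilon-regularized `sqrt(gx^2 + gy^2 + epsilon)`; with
#' `literal = TRUE` (the default) the returned `magnitude` is the verbatim
#' half-sum-of-squares form `0.5 * sqrt(diffs^2 + 4*dx^2*epsilon)`, which
#' equals `dx` times the consistent magnitude and carries intensity units.
#'
#' @param field an `image_field`.
#' @param epsilon positive gradient regularizer; keeps the magnitude (and
#'   every division by it) bounded away from zero.
#' @param literal which reading of the magnitude to report (see Details in
#'   the methods vignette); derivative components are unaffected.
#' @return a `gradient_field`: list with `gx`, `gy`, `magnitude`,
#'   `epsilon`, `spacing`, `literal`.
#' @export
central_gradient <- function(field, epsilon, literal = TRUE) {
  field <- as_image_field(field)
  if (!is.numeric(epsilon) || epsilon <= 0) {
    stop("`epsilon` must be positive", call. = FALSE)
  }
  gr <- cpp_gradient(field$values, field$spacing, epsilon)
  mag <- if (literal) field$spacing * gr$mag else gr$mag
  structure(list(gx = gr$gx, gy = gr$gy, magnitude = mag,
                 epsilon = epsilon, spacing = field$spacing,
                 literal = literal),
            class = "gradient_field")
}

#' Level-set curvature
#'
#' The curvature of the iso-intensity contours,
#' `kappa = div(grad g / |grad g|)`, discretized by central differences of
#' the epsilon-regularized unit gradient with mirrored ghosts.
#'
#' @inheritParams central_gradient
#' @return a `curvature_field`: list with `kappa` (matrix, units 1/pixel
#'   length), `epsilon`, `spacing`.
#' @export
curvature <- function(field, epsilon) {
  field <- as_image_field(field)
  if (!is.numeric(epsilon) || epsilon <= 0) {
    stop("`epsilon` must be positive", call. = FALSE)
  }
  structure(list(kappa = cpp_curvature(field$values, field$spacing, epsilon),
                 epsilon = epsilon, spacing = field$spacing),
            class = "curvature_field")
}

#' Staggered half-pixel stencil bundle
#'
#' All face-centred quantities the elastica flux needs, on x faces
#' (between vertically adjacent pixels, `(M+1) x N`) and y faces
#' (`M x (N+1)`): the min-mod averaged curvature, the in-axis two-point
#' derivative, the cross-axis min-mod of adjacent central differences (of
#' both the image and the product `kappa * |grad g|`), and the regularized
#' face gradient magnitude.
#'
#' @inheritParams central_gradient
#' @return a named list of staggered matrices: `kappa_x`, `dxg_x`, `dyg_x`,
#'   `dxP_x`, `dyP_x`, `mag_x` on x faces and the `_y` counterparts on y
#'   faces, where `P = kappa * |grad g|`.
#' @export
half_pixel_bundle <- function(field, epsilon) {
  field <- as_image_field(field)
  if (!is.numeric(epsilon) || epsilon <= 0) {
    stop("`epsilon` must be positive", call. = FALSE)
  }
  cpp_half_bundle(field$values, field$spacing, epsilon)
}
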