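#' Multiplicative noise specification
#'
#' Describes the two multiplicative (speckle) noise families used by the
#' experiment harnesses: `uniform_speckle` multiplies the clean image by
#' i.i.d. Uniform draws with mean 1 and variance `sigma2` (support
#' `[1 - sqrt(3*sigma2), 1 + sqrt(3*sigma2)]`, the unique uniform with those
#' moments, which stays positive only for `sigma2 < 1/3`); `gamma`
#' multiplies by i.i.d. Gamma(shape `L`, mean 1) draws, the classical
#' intensity-format L-look speckle model with variance `1/L`.
#'
#' @param family `"uniform_speckle"` or `"gamma"`.
#' @param sigma2 variance of the uniform multiplier (0 <= sigma2 < 1/3).
#' @param L number of looks for the gamma family (L >= 1).
#' @param seed integer RNG seed making realizations reproducible.
#' @return a `noise_spec` object.
#' @export
noise_spec <- function(family = c("uniform_speckle", "gamma"), sigma2 = 0.1,
                       L = 3, seed = 1L) {
  family <- match.arg(family)
  if (family == "uniform_speckle") {
    if (!(sigma2 >= 0 && sigma2 < 1 / 3)) {
      stop("uniform speckle requires 0 <= sigma2 < 1/3 ",
           "(support must stay positive)", call. = FALSE)
    }
  } else {
    if (L < 1) stop("gamma noise requires L >= 1", call. = FALSE)
  }
  structure(list(family = family, sigma2 = sigma2, L = L,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  if (x$family == "uniform_speckle") {
    cat(sprintf("<noise_spec uniform speckle, sigma2 = %g, seed = %d>\n",
                x$sigma2, x$seed))
  } else {
    cat(sprintf("<noise_spec gamma, L = %g looks, seed = %d>\n", x$L, x$seed))
  }
  invisible(x)
}

#' Corrupt an image with uniform-distribution speckle
#'
#' Returns `f = g * eta` with `eta` i.i.d. Uniform on
#' `[1 - sqrt(3*sigma2), 1 + sqrt(3*sigma2)]` (mean 1, variance `sigma2`).
#'
#' @param g clean `image_field`, strictly positive.
#' @param sigma2 multiplier variance, `0 <= sigma2 < 1/3`.
#' @param seed integer RNG seed.
#' @return noisy `image_field`.
#' @export
speckle_uniform <- function(g, sigma2 = 0.1, seed = 1L) {
  g <- as_image_field(g)
  stopifnot_positive_field(g)
  if (!(sigma2 >= 0 && sigma2 < 1 / 3)) {
    stop("need 0 <= sigma2 < 1/3: at sigma2 = 1/3 the support touches 0",
         call. = FALSE)
  }
  half <- sqrt(3 * sigma2)
  eta <- withr::with_seed(seed,
    matrix(runif(length(g$values), 1 - half, 1 + half),
           nrow(g$values), ncol(g$values)))
  image_field(g$values * eta, spacing = g$spacing)
}

#' Corrupt an image with L-look gamma speckle
#'
#' Returns `f = g * eta` with `eta` i.i.d. Gamma(shape `L`, scale `1/L`),
#' i.e. mean 1 and variance `1/L`.
#'
#' @inheritParams speckle_uniform
#' @param L number of looks, `L >= 1`.
#' @return noisy `image_field`.
#' @export
speckle_gamma <- function(g, L = 3, seed = 1L) {
  g <- as_image_field(g)
  stopifnot_positive_field(g)
  if (L < 1) stop("need L >= 1 looks", call. = FALSE)
  eta <- withr::with_seed(seed,
    matrix(rgamma(length(g$values), shape = L, scale = 1 / L),
           nrow(g$values), ncol(g$values)))
  image_field(g$values * eta, spacing = g$spacing)
}

#' Apply a noise specification to a clean image
#'
#' @param g clean `image_field`.
#' @param spec a [noise_spec()].
#' @param seed optional seed overriding the one stored in `spec`.
#' @return noisy `image_field`.
#' @export
apply_noise <- function(g, spec, seed = NULL) {
  seed <- if (is.null(seed)) spec$seed else as.integer(seed)
  switch(spec$family,
    uniform_speckle = speckle_uniform(g, spec$sigma2, seed),
    gamma = speckle_gamma(g, spec$L, seed)
  )
}
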