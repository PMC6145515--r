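#' Parameters for the Weberized TV (AOS) baseline
#'
#' The second-order Weberized TV flow
#' `dg/dt = div(grad g / (|grad g|^2 + epsilon)) - lambda(g) (g - f)`,
#' integrated semi-implicitly by additive operator splitting: per step the
#' diffusivity is frozen, one tridiagonal system is solved along each axis,
#' and the two axis solutions are averaged.  The scheme is unconditionally
#' stable in the diffusion part, so `tau` can be far larger than an
#' explicit step.
#'
#' The squared-magnitude denominator `|grad g|^2 + epsilon` is the model's
#' stated form; `conventional_tv = TRUE` switches to the usual
#' `sqrt(|grad g|^2 + epsilon)`.
#'
#' @param beta1,beta2 Weber fidelity weights.
#' @param epsilon positive regularizer in the diffusivity denominator.
#' @param tau AOS time step (> 0).
#' @param spacing grid step.
#' @param max_iter,rel_tol,positivity_floor as in [elastica_params()].
#' @param conventional_tv use the conventional TV diffusivity instead of
#'   the squared-magnitude form.
#' @return an `m1_params` list.
#' @export
m1_params <- function(beta1 = 0.0061, beta2 = 0.0411, epsilon = 1e-6,
                      tau = 2e-4, spacing = 10, max_iter = 150,
                      rel_tol = 1e-6, positivity_floor = 1e-3,
                      conventional_tv = FALSE) {
  if (tau <= 0 || epsilon <= 0) {
    stop("tau and epsilon must be positive", call. = FALSE)
  }
  structure(list(beta1 = beta1, beta2 = beta2, epsilon = epsilon, tau = tau,
                 spacing = spacing, max_iter = as.integer(max_iter),
                 rel_tol = rel_tol, positivity_floor = positivity_floor,
                 conventional_tv = isTRUE(conventional_tv)),
            class = "m1_params")
}

# Thomas algorithm, vectorized across the columns of the right-hand side:
# each column of (a, b, c, d) is an independent tridiagonal system along
# the rows (a sub-, b main, c super-diagonal).
thomas_solve_cols <- function(a, b, c, d) {
  M <- nrow(b)
  cp <- b * 0
  dp <- b * 0
  cp[1, ] <- c[1, ] / b[1, ]
  dp[1, ] <- d[1, ] / b[1, ]
  for (i in 2:M) {
    denom <- b[i, ] - a[i, ] * cp[i - 1, ]
    cp[i, ] <- c[i, ] / denom
    dp[i, ] <- (d[i, ] - a[i, ] * dp[i - 1, ]) / denom
  }
  x <- dp
  for (i in (M - 1):1) x[i, ] <- dp[i, ] - cp[i, ] * x[i + 1, ]
  x
}

# one semi-implicit solve along the row direction with frozen face
# diffusivities Df ((M+1) x N, zero on boundary faces): (I - 2 tau A) x = d
aos_axis_solve <- function(Df, d, tau, h) {
  M <- nrow(d)
  w <- 2 * tau / h^2
  lower <- Df[1:M, , drop = FALSE]        # face below pixel i
  upper <- Df[2:(M + 1), , drop = FALSE]  # face above pixel i
  b <- 1 + w * (lower + upper)
  a <- -w * lower
  c <- -w * upper
  thomas_solve_cols(a, b, c, d)
}

# harmonic face average of a positive pixel diffusivity, along rows;
# boundary faces get zero (no normal flux)
face_harmonic <- function(D) {
  M <- nrow(D)
  inner <- 2 * D[1:(M - 1), , drop = FALSE] * D[2:M, , drop = FALSE] /
    (D[1:(M - 1), , drop = FALSE] + D[2:M, , drop = FALSE])
  rbind(0, inner, 0)
}

m1_energy <- function(gv, fv, p) {
  gr <- cpp_gradient(gv, p$spacing, p$epsilon)
  sum((p$beta1 + p$beta2 / gv) * gr$mag + log(gv) + fv / gv) * p$spacing^2
}

#' Denoise with the Weberized TV (AOS) baseline
#'
#' @param f observed noisy image (`image_field`, strictly positive).
#' @param params an [m1_params()] list.
#' @param reference optional clean image for per-iteration PSNR.
#' @param record_energy record the discrete TV energy per iteration.
#' @return a list with `image` and `trace` (a [solver_trace()]).
#' @export
m1_denoise <- function(f, params = m1_params(), reference = NULL,
                       record_energy = FALSE) {
  f <- as_image_field(f)
  stopifnot_positive_field(f, "observed image")
  p <- params
  fv <- f$values
  gv <- fv
  h <- p$spacing
  ref <- if (is.null(reference)) NULL else as_image_field(reference)$values
  energies <- numeric()
  rels <- numeric()
  psnrs <- numeric()
  clamps <- 0L
  e0 <- if (record_energy) m1_energy(gv, fv, p) else NA_real_
  iters <- 0L
  for (n in seq_len(p$max_iter)) {
    gr <- cpp_gradient(gv, h, p$epsilon)
    mag2 <- gr$gx^2 + gr$gy^2 + p$epsilon
    D <- if (p$conventional_tv) 1 / sqrt(mag2) else 1 / mag2
    lam <- p$beta1 + p$beta2 / gv
    rhs <- gv - p$tau * lam * (gv - fv)
    sol_x <- aos_axis_solve(face_harmonic(D), rhs, p$tau, h)
    sol_y <- t(aos_axis_solve(face_harmonic(t(D)), t(rhs), p$tau, h))
    gn <- 0.5 * (sol_x + sol_y)
    if (!all(is.finite(gn))) {
      return(list(image = image_field(gv, spacing = h),
                  trace = solver_trace("m1", energies, rels, psnrs, n - 1L,
                                       clamps, e0, diverged = TRUE)))
    }
    below <- gn < p$positivity_floor
    clamps <- clamps + sum(below)
    gn[below] <- p$positivity_floor
    rel <- sqrt(sum((gn - gv)^2)) / max(sqrt(sum(gv^2)), 1e-300)
    gv <- gn
    iters <- n
    rels[n] <- rel
    if (record_energy) energies[n] <- m1_energy(gv, fv, p)
    if (!is.null(ref)) psnrs[n] <- psnr(as_image_field(ref, h),
                                        image_field(gv, h))
    if (rel < p$rel_tol) break
  }
  list(image = image_field(gv, spacing = h),
       trace = solver_trace("m1", energies, rels, psnrs, iters, clamps, e0))
}
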