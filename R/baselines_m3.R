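# Log-domain operators shared by the M3/M4 baselines.  These schemes are
# formulated on the unit pixel grid: forward differences with the
# backward-difference (negative adjoint) divergence, Neumann borders.

fdx <- function(u) rbind(u[-1, , drop = FALSE] - u[-nrow(u), , drop = FALSE], 0)
fdy <- function(u) cbind(u[, -1, drop = FALSE] - u[, -ncol(u), drop = FALSE], 0)

bdivx <- function(p) {
  M <- nrow(p)
  rbind(p[1, , drop = FALSE],
        p[2:(M - 1), , drop = FALSE] - p[1:(M - 2), , drop = FALSE],
        -p[M - 1, , drop = FALSE])
}
bdivy <- function(p) t(bdivx(t(p)))
bdiv <- function(p1, p2) bdivx(p1) + bdivy(p2)

#' Soft-thresholding (shrinkage) operator
#'
#' `T(x, gamma) = (x/|x|) * max(|x| - gamma, 0)`, elementwise, with 0 at
#' `x = 0`: the proximal map of the absolute value, used by the
#' split-Bregman update.
#'
#' @param x numeric vector or matrix.
#' @param gamma positive threshold.
#' @return same shape as `x`.
#' @export
soft_threshold <- function(x, gamma) {
  if (!is.numeric(gamma) || gamma <= 0) {
    stop("`gamma` must be positive", call. = FALSE)
  }
  sign(x) * pmax(abs(x) - gamma, 0)
}

# isotropic (joint-magnitude) shrinkage of a 2-vector field
soft_threshold_pair <- function(x1, x2, gamma) {
  m <- sqrt(x1^2 + x2^2)
  s <- pmax(m - gamma, 0) / pmax(m, .Machine$double.xmin)
  list(s * x1, s * x2)
}

#' Parameters for the hybrid split model
#'
#' The model works on `xi = log f` and splits the smoothed-gradient field
#' `v` from the TV term: `min |grad v| + (lambda/2)|grad xi - v|^2 +
#' alpha |grad xi| + beta (f0 exp(-xi) + xi)`.  `v` is solved by a
#' Chambolle dual fixed point, `xi` by a proximal-linearized step inside a
#' split-Bregman loop with isotropic shrinkage.
#'
#' `sigma_prox` must satisfy roughly
#' `sigma_prox * (8 mu + beta * max(f0 exp(-xi))) < 2` for the explicit
#' proximal step to be stable; the default is set accordingly.
#'
#' @param lambda coupling weight between `v` and `grad xi`.
#' @param alpha TV weight on `xi`.
#' @param beta fidelity weight.
#' @param mu split-Bregman penalty.
#' @param tau_dual Chambolle fixed-point step (<= 1/8 for convergence).
#' @param sigma_prox proximal step for the `xi` update.
#' @param n_dual dual sweeps per `v` update (duals restart from zero).
#' @param max_iter,rel_tol outer stopping controls.
#' @return an `m3_params` list.
#' @export
m3_params <- function(lambda = 10, alpha = 1, beta = 30, mu = 10,
                      tau_dual = 0.125, sigma_prox = 0.01, n_dual = 10,
                      max_iter = 300, rel_tol = 1e-6) {
  if (any(c(lambda, alpha, beta, mu, tau_dual, sigma_prox) <= 0)) {
    stop("all weights and steps must be positive", call. = FALSE)
  }
  structure(list(lambda = lambda, alpha = alpha, beta = beta, mu = mu,
                 tau_dual = tau_dual, sigma_prox = sigma_prox,
                 n_dual = as.integer(n_dual), max_iter = as.integer(max_iter),
                 rel_tol = rel_tol),
            class = "m3_params")
}

#' Chambolle dual update of the smoothed-gradient field
#'
#' Runs the normalized dual fixed-point iteration from zero initialization
#' on the two dual fields (one per component of `grad xi`), then returns
#' `v = grad xi - (1/lambda) div q`.  Each dual field stays bounded by 1 in
#' magnitude (the update divides by `1 + tau |.|`).
#'
#' @param xi log-image matrix.
#' @param params an [m3_params()] list.
#' @return list with components `v1`, `v2` and the dual magnitudes
#'   `p1_mag`, `p2_mag` (for diagnostics).
#' @export
chambolle_v_update <- function(xi, params = m3_params()) {
  lam <- params$lambda
  tau <- params$tau_dual
  xix <- fdx(xi)
  xiy <- fdy(xi)
  upd <- function(s) {
    # duals for one scalar target s: p solves the TV prox of s via
    # p <- (p + tau grad(div p - lambda s)) / (1 + tau |grad(...)|)
    p1 <- xi * 0
    p2 <- xi * 0
    for (l in seq_len(params$n_dual)) {
      A <- bdiv(p1, p2) - lam * s
      g1 <- fdx(A)
      g2 <- fdy(A)
      den <- 1 + tau * sqrt(g1^2 + g2^2)
      p1 <- (p1 + tau * g1) / den
      p2 <- (p2 + tau * g2) / den
    }
    list(p1 = p1, p2 = p2, div = bdiv(p1, p2))
  }
  d1 <- upd(xix)
  d2 <- upd(xiy)
  list(v1 = xix - d1$div / lam, v2 = xiy - d2$div / lam,
       p1_mag = sqrt(d1$p1^2 + d1$p2^2), p2_mag = sqrt(d2$p1^2 + d2$p2^2))
}

#' Denoise with the hybrid split model
#'
#' Alternates the Chambolle `v` update, the proximal-linearized log-image
#' update, isotropic shrinkage of the gradient split variable, and the
#' Bregman accumulator, then maps back with `exp`.  Output is strictly
#' positive by construction.
#'
#' @param f0 observed noisy image (`image_field`, strictly positive).
#' @param params an [m3_params()] list.
#' @param reference optional clean image for per-iteration PSNR.
#' @return a list with `image` and `trace`.
#' @export
m3_denoise <- function(f0, params = m3_params(), reference = NULL) {
  f0 <- as_image_field(f0)
  stopifnot_positive_field(f0, "observed image")
  p <- params
  f0v <- f0$values
  xi <- log(f0v)
  eta1 <- xi * 0; eta2 <- xi * 0
  b1 <- xi * 0; b2 <- xi * 0
  ref <- if (is.null(reference)) NULL else as_image_field(reference)$values
  rels <- numeric(); psnrs <- numeric(); iters <- 0L
  for (k in seq_len(p$max_iter)) {
    v <- chambolle_v_update(xi, p)
    # proximal-linearized xi step; the penalty is ||eta - grad xi + b||^2,
    # whose xi-gradient is -mu div(grad xi - eta - b) -- note the minus on
    # b, forced by the same sign convention as the eta and b updates
    gx <- fdx(xi); gy <- fdy(xi)
    grad_fid <- p$beta * (1 - f0v * exp(-xi))
    xi_new <- xi - p$sigma_prox *
      (grad_fid - p$mu * bdiv(gx - eta1 - b1, gy - eta2 - b2))
    rel <- sqrt(sum((xi_new - xi)^2)) / max(sqrt(sum(xi^2)), 1e-300)
    xi <- xi_new
    if (!all(is.finite(xi))) {
      return(list(image = image_field(exp(pmin(pmax(xi, -700), 700)),
                                      spacing = f0$spacing),
                  trace = solver_trace("m3", rel_changes = rels, psnr = psnrs,
                                       iterations = iters, diverged = TRUE)))
    }
    # shrinkage of the gradient split variable (Bregman step)
    gx <- fdx(xi); gy <- fdy(xi)
    z1 <- p$lambda * v$v1 + p$mu * (gx - b1)
    z2 <- p$lambda * v$v2 + p$mu * (gy - b2)
    sh <- soft_threshold_pair(z1, z2, p$alpha)
    eta1 <- sh[[1]] / (p$lambda + p$mu)
    eta2 <- sh[[2]] / (p$lambda + p$mu)
    b1 <- b1 + eta1 - gx
    b2 <- b2 + eta2 - gy
    iters <- k
    rels[k] <- rel
    if (!is.null(ref)) psnrs[k] <- psnr(image_field(ref, f0$spacing),
                                        image_field(exp(xi), f0$spacing))
    if (rel < p$rel_tol) break
  }
  list(image = image_field(exp(xi), spacing = f0$spacing),
       trace = solver_trace("m3", rel_changes = rels, psnr = psnrs,
                            iterations = iters))
}
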