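#' Parameters for the nonconvex edge-indicator model
#'
#' Weighted TV with weight `eps_cvx + (1 - eps_cvx) b^2`, where the edge
#' indicator `b = alpha_b / (1 + alpha_b |grad u_smooth|)` (values in
#' `(0, alpha_b]`) is refreshed from a Gaussian-smoothed log image between
#' outer sweeps; the log-fidelity `lambda (u + z exp(-u))` subproblem is
#' solved pointwise by Newton inside an inner ADMM.
#'
#' @param lambda fidelity weight.
#' @param eps_cvx convex-combination weight in (0, 1).
#' @param alpha_b ceiling of the edge indicator (> 0).
#' @param sigma_smooth Gaussian smoothing width (pixels) for the edge
#'   indicator.
#' @param mu ADMM penalty.
#' @param rho_dual Chambolle projection step for the weighted TV prox.
#' @param tau_stop mean-change threshold for the outer loop.
#' @param outer_iter,inner_iter,dual_iter,newton_iter iteration budgets for
#'   the outer sweep, inner ADMM, dual projection, and Newton solves.
#' @return an `m4_params` list.
#' @export
m4_params <- function(lambda = 20, eps_cvx = 0.1, alpha_b = 10,
                      sigma_smooth = 1.5, mu = 10, rho_dual = 0.125,
                      tau_stop = 1e-5, outer_iter = 10, inner_iter = 10,
                      dual_iter = 10, newton_iter = 5) {
  if (!(eps_cvx > 0 && eps_cvx < 1)) {
    stop("eps_cvx must lie strictly between 0 and 1", call. = FALSE)
  }
  if (alpha_b <= 0 || lambda <= 0 || mu <= 0 || rho_dual <= 0) {
    stop("lambda, alpha_b, mu and rho_dual must be positive", call. = FALSE)
  }
  structure(list(lambda = lambda, eps_cvx = eps_cvx, alpha_b = alpha_b,
                 sigma_smooth = sigma_smooth, mu = mu, rho_dual = rho_dual,
                 tau_stop = tau_stop, outer_iter = as.integer(outer_iter),
                 inner_iter = as.integer(inner_iter),
                 dual_iter = as.integer(dual_iter),
                 newton_iter = as.integer(newton_iter)),
            class = "m4_params")
}

#' Pointwise Newton solve of the log-fidelity subproblem
#'
#' Solves `lambda (1 - z exp(-u)) + mu (u - v + d) = 0` per pixel.  The
#' left side is strictly increasing in `u` (derivative
#' `lambda z exp(-u) + mu > 0`), so the root is unique; a handful of Newton
#' iterations from `u = v - d` reaches it to near machine precision.
#'
#' @param v,d current ADMM split variable and scaled dual (matrices).
#' @param z observed (positive) image matrix.
#' @param lambda,mu model and penalty weights.
#' @param iters Newton iteration count.
#' @return matrix `u` of the same shape.
#' @export
m4_newton_u <- function(v, d, z, lambda, mu, iters = 5) {
  if (any(z <= 0)) stop("z must be strictly positive", call. = FALSE)
  u <- v - d
  for (i in seq_len(iters)) {
    e <- z * exp(-u)
    phi <- lambda * (1 - e) + mu * (u - v + d)
    u <- u - phi / (lambda * e + mu)
  }
  u
}

# separable Gaussian smoothing with replicate (Neumann) borders
gaussian_smooth <- function(u, sigma) {
  if (sigma <= 0) return(u)
  K <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-K:K)^2) / (2 * sigma^2))
  w <- w / sum(w)
  blur_rows <- function(x) {
    M <- nrow(x)
    out <- x * 0
    for (k in -K:K) {
      idx <- pmin(pmax(seq_len(M) + k, 1L), M)
      out <- out + w[k + K + 1L] * x[idx, , drop = FALSE]
    }
    out
  }
  t(blur_rows(t(blur_rows(u))))
}

# weighted TV prox of s = u + d via Chambolle projection with |q| <= w:
# v = s - (lambda/mu) div q
m4_tv_prox <- function(s, w, p, q1, q2) {
  for (m in seq_len(p$dual_iter)) {
    A <- bdiv(q1, q2) - (p$mu / p$lambda) * s
    g1 <- fdx(A)
    g2 <- fdy(A)
    den <- 1 + p$rho_dual * sqrt(g1^2 + g2^2) / w
    q1 <- (q1 + p$rho_dual * g1) / den
    q2 <- (q2 + p$rho_dual * g2) / den
  }
  list(v = s - (p$lambda / p$mu) * bdiv(q1, q2), q1 = q1, q2 = q2)
}

#' Denoise with the nonconvex edge-indicator model
#'
#' Outer loop: solve the weighted-TV + log-fidelity subproblem by inner
#' ADMM (pointwise Newton for the fidelity, weighted Chambolle projection
#' for the TV prox, scaled dual update), then refresh the edge indicator
#' from the Gaussian-smoothed log image.  Returns `exp(u)`, strictly
#' positive.
#'
#' @param z observed noisy image (`image_field`, strictly positive).
#' @param params an [m4_params()] list.
#' @param reference optional clean image for per-outer-sweep PSNR.
#' @return a list with `image` and `trace`; the trace also carries the
#'   final edge-indicator field in `$edge_indicator`.
#' @export
m4_denoise <- function(z, params = m4_params(), reference = NULL) {
  z <- as_image_field(z)
  stopifnot_positive_field(z, "observed image")
  p <- params
  zv <- z$values
  u <- log(zv)
  b <- matrix(p$alpha_b, nrow(zv), ncol(zv))
  ref <- if (is.null(reference)) NULL else as_image_field(reference)$values
  rels <- numeric(); psnrs <- numeric(); iters <- 0L
  for (k in seq_len(p$outer_iter)) {
    u_prev <- u
    w <- p$eps_cvx + (1 - p$eps_cvx) * b^2
    v <- u
    d <- u * 0
    q1 <- u * 0
    q2 <- u * 0
    for (n in seq_len(p$inner_iter)) {
      u <- m4_newton_u(v, d, zv, p$lambda, p$mu, p$newton_iter)
      pr <- m4_tv_prox(u + d, w, p, q1, q2)
      v <- pr$v
      q1 <- pr$q1
      q2 <- pr$q2
      d <- d + u - v
    }
    u <- v # the TV-regularized iterate is the sweep's output
    ut <- gaussian_smooth(u, p$sigma_smooth)
    b <- p$alpha_b / (1 + p$alpha_b * sqrt(fdx(ut)^2 + fdy(ut)^2))
    iters <- k
    rels[k] <- sqrt(sum((u - u_prev)^2)) / max(sqrt(sum(u_prev^2)), 1e-300)
    if (!is.null(ref)) psnrs[k] <- psnr(image_field(ref, z$spacing),
                                        image_field(exp(u), z$spacing))
    if (!all(is.finite(u))) {
      tr <- solver_trace("m4", rel_changes = rels, psnr = psnrs,
                         iterations = iters, diverged = TRUE)
      tr$edge_indicator <- b
      return(list(image = image_field(exp(pmin(pmax(u, -700), 700)),
                                      spacing = z$spacing), trace = tr))
    }
    if (abs(mean(u - u_prev)) < p$tau_stop) break
  }
  tr <- solver_trace("m4", rel_changes = rels, psnr = psnrs,
                     iterations = iters)
  tr$edge_indicator <- b
  list(image = image_field(exp(u), spacing = z$spacing), trace = tr)
}
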