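test_that("soft_threshold matches its truth table and validates gamma", {
  expect_identical(soft_threshold(5, 2), 3)
  expect_identical(soft_threshold(1, 2), 0)
  expect_identical(soft_threshold(-5, 2), -3)
  expect_identical(soft_threshold(0, 1), 0)
  m <- matrix(c(-3, -1, 0, 1, 3, 10), 2, 3)
  expect_equal(soft_threshold(m, 1), matrix(c(-2, 0, 0, 0, 2, 9), 2, 3))
  expect_error(soft_threshold(1, 0), "positive")
})

test_that("M1 leaves constants unchanged and respects the maximum principle", {
  c0 <- image_field(matrix(1.3, 10, 10))
  out <- m1_denoise(c0, m1_params(max_iter = 5, rel_tol = 0))
  expect_equal(out$image$values, c0$values, tolerance = 1e-12)
  # fidelity off: semi-implicit diffusion cannot leave the input range
  fld <- random_positive_field(16, 16, seed = 21, spacing = 10)
  out <- m1_denoise(fld, m1_params(beta1 = 0, beta2 = 0, tau = 5,
                                   max_iter = 8, rel_tol = 0))
  expect_gte(min(out$image$values), min(fld$values) - 1e-10)
  expect_lte(max(out$image$values), max(fld$values) + 1e-10)
})

test_that("one AOS step approaches the unsplit semi-implicit solve at O(tau^2)", {
  fld <- random_positive_field(16, 16, seed = 13, spacing = 10)
  fv <- fld$values
  h <- 10
  # unsplit oracle: dense (I - tau (Ax + Ay)) solve with the same frozen
  # diffusivities and harmonic face averages
  unsplit <- function(tau, eps) {
    gr <- oracle_gradient(fv, h, eps)
    D <- 1 / (gr$gx^2 + gr$gy^2 + eps)
    M <- nrow(fv); N <- ncol(fv); n <- M * N
    idx <- function(i, j) (j - 1L) * M + i
    A <- matrix(0, n, n)
    hm <- function(a, b) 2 * a * b / (a + b)
    for (i in 1:M) for (j in 1:N) {
      if (i < M) {
        df <- hm(D[i, j], D[i + 1, j]) / h^2
        A[idx(i, j), idx(i, j)] <- A[idx(i, j), idx(i, j)] - df
        A[idx(i, j), idx(i + 1, j)] <- A[idx(i, j), idx(i + 1, j)] + df
        A[idx(i + 1, j), idx(i + 1, j)] <- A[idx(i + 1, j), idx(i + 1, j)] - df
        A[idx(i + 1, j), idx(i, j)] <- A[idx(i + 1, j), idx(i, j)] + df
      }
      if (j < N) {
        df <- hm(D[i, j], D[i, j + 1]) / h^2
        A[idx(i, j), idx(i, j)] <- A[idx(i, j), idx(i, j)] - df
        A[idx(i, j), idx(i, j + 1)] <- A[idx(i, j), idx(i, j + 1)] + df
        A[idx(i, j + 1), idx(i, j + 1)] <- A[idx(i, j + 1), idx(i, j + 1)] - df
        A[idx(i, j + 1), idx(i, j)] <- A[idx(i, j + 1), idx(i, j)] + df
      }
    }
    lam <- 0.0061 + 0.0411 / fv
    rhs <- as.vector(fv - tau * lam * (fv - fv)) # g0 = f: zero residual
    matrix(solve(diag(n) - tau * A, rhs), M, N)
  }
  err <- function(tau) {
    aos <- m1_denoise(fld, m1_params(tau = tau, epsilon = 1e-2, max_iter = 1,
                                     rel_tol = 0))$image$values
    sqrt(sum((aos - unsplit(tau, 1e-2))^2))
  }
  # tau small enough that tau * D / h^2 << 1 (the Taylor regime of the
  # splitting-error estimate)
  e1 <- err(0.02); e2 <- err(0.01)
  expect_gt(e1 / e2, 2.5) # ratio ~4 for an O(tau^2) splitting error
  expect_lt(e1 / e2, 6)
})

test_that("M1 improves PSNR on a noisy phantom", {
  ph <- study_phantom(48)
  f <- speckle_uniform(ph, 0.1, seed = 1)
  out <- m1_denoise(f, study_m1_params())
  expect_gt(psnr(ph, out$image), psnr(ph, f) + 3)
})

test_that("chambolle_v_update: zero on constants, bounded duals, large-lambda limit", {
  const <- matrix(1.7, 12, 12)
  v <- chambolle_v_update(const, m3_params())
  expect_true(all(v$v1 == 0) && all(v$v2 == 0))
  xi <- log(study_phantom(24)$values)
  v <- chambolle_v_update(xi, m3_params(n_dual = 30))
  expect_lte(max(v$p1_mag), 1 + 1e-12)
  expect_lte(max(v$p2_mag), 1 + 1e-12)
  ramp <- outer(seq(0, 1, length.out = 16), rep(1, 16))
  vbig <- chambolle_v_update(ramp, m3_params(lambda = 1e7))
  gx <- speckletv:::fdx(ramp)
  expect_lt(max(abs(vbig$v1 - gx)), 1e-5)
})

test_that("M3: constant fixed point, positivity, and denoising sanity", {
  c0 <- image_field(matrix(0.9, 12, 12))
  out <- m3_denoise(c0, m3_params(max_iter = 10, rel_tol = 0))
  expect_equal(out$image$values, c0$values, tolerance = 1e-11)
  ph <- study_phantom(48)
  f <- speckle_gamma(ph, 3, seed = 2)
  out <- m3_denoise(f, m3_params())
  expect_true(all(out$image$values > 0))
  expect_gt(psnr(ph, out$image), psnr(ph, f))
})

test_that("M3 shrinkage step equals the literal transcription", {
  # eta = T(lambda v + mu (grad xi - b), alpha) / (lambda + mu), with the
  # joint two-component magnitude
  withr::with_seed(31, {
    z1 <- matrix(rnorm(36, sd = 3), 6, 6)
    z2 <- matrix(rnorm(36, sd = 3), 6, 6)
  })
  sh <- speckletv:::soft_threshold_pair(z1, z2, 1.3)
  for (i in 1:6) for (j in 1:6) {
    m <- sqrt(z1[i, j]^2 + z2[i, j]^2)
    fac <- if (m > 0) max(m - 1.3, 0) / m else 0
    expect_equal(sh[[1]][i, j], z1[i, j] * fac, tolerance = 1e-14)
    expect_equal(sh[[2]][i, j], z2[i, j] * fac, tolerance = 1e-14)
  }
})

test_that("m4_newton_u solves its scalar root problem", {
  z <- matrix(exp(seq(-1, 1, length.out = 16)), 4, 4)
  v <- log(z); d <- v * 0
  expect_equal(m4_newton_u(v, d, z, 20, 10), log(z), tolerance = 1e-12)
  withr::with_seed(8, {
    z <- matrix(runif(16, 0.2, 2), 4, 4)
    v <- log(z) + matrix(rnorm(16, sd = 0.3), 4, 4)
    d <- matrix(rnorm(16, sd = 0.05), 4, 4)
  })
  u <- m4_newton_u(v, d, z, 20, 10, iters = 5)
  resid <- 20 * (1 - z * exp(-u)) + 10 * (u - v + d)
  expect_lt(max(abs(resid)), 1e-10)
  # penalty domination
  u_big <- m4_newton_u(v, d, z, 20, 1e9, iters = 8)
  expect_lt(max(abs(u_big - (v - d))), 1e-6)
  expect_error(m4_newton_u(v, d, z * 0, 20, 10), "positive")
})

test_that("M4: constant fixed point, edge indicator range, objective descent", {
  c0 <- image_field(matrix(1.4, 12, 12))
  out <- m4_denoise(c0, m4_params(outer_iter = 3))
  expect_equal(out$image$values, c0$values, tolerance = 1e-11)
  expect_equal(out$trace$edge_indicator, matrix(10, 12, 12))

  ph <- study_phantom(32)
  z <- speckle_gamma(ph, 3, seed = 4)
  p <- m4_params()
  out <- m4_denoise(z, p)
  expect_true(all(out$image$values > 0))
  expect_true(all(out$trace$edge_indicator > 0 &
                    out$trace$edge_indicator <= p$alpha_b))
  expect_gt(psnr(ph, out$image), psnr(ph, z))

  # inner ADMM: weighted objective at u decreases over the first sweeps
  zv <- z$values
  u <- log(zv); b <- matrix(p$alpha_b, 32, 32)
  w <- p$eps_cvx + (1 - p$eps_cvx) * b^2
  fdx <- speckletv:::fdx; fdy <- speckletv:::fdy
  objective <- function(u) {
    p$lambda * sum(u + zv * exp(-u)) + sum(w * sqrt(fdx(u)^2 + fdy(u)^2))
  }
  v <- u; d <- u * 0; q1 <- u * 0; q2 <- u * 0
  prev <- objective(u)
  for (n in 1:10) {
    u <- m4_newton_u(v, d, zv, p$lambda, p$mu, p$newton_iter)
    pr <- speckletv:::m4_tv_prox(u + d, w, p, q1, q2)
    v <- pr$v; q1 <- pr$q1; q2 <- pr$q2
    d <- d + u - v
    cur <- objective(u)
    expect_lte(cur, prev + abs(prev) * 1e-9)
    prev <- cur
  }
})

test_that("all four solvers return strictly positive images", {
  ph <- study_phantom(24)
  f <- speckle_uniform(ph, 0.2, seed = 6)
  quick <- list(
    m1_denoise(f, m1_params(max_iter = 10, rel_tol = 0))$image,
    m2_denoise(f, elastica_params(max_iter = 50, rel_tol = 0),
               record_energy = FALSE)$image,
    m3_denoise(f, m3_params(max_iter = 30))$image,
    m4_denoise(f, m4_params(outer_iter = 3))$image)
  for (img in quick) expect_gt(min(img$values), 0)
})
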