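# Independent literal transcriptions of the discrete scheme, written as
# naive per-pixel loops.  These deliberately share no code with the
# package's vectorized/compiled implementation; they are the second route
# of every dual-route check.

oracle_minmod <- function(m, n) {
  ((sign(m) + sign(n)) / 2) * min(abs(m), abs(n))
}

# mirrored one-pixel ghost ring: g[i,0]=g[i,1], g[i,N+1]=g[i,N], etc.
# Returned with index helpers: P(i, j) addresses whole-pixel (i, j) with
# i in 0..M+1, j in 0..N+1.
oracle_pad_fun <- function(g) {
  M <- nrow(g); N <- ncol(g)
  function(i, j) {
    i <- min(max(i, 1L), M)
    j <- min(max(j, 1L), N)
    g[i, j]
  }
}

# central-difference gradient components over 2h and the consistent
# magnitude sqrt(gx^2 + gy^2 + eps)
oracle_gradient <- function(g, h, eps) {
  M <- nrow(g); N <- ncol(g)
  G <- oracle_pad_fun(g)
  gx <- matrix(0, M, N); gy <- matrix(0, M, N); mag <- matrix(0, M, N)
  for (i in 1:M) for (j in 1:N) {
    gx[i, j] <- (G(i + 1, j) - G(i - 1, j)) / (2 * h)
    gy[i, j] <- (G(i, j + 1) - G(i, j - 1)) / (2 * h)
    mag[i, j] <- sqrt(gx[i, j]^2 + gy[i, j]^2 + eps)
  }
  list(gx = gx, gy = gy, mag = mag)
}

# level-set curvature: central divergence of the regularized unit gradient,
# with the unit gradient itself evaluated one mirrored ring out
oracle_curvature <- function(g, h, eps) {
  M <- nrow(g); N <- ncol(g)
  G <- oracle_pad_fun(g)
  nfun <- function(i, j) {
    # unit gradient at padded location (i, j); its own neighbors clamp too
    dx <- (G(i + 1, j) - G(i - 1, j)) / (2 * h)
    dy <- (G(i, j + 1) - G(i, j - 1)) / (2 * h)
    m <- sqrt(dx^2 + dy^2 + eps)
    c(dx / m, dy / m)
  }
  k <- matrix(0, M, N)
  for (i in 1:M) for (j in 1:N) {
    k[i, j] <- (nfun(i + 1, j)[1] - nfun(i - 1, j)[1]) / (2 * h) +
               (nfun(i, j + 1)[2] - nfun(i, j - 1)[2]) / (2 * h)
  }
  k
}

# all half-pixel (face) quantities; P = kappa * |grad g| on whole pixels,
# padded by mirroring like g
oracle_bundle <- function(g, h, eps) {
  M <- nrow(g); N <- ncol(g)
  G <- oracle_pad_fun(g)
  kap <- oracle_curvature(g, h, eps)
  mag <- oracle_gradient(g, h, eps)$mag
  K <- oracle_pad_fun(kap)
  P <- oracle_pad_fun(kap * mag)

  kx <- dxg_x <- dyg_x <- dxP_x <- dyP_x <- mag_x <- matrix(0, M + 1, N)
  for (f in 0:M) for (j in 1:N) {
    a <- f; b <- f + 1
    dxg <- (G(b, j) - G(a, j)) / h
    dyg <- oracle_minmod((G(b, j + 1) - G(b, j - 1)) / (2 * h),
                         (G(a, j + 1) - G(a, j - 1)) / (2 * h))
    dxP <- (P(b, j) - P(a, j)) / h
    dyP <- oracle_minmod((P(b, j + 1) - P(b, j - 1)) / (2 * h),
                         (P(a, j + 1) - P(a, j - 1)) / (2 * h))
    kx[f + 1, j] <- oracle_minmod(K(b, j), K(a, j))
    dxg_x[f + 1, j] <- dxg
    dyg_x[f + 1, j] <- dyg
    dxP_x[f + 1, j] <- dxP
    dyP_x[f + 1, j] <- dyP
    mag_x[f + 1, j] <- sqrt(dxg^2 + dyg^2 + eps)
  }

  ky <- dyg_y <- dxg_y <- dyP_y <- dxP_y <- mag_y <- matrix(0, M, N + 1)
  for (i in 1:M) for (f in 0:N) {
    a <- f; b <- f + 1
    dyg <- (G(i, b) - G(i, a)) / h
    dxg <- oracle_minmod((G(i + 1, b) - G(i - 1, b)) / (2 * h),
                         (G(i + 1, a) - G(i - 1, a)) / (2 * h))
    dyP <- (P(i, b) - P(i, a)) / h
    dxP <- oracle_minmod((P(i + 1, b) - P(i - 1, b)) / (2 * h),
                         (P(i + 1, a) - P(i - 1, a)) / (2 * h))
    ky[i, f + 1] <- oracle_minmod(K(i, b), K(i, a))
    dyg_y[i, f + 1] <- dyg
    dxg_y[i, f + 1] <- dxg
    dyP_y[i, f + 1] <- dyP
    dxP_y[i, f + 1] <- dxP
    mag_y[i, f + 1] <- sqrt(dxg^2 + dyg^2 + eps)
  }
  list(kappa_x = kx, dxg_x = dxg_x, dyg_x = dyg_x, dxP_x = dxP_x,
       dyP_x = dyP_x, mag_x = mag_x, kappa_y = ky, dyg_y = dyg_y,
       dxg_y = dxg_y, dyP_y = dyP_y, dxP_y = dxP_y, mag_y = mag_y)
}

# flux components from the vector form with perp = (-gy, gx):
# U = (a1 + a2 k^2) grad/|grad| - (2 a2/|grad|^3) (perp . grad(k|grad|)) perp
oracle_flux <- function(g, h, eps, a1, a2) {
  B <- oracle_bundle(g, h, eps)
  M <- nrow(g); N <- ncol(g)
  U1 <- matrix(0, M + 1, N)
  for (f in 1:(M + 1)) for (j in 1:N) {
    k <- B$kappa_x[f, j]; gx <- B$dxg_x[f, j]; gy <- B$dyg_x[f, j]
    m <- B$mag_x[f, j]
    dot <- (-gy) * B$dxP_x[f, j] + gx * B$dyP_x[f, j]
    U1[f, j] <- (a1 + a2 * k^2) * gx / m - (2 * a2 / m^3) * dot * (-gy)
  }
  U2 <- matrix(0, M, N + 1)
  for (i in 1:M) for (f in 1:(N + 1)) {
    k <- B$kappa_y[i, f]; gx <- B$dxg_y[i, f]; gy <- B$dyg_y[i, f]
    m <- B$mag_y[i, f]
    dot <- (-gy) * B$dxP_y[i, f] + gx * B$dyP_y[i, f]
    U2[i, f] <- (a1 + a2 * k^2) * gy / m - (2 * a2 / m^3) * dot * gx
  }
  list(U1 = U1, U2 = U2)
}

oracle_divergence <- function(U1, U2, h) {
  M <- nrow(U2); N <- ncol(U1)
  d <- matrix(0, M, N)
  for (i in 1:M) for (j in 1:N) {
    d[i, j] <- (U1[i + 1, j] - U1[i, j]) / h + (U2[i, j + 1] - U2[i, j]) / h
  }
  d
}

# discrete energy with the verbatim (intensity-unit) whole-pixel magnitude
oracle_energy <- function(g, f, h, eps, b1, b2, a1, a2, literal = TRUE) {
  kap <- oracle_curvature(g, h, eps)
  M <- nrow(g); N <- ncol(g)
  G <- oracle_pad_fun(g)
  s <- 0
  for (i in 1:M) for (j in 1:N) {
    mag40 <- 0.5 * sqrt((G(i + 1, j) - G(i - 1, j))^2 +
                        (G(i, j + 1) - G(i, j - 1))^2 + 4 * h^2 * eps)
    magv <- if (literal) mag40 else mag40 / h
    s <- s + (b1 + b2 / g[i, j]) * (a1 + a2 * kap[i, j]^2) * magv +
      log(g[i, j]) + f[i, j] / g[i, j]
  }
  h * h * s
}

oracle_psnr <- function(ghat, g) {
  ss <- 0
  for (i in seq_len(nrow(g))) for (j in seq_len(ncol(g))) {
    ss <- ss + (ghat[i, j] - g[i, j])^2
  }
  10 * log10(nrow(g) * ncol(g) * max(ghat)^2 / ss)
}

# pure TV flux at faces (the alpha2 = 0 limit), coded directly
oracle_tv_flux <- function(g, h, eps, a1) {
  M <- nrow(g); N <- ncol(g)
  G <- oracle_pad_fun(g)
  U1 <- matrix(0, M + 1, N)
  for (f in 0:M) for (j in 1:N) {
    dxg <- (G(f + 1, j) - G(f, j)) / h
    dyg <- oracle_minmod((G(f + 1, j + 1) - G(f + 1, j - 1)) / (2 * h),
                         (G(f, j + 1) - G(f, j - 1)) / (2 * h))
    U1[f + 1, j] <- a1 * dxg / sqrt(dxg^2 + dyg^2 + eps)
  }
  U2 <- matrix(0, M, N + 1)
  for (i in 1:M) for (f in 0:N) {
    dyg <- (G(i, f + 1) - G(i, f)) / h
    dxg <- oracle_minmod((G(i + 1, f + 1) - G(i - 1, f + 1)) / (2 * h),
                         (G(i + 1, f) - G(i - 1, f)) / (2 * h))
    U2[i, f + 1] <- a1 * dyg / sqrt(dxg^2 + dyg^2 + eps)
  }
  list(U1 = U1, U2 = U2)
}

random_positive_field <- function(M, N, seed, lo = 0.2, hi = 1.2,
                                  spacing = 10) {
  withr::with_seed(seed, {
    image_field(matrix(runif(M * N, lo, hi), M, N), spacing = spacing)
  })
}
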