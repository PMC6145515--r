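test_that("minmod matches its sign truth table and algebraic properties", {
  expect_identical(minmod(2, 3), 2)
  expect_identical(minmod(-2, 3), 0)
  expect_identical(minmod(-4, -1), -1)
  expect_identical(minmod(0, 5), 0)
  for (k in 1:50) {
    mn <- withr::with_seed(k, runif(2, -5, 5))
    expect_equal(minmod(mn[1], mn[2]), minmod(mn[2], mn[1]))
    expect_lte(abs(minmod(mn[1], mn[2])), min(abs(mn)))
    expect_equal(minmod(mn[1], mn[1]), mn[1])
  }
  expect_error(minmod(NA_real_, 1), "finite")
})

test_that("neumann_pad mirrors edges and corners and is interior-idempotent", {
  v <- matrix(as.numeric(1:9), 3, 3)
  p <- neumann_pad(image_field(v, spacing = 1))$values
  expect_identical(dim(p), c(5L, 5L))
  expect_identical(p[2:4, 2:4], v)
  expect_identical(p[1, 2:4], v[1, ])      # top ghost row
  expect_identical(p[2:4, 5], v[, 3])      # right ghost col
  expect_identical(p[1, 1], v[1, 1])       # corner: both reflections
  expect_identical(p[5, 5], v[3, 3])
  const <- neumann_pad(image_field(matrix(4, 3, 3)))$values
  expect_true(all(const == 4))
  # padding twice agrees with padding the padded field on the shared ring
  pp <- neumann_pad(image_field(p, spacing = 1))$values
  expect_identical(pp[2:6, 2:6], p)
})

test_that("central gradient is exact on constants and linear ramps", {
  h <- 10
  const <- image_field(matrix(3, 6, 6), spacing = h)
  gr <- central_gradient(const, epsilon = 1e-4)
  expect_true(all(gr$gx == 0) && all(gr$gy == 0))
  expect_equal(gr$magnitude, matrix(h * sqrt(1e-4), 6, 6)) # literal reading
  expect_equal(central_gradient(const, 1e-4, literal = FALSE)$magnitude,
               matrix(sqrt(1e-4), 6, 6))
  ramp <- image_field(outer(rep(1, 7), (1:7) * 0.3 * h) + 1, spacing = h)
  gr <- central_gradient(ramp, epsilon = 1e-12)
  expect_equal(gr$gy[, 2:6], matrix(0.3, 7, 5), tolerance = 1e-12)
  expect_equal(gr$gx, matrix(0, 7, 7), tolerance = 1e-12)
  expect_error(central_gradient(ramp, epsilon = 0), "positive")
})

test_that("gradient, curvature and bundle match the per-pixel oracles", {
  for (k in 1:8) {
    fld <- random_positive_field(5 + k %% 3, 6, seed = 100 + k)
    o <- oracle_gradient(fld$values, fld$spacing, 1e-3)
    g <- central_gradient(fld, 1e-3, literal = FALSE)
    expect_equal(g$gx, o$gx, tolerance = 1e-14)
    expect_equal(g$gy, o$gy, tolerance = 1e-14)
    expect_equal(g$magnitude, o$mag, tolerance = 1e-14)
    k2 <- curvature(fld, 1e-3)$kappa
    expect_equal(k2, oracle_curvature(fld$values, fld$spacing, 1e-3),
                 tolerance = 1e-13)
    b <- half_pixel_bundle(fld, 1e-3)
    ob <- oracle_bundle(fld$values, fld$spacing, 1e-3)
    for (nm in names(ob)) expect_equal(b[[nm]], ob[[nm]], tolerance = 1e-13)
  }
})

test_that("curvature vanishes on constants and planes, matches 1/r on a cone", {
  expect_true(all(curvature(image_field(matrix(2, 8, 8)), 1e-6)$kappa == 0))
  plane <- image_field(outer(1:9, 1:9, function(i, j) 0.2 * i + 0.1 * j) + 1,
                       spacing = 1)
  expect_lt(max(abs(curvature(plane, 1e-10)$kappa[3:7, 3:7])), 1e-8)
  n <- 101
  r <- sqrt(outer((1:n) - 51, rep(1, n))^2 + outer(rep(1, n), (1:n) - 51)^2)
  cone <- image_field(pmax(r, 1e-9), spacing = 1)
  kap <- curvature(cone, 1e-8)$kappa
  ring <- abs(r - 20) < 0.5
  expect_lt(abs(mean(kap[ring]) - 1 / 20) / (1 / 20), 0.05)
})

test_that("half-pixel bundle: constants give zero derivatives, sqrt(eps) magnitude", {
  b <- half_pixel_bundle(image_field(matrix(5, 6, 7)), 1e-4)
  for (nm in c("dxg_x", "dyg_x", "dxP_x", "dyP_x", "kappa_x"))
    expect_true(all(b[[nm]] == 0))
  expect_equal(b$mag_x, matrix(sqrt(1e-4), 7, 7))
  expect_equal(b$mag_y, matrix(sqrt(1e-4), 6, 8))
})

test_that("bundle mirrors under left-right flip with flipped derivative signs", {
  fld <- random_positive_field(6, 6, seed = 42)
  flipped <- image_field(fld$values[6:1, ], spacing = fld$spacing)
  b <- half_pixel_bundle(fld, 1e-3)
  bf <- half_pixel_bundle(flipped, 1e-3)
  # x faces reverse order; in-axis x derivatives change sign
  expect_equal(bf$dxg_x, -b$dxg_x[7:1, ], tolerance = 1e-14)
  expect_equal(bf$dyg_x, b$dyg_x[7:1, ], tolerance = 1e-14)
  expect_equal(bf$mag_x, b$mag_x[7:1, ], tolerance = 1e-14)
})

test_that("diffops commute with transposition (90-degree symmetry)", {
  fld <- random_positive_field(7, 7, seed = 9)
  tfld <- image_field(t(fld$values), spacing = fld$spacing)
  expect_equal(curvature(tfld, 1e-3)$kappa, t(curvature(fld, 1e-3)$kappa),
               tolerance = 1e-14)
  g <- central_gradient(fld, 1e-3)
  gt <- central_gradient(tfld, 1e-3)
  expect_equal(gt$gx, t(g$gy), tolerance = 1e-14)
  expect_equal(gt$magnitude, t(g$magnitude), tolerance = 1e-14)
  b <- half_pixel_bundle(fld, 1e-3)
  bt <- half_pixel_bundle(tfld, 1e-3)
  expect_equal(bt$dxg_x, t(b$dyg_y), tolerance = 1e-14)
  expect_equal(bt$kappa_x, t(b$kappa_y), tolerance = 1e-14)
})
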