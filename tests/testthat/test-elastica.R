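test_that("weber_lambda follows (beta1 g + beta2)/g", {
  g1 <- image_field(matrix(1, 4, 4))
  expect_equal(weber_lambda(g1, 0.003, 0.05), matrix(0.053, 4, 4))
  g <- random_positive_field(5, 5, seed = 2)
  expect_equal(weber_lambda(g, 0.7, 0), matrix(0.7, 5, 5))
  expect_equal(weber_lambda(image_field(2 * g$values), 0, 0.1),
               weber_lambda(g, 0, 0.1) / 2)
  expect_no_error(weber_lambda(image_field(matrix(1e-9, 3, 3)), 1, 1))
  expect_error(weber_lambda(image_field(matrix(0, 3, 3) - 1 + 1), 1, 1),
               "positive")
})

test_that("elastica flux vanishes on constants and matches the formula oracle", {
  const <- image_field(matrix(2.5, 6, 6))
  fl <- elastica_flux(const, elastica_params())
  expect_true(all(fl$U1 == 0) && all(fl$U2 == 0))
  for (k in 1:20) {
    fld <- random_positive_field(6, 6, seed = 300 + k)
    p <- elastica_params(epsilon = 1e-3)
    fl <- elastica_flux(fld, p)
    of <- oracle_flux(fld$values, fld$spacing, 1e-3, p$alpha1, p$alpha2)
    expect_equal(fl$U1, of$U1, tolerance = 1e-12)
    expect_equal(fl$U2, of$U2, tolerance = 1e-12)
    dv <- flux_divergence(fl)
    expect_equal(dv, oracle_divergence(of$U1, of$U2, fld$spacing),
                 tolerance = 1e-12)
  }
})

test_that("alpha2 = 0 reduces the flux to the pure TV flux", {
  fld <- random_positive_field(8, 7, seed = 77)
  p <- elastica_params(alpha1 = 0.6, alpha2 = 0, epsilon = 1e-3)
  fl <- elastica_flux(fld, p)
  tv <- oracle_tv_flux(fld$values, fld$spacing, 1e-3, 0.6)
  expect_equal(fl$U1, tv$U1, tolerance = 1e-13)
  expect_equal(fl$U2, tv$U2, tolerance = 1e-13)
})

test_that("flux divergence: zero flux, constant interior flux, domain sum", {
  z <- flux_divergence(list(U1 = matrix(0, 7, 6), U2 = matrix(0, 6, 7)),
                       spacing = 2)
  expect_true(all(z == 0))
  U1 <- matrix(1, 7, 6); U1[1, ] <- 0; U1[7, ] <- 0 # boundary faces closed
  d <- flux_divergence(list(U1 = U1, U2 = matrix(0, 6, 7)), spacing = 2)
  expect_true(all(d[2:5, ] == 0))
  fld <- random_positive_field(12, 9, seed = 5)
  fl <- elastica_flux(fld, elastica_params())
  expect_lt(abs(sum(flux_divergence(fl))), 1e-10)
})

test_that("m2_step: constant fixed point, dt = 0 identity, energy descent", {
  c0 <- image_field(matrix(0.8, 8, 8))
  expect_equal(m2_step(c0, c0)$values, c0$values)
  ph <- study_phantom(24)
  f <- speckle_uniform(ph, 0.1, seed = 1)
  p0 <- elastica_params(dt = 0)
  expect_equal(m2_step(f, f, p0)$values, f$values)
  p <- elastica_params()
  e_before <- m2_energy(f, f, p)
  g1 <- m2_step(f, f, p)
  expect_lte(m2_energy(g1, f, p), e_before + abs(e_before) * 1e-9)
  expect_error(m2_step(f, study_phantom(16)), "same shape")
})

test_that("discrete energy matches its closed form and the sum oracle", {
  p <- elastica_params(epsilon = 1e-4, spacing = 10)
  c0 <- image_field(matrix(1.5, 6, 6), spacing = 10)
  closed <- 10 * 10 * 36 *
    ((p$beta1 + p$beta2 / 1.5) * p$alpha1 * (10 * sqrt(1e-4)) +
       log(1.5) + 1)
  expect_equal(m2_energy(c0, c0, p), closed, tolerance = 1e-12)
  for (k in 1:5) {
    fld <- random_positive_field(8, 8, seed = 400 + k)
    f <- random_positive_field(8, 8, seed = 500 + k)
    expect_equal(m2_energy(fld, f, p),
                 oracle_energy(fld$values, f$values, 10, 1e-4, p$beta1,
                               p$beta2, p$alpha1, p$alpha2, literal = TRUE),
                 tolerance = 1e-12)
    # more regularization weight on a non-constant field costs energy
    p_up <- elastica_params(alpha1 = p$alpha1 * 2, epsilon = 1e-4)
    expect_gt(m2_energy(fld, f, p_up), m2_energy(fld, f, p))
  }
})

test_that("m2_denoise: clean input is a fixed point; trace is consistent", {
  c0 <- image_field(matrix(0.6, 12, 12))
  out <- m2_denoise(c0, elastica_params(max_iter = 20))
  expect_equal(out$image$values, c0$values)
  expect_lte(out$trace$iterations, 20)
  expect_length(out$trace$rel_changes, out$trace$iterations)
  ph <- study_phantom(24)
  f <- speckle_uniform(ph, 0.1, 3)
  out <- m2_denoise(f, elastica_params(max_iter = 30, rel_tol = 0),
                    reference = ph)
  expect_length(out$trace$energies, 30)
  expect_length(out$trace$psnr, 30)
  td <- tidy(out$trace)
  expect_identical(nrow(td), 30L)
  expect_true(all(c("energy", "psnr_db") %in% names(td)))
  expect_identical(glance(out$trace)$iterations, 30L)
})

test_that("the flow commutes with rotations and flips of the input", {
  ph <- study_phantom(20)
  f <- speckle_uniform(ph, 0.1, seed = 8)
  p <- elastica_params(max_iter = 50, rel_tol = 0)
  base <- m2_denoise(f, p, record_energy = FALSE)$image$values
  rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
  out_rot <- m2_denoise(image_field(rot90(f$values)), p,
                        record_energy = FALSE)$image$values
  expect_equal(out_rot, rot90(base), tolerance = 1e-10)
  out_flip <- m2_denoise(image_field(f$values[20:1, ]), p,
                         record_energy = FALSE)$image$values
  expect_equal(out_flip, base[20:1, ], tolerance = 1e-10)
})

test_that("the verbatim fidelity sign ascends the fidelity residual", {
  ph <- study_phantom(16)
  f <- speckle_uniform(ph, 0.05, seed = 2)
  g <- image_field(f$values * 1.05) # displaced from f
  step_desc <- m2_step(g, f, elastica_params(alpha1 = 0, alpha2 = 1e-9,
                                             beta1 = 1, beta2 = 0, dt = 1e-2))
  step_verb <- m2_step(g, f, elastica_params(alpha1 = 0, alpha2 = 1e-9,
                                             beta1 = 1, beta2 = 0, dt = 1e-2,
                                             verbatim_sign = TRUE))
  resid <- function(x) sum((x$values - f$values)^2)
  expect_lt(resid(step_desc), resid(g))   # descent shrinks the residual
  expect_gt(resid(step_verb), resid(g))   # printed sign grows it
})
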