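run_denoiser <- function(method, f, params, reference = NULL) {
  switch(method,
    m1 = m1_denoise(f, params, reference = reference),
    m2 = m2_denoise(f, params, reference = reference, record_energy = FALSE),
    m3 = m3_denoise(f, params, reference = reference),
    m4 = m4_denoise(f, params, reference = reference),
    stop("unknown method: ", method, call. = FALSE)
  )
}

default_params_for <- function(method) {
  switch(method,
    m1 = study_m1_params(),
    m2 = elastica_preset("phantom"),
    m3 = m3_params(),
    m4 = m4_params(),
    stop("unknown method: ", method, call. = FALSE)
  )
}

#' Calibrated study configurations
#'
#' The fixed solver settings used by the experiment harnesses on
#' [study_phantom()] scenes; iteration budgets and the AOS step were
#' calibrated once on a held-out seed (see the methods vignette) and are
#' not re-tuned per run.
#'
#' @return for `study_m1_params()`, an [m1_params()] list.
#' @export
study_m1_params <- function() {
  m1_params(tau = 2e-4, max_iter = 125, rel_tol = 0)
}

#' Compare denoising methods across seeds
#'
#' For each seed: draw a noise realization of the clean image, run every
#' requested method on it, and record PSNR against the clean reference.
#' A failing method yields a flagged row (`error` column), not an abort.
#'
#' @param clean clean reference `image_field`.
#' @param noise a [noise_spec()]; its seed is replaced by each element of
#'   `seeds` in turn.
#' @param configs named list of per-method parameter objects; names pick
#'   the methods (`"m1"`, `"m2"`, `"m3"`, `"m4"`).  `NULL` entries get the
#'   calibrated study defaults.
#' @param seeds integer vector of seeds.
#' @param image_name label recorded in the output.
#' @return a tibble with one row per (seed, method): columns `image`,
#'   `method`, `seed`, `psnr_noisy_db`, `psnr_db`, `iterations`,
#'   `clamp_count`, `error`.
#' @export
compare_methods <- function(clean, noise,
                            configs = list(m1 = NULL, m2 = NULL),
                            seeds = 1:5, image_name = "phantom") {
  clean <- as_image_field(clean)
  methods <- names(configs)
  stopifnot(length(methods) > 0, !any(methods == ""))
  rows <- list()
  for (seed in seeds) {
    f <- apply_noise(clean, noise, seed = seed)
    p_noisy <- psnr(clean, f)
    for (m in methods) {
      params <- if (is.null(configs[[m]])) default_params_for(m) else configs[[m]]
      res <- tryCatch(run_denoiser(m, f, params), error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          image = image_name, method = m, seed = seed,
          psnr_noisy_db = p_noisy, psnr_db = NA_real_,
          iterations = NA_integer_, clamp_count = NA_integer_,
          error = conditionMessage(res))
      } else {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          image = image_name, method = m, seed = seed,
          psnr_noisy_db = p_noisy, psnr_db = psnr(clean, res$image),
          iterations = res$trace$iterations,
          clamp_count = res$trace$clamp_count,
          error = if (res$trace$diverged) "diverged" else NA_character_)
      }
    }
  }
  do.call(rbind, rows)
}

#' Mean and spread of a method comparison
#'
#' @param rows output of [compare_methods()].
#' @return a tibble with one row per method: mean and sd of the restored
#'   PSNR and the mean improvement over the noisy input.
#' @export
summarize_comparison <- function(rows) {
  out <- lapply(split(rows, rows$method), function(d) {
    tibble::tibble(method = d$method[1], n_seeds = nrow(d),
                   psnr_mean_db = mean(d$psnr_db),
                   psnr_sd_db = if (nrow(d) > 1) sd(d$psnr_db) else NA_real_,
                   gain_mean_db = mean(d$psnr_db - d$psnr_noisy_db))
  })
  do.call(rbind, out)
}

#' Time-step study for the elastica/Weber solver
#'
#' Reruns the solver at each requested `dt` with all other parameters
#' fixed (including the iteration budget), across seeds.
#'
#' @inheritParams compare_methods
#' @param params an [elastica_params()] baseline setting.
#' @param dts positive time steps to try.
#' @return a tibble with one row per (dt, seed).
#' @export
dt_study <- function(clean, noise, params = elastica_preset("phantom_small"),
                     dts = c(2e-5, 2e-4, 2e-3, 2e-2), seeds = 1:5) {
  clean <- as_image_field(clean)
  if (any(dts <= 0)) stop("all dts must be positive", call. = FALSE)
  rows <- list()
  for (seed in seeds) {
    f <- apply_noise(clean, noise, seed = seed)
    for (dt in dts) {
      p <- params
      p$dt <- dt
      res <- m2_denoise(f, p, record_energy = FALSE)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        dt = dt, seed = seed, psnr_noisy_db = psnr(clean, f),
        psnr_db = psnr(clean, res$image),
        iterations = res$trace$iterations,
        diverged = res$trace$diverged)
    }
  }
  do.call(rbind, rows)
}

#' Joint parameter-sensitivity sweep
#'
#' Scales the weight quadruple `(beta1, beta2, alpha1, alpha2)` jointly by
#' each factor, reruns the solver, and reports the PSNR change against the
#' unscaled run with the same seed.
#'
#' @inheritParams dt_study
#' @param factors positive scale multipliers; 1 (the baseline) is added if
#'   absent.
#' @return a tibble with one row per (factor, seed), including
#'   `delta_psnr_db`, the signed change versus the factor-1 run.
#' @export
sensitivity_sweep <- function(clean, noise,
                              params = elastica_preset("phantom_small"),
                              factors = c(0.3, 0.6, 1, 1.4, 1.7),
                              seeds = 1:5) {
  clean <- as_image_field(clean)
  if (any(factors <= 0)) stop("all factors must be positive", call. = FALSE)
  factors <- sort(unique(c(1, factors)))
  rows <- list()
  for (seed in seeds) {
    f <- apply_noise(clean, noise, seed = seed)
    res_seed <- lapply(factors, function(cf) {
      p <- params
      p$beta1 <- params$beta1 * cf
      p$beta2 <- params$beta2 * cf
      p$alpha1 <- params$alpha1 * cf
      p$alpha2 <- params$alpha2 * cf
      m2_denoise(f, p, record_energy = FALSE)
    })
    ps <- vapply(res_seed, function(r) psnr(clean, r$image), numeric(1))
    base <- ps[factors == 1]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      factor_scale = factors, seed = seed, psnr_db = ps,
      delta_psnr_db = ps - base)
  }
  do.call(rbind, rows)
}

#' Plot a method comparison
#'
#' @param rows output of [compare_methods()].
#' @return a ggplot object (PSNR by method across seeds).
#' @export
plot_comparison <- function(rows) {
  ggplot2::ggplot(rows, ggplot2::aes(x = method, y = psnr_db)) +
    ggplot2::geom_boxplot(outlier.shape = NA, colour = "grey50") +
    ggplot2::geom_jitter(width = 0.08, height = 0) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = mean(rows$psnr_noisy_db)),
                        linetype = "dashed") +
    ggplot2::labs(y = "PSNR (dB)", x = NULL,
                  caption = "dashed line: mean PSNR of the noisy input") +
    ggplot2::theme_minimal()
}
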