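# speckletv

Variational restoration of 2-D grayscale images corrupted by
**multiplicative (speckle) noise** — the degradation `f = g * eta`
characteristic of coherent imaging (ultrasound, SAR, PET), where the
noise scales with the signal and additive-noise methods do not apply.
The package is aimed at researchers in biological/medical image analysis
who need a tested, reproducible reference implementation of
curvature-regularized speckle removal and its classical baselines.

## The model

The central solver minimizes an Euler-elastica, Weberized-TV energy

    E(g) = ∫ (β₁ + β₂/g) (α₁ + α₂ κ²) |∇g| dx  +  ∫ (log g + f/g) dx,
    κ = ∇·(∇g/|∇g|),

whose three factors are total variation (edge preservation), the
elastica curvature weight `α₁ + α₂κ²` (suppresses TV's staircase
artifact by penalizing curved level lines), and the Weber weight
`β₁ + β₂/g` (perceptual scaling by background intensity).  The fidelity
`log g + f/g` is the MAP term for mean-one gamma speckle.  Minimization
integrates the fourth-order flow

    ∂g/∂t = ∇·U − (β₁ + β₂/g)(g − f)

with a staggered-grid min-mod finite-difference scheme (Neumann
boundaries, explicit steps, default `dt = 2e-4`).  Three comparison
solvers are included: Weberized TV via additive operator splitting
(`m1_denoise`), a log-domain hybrid split-Bregman/Chambolle model
(`m3_denoise`), and a weighted-TV model with a nonconvex edge indicator
solved by ADMM (`m4_denoise`).  Synthetic phantoms, uniform/gamma
speckle simulators, PSNR and line-profile evaluation, and multi-seed
experiment harnesses (tidy tibble output, `autoplot()` figures) complete
the toolkit.

## Worked example

```r
library(speckletv)

ph  <- study_phantom(96)                      # shapes scene, unit scale
f   <- speckle_uniform(ph, sigma2 = 0.1, seed = 1)
out <- m2_denoise(f, elastica_preset("phantom"), reference = ph)

psnr(ph, f)            # 15.06 dB   (noisy input)
psnr(ph, out$image)    # 29.39 dB   (restored)
glance(out$trace)
#> # A tibble: 1 x 7
#>   method iterations final_rel_change final_energy final_psnr_db clamp_count diverged
#>   <chr>       <int>            <dbl>        <dbl>         <dbl>       <int> <lgl>
#> 1 m2          40000       0.00000101      163907.          29.4           0 FALSE
```

The ~14 dB gain is typical for the piecewise-constant study scene at
noise variance 0.1.  `autoplot(out$trace)` shows the PSNR and update
norm per iteration; `plot_line_profiles(list(clean = ph, noisy = f,
restored = out$image), 48)` overlays one image row before and after
restoration.  Multi-seed comparisons:

```r
rows <- compare_methods(study_phantom(128),
                        noise_spec("uniform_speckle", sigma2 = 0.1),
                        configs = list(m1 = NULL, m2 = NULL), seeds = 1:5)
summarize_comparison(rows)
```

A thin command-line front end ships in `inst/cli/speckletv`
(subcommands `synth`, `add-noise`, `denoise`, `run`, `evaluate`, `compare`,
`dt-study`, `sweep`; exit codes 0/2/3/4).

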