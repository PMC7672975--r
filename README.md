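# capsim

Antibody penetration into 3D in vitro tumor models is limited by diffusion
through the extracellular space and by binding to a finite pool of
cell-surface antigens. `capsim` is an R toolkit for simulating and
calibrating antibody transport across a 2D cross-section of an
alginate-encapsulated tumor microenvironment (TME) co-culture — cancer-cell
spheroids, fibroblasts and collagen fibers inside a ~700 µm capsule — the
kind of system imaged by light-sheet fluorescence microscopy (LSFM) during
an antibody challenge.

It is aimed at researchers who want to ask *where and when* an antibody
reaches cell clusters in such capsules, and to benchmark a transport model
against measured fluorescence profiles.

## Model

Transport is purely diffusive (Fick's second law in 2D),

    ∂C/∂t = ∇·(D ∇C),

solved with an explicit flux-conservative finite-difference scheme on a
200 × 200 mesh over a 1000 µm square, with harmonic-mean interface
diffusivities so zero-diffusivity collagen fibers are exact barriers. The
exterior of the 350 µm-radius capsule is held at the injection
concentration C_inj = 13 µg/mL (Dirichlet); the interior starts at zero.
Diffusivity is heterogeneous: D_medium = 0.15 µm²/s in medium and alginate,
D_cell = D_medium/100 in cells, linearly graded from 0 at a spheroid's
center to D_cell at its rim (D = D_cell · d / r_sph), and 0 in fibers.

Binding-site saturation is modeled as a multiplicative decay of cell-node
diffusivity driven by the local normalized concentration
C_norm = C / (0.01 · C_inj), clamped below 1:

    D ← D · exp( −(Δt/Δt_ref) · a · C_norm^n / (1 − C_norm)^p ),

with adjustable parameters (a, n, p). ROI mean-concentration profiles are
fitted with Richards-family sigmoids

    P(t) = M / [1 + α·exp(−M β t)]^γ,   α = [(M/P0)^(1/γ) − 1]·exp(M β t0),

yielding delay times (first crossing of 5% of the profile maximum) and
log-phase slopes (OLS slope over the 15–85% band). Calibration minimizes
the RMSE between min-max-normalized simulated and observed profiles over
(a, n, p) with BFGS in log-space.

## Worked example

```r
library(capsim)

dom <- build_domain(grid_spec()) |>                      # 200x200, R = 350 um
  place_elements(placement_config(n_fibers = 10), seed = 1) |>
  init_diffusivity(transport_config())                   # 0.15 / 0.0015 um^2/s
dom
#> <capsule_domain> 200 x 200 nodes (dx = 5 um), capsule R = 350 um
#>   nodes: exterior=24620, medium=14191, cancer=316, fibroblast=809, fiber=64
#>   spheroids: 1; diffusivity initialized

res <- run_simulation(dom, simulation_config(), saturation_params(1, 1, 1))
rois <- roi_spec("spheroid", dom$spheroids$x, dom$spheroids$y,
                 dom$spheroids$radius)
prof <- extract_profile(res, rois)
fit_profiles(prof)
#> # A tibble: 1 × 8
#>   roi_id   family         M  beta gamma    R2 delay_min     slope
#>   <chr>    <chr>      <dbl> <dbl> <dbl> <dbl>     <dbl>     <dbl>
#> 1 spheroid richards 0.00191  27.1  1.05 0.998      81.6 0.0000214
```

`fit_profiles()` reports, per ROI, the best-fitting sigmoid family, its
upper asymptote `M` (µg/mL), intrinsic growth rate `beta`, asymmetry
`gamma`, the goodness of fit `R2`, the arrival `delay_min` (minutes) and
the log-phase `slope` (µg/mL per minute). Here the 50 µm spheroid sits
~170 µm from the periphery: the antibody needs ~82 min to arrive, and the
cluster plateaus near 0.002 µg/mL because its cells saturate at 1% of the
13 µg/mL injection long before equilibrating with the medium.

Calibration against observed (or pseudo-experimental) profiles:

```r
fx <- make_pseudo_experiment(tempdir(), noise_sigma = 0.02, seed = 1)
roi <- with(fx$domain$spheroids, roi_spec("spheroid_1", x, y, radius))
fit <- fit_saturation(fx$domain, roi, fx$profiles,
                      init = c(0.5, 1.5, 0.7),
                      sim = simulation_config(store_diffusivity = FALSE))
glance(fit)   # fitted (a, n, p), normalized-profile RMSE, simulation count
```

A command-line interface wraps the same functions
(`build-capsule`, `digitize`, `simulate`, `fit-profiles`, `calibrate`,
`make-fixture`):

```sh
CAPSIM=$(Rscript -e 'cat(system.file("scripts", "capsim.R", package = "capsim"))')
Rscript "$CAPSIM" simulate \
  --config "$(Rscript -e 'cat(system.file("extdata", "default_run.yaml", package = "capsim"))')" \
  --out runs/demo --seed 42
```

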