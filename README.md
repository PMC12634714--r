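# sweat2blood

Non-invasive estimation of blood glucose concentration time courses from
sweat glucose measurements.

Sweat sensing is an attractive alternative to fingerstick sampling for
diabetes monitoring, but sweat glucose is a delayed, attenuated and diluted
echo of blood glucose. `sweat2blood` provides the full modelling chain
needed to invert that echo:

* a **biophysical transport model** — a 1-D compartmental
  convection–diffusion description of glucose moving from a blood capillary
  through the interstitial fluid (ISF) and the sweat-gland lumen to the skin
  surface (Starling filtration, Darcy/Poiseuille gland flow, Fickian wall
  transfer, sweat-rate dilution `1/(1 + K_w/g · u_sg,n)`), solved by an
  implicit method of lines with a compiled tridiagonal stepper;
* its **impulse response** `h(t)` and the reduction to the three-parameter
  **local density random walk (LDRW)** indicator-dilution model

  `C(t) = A e^λ sqrt(λ / 2πμt) · exp(−(λ/2)(t/μ + μ/t))`

  (area `A` = transfer gain, transit-time scale `μ`, skewness `λ` = Pe/2),
  identified by an exact multiple-linear-regression linearisation in the log
  domain (`y = ln C + ½ ln t` regressed on `{1, t, 1/t}`);
* a **double-loop inverse estimator**: alternating bounded updates of the
  blood glucose unknowns (one damped Gauss–Newton step, regularised by the
  Morozov discrepancy principle) and of the LDRW parameters (one bounded
  quasi-Newton iteration), from a 5.5 mmol L⁻¹ initial guess until the
  normalised mean-square sweat error drops below 0.001;
* **evaluation metrics** (RMSE, MAE, RMSPE, Pearson R, R², RMSD, AICc) and
  the two **Monte-Carlo parameter sensitivity analyses** (output CV under
  per-parameter Gaussian perturbation; CVs of refitted LDRW parameters under
  transport-parameter perturbation);
* a **synthetic data generator** reproducing the marginal structure of seven
  published paired sweat/blood experiments, so the whole pipeline is
  testable without external data.

Concentrations are stored in mol m⁻³ (numerically identical to mmol L⁻¹;
1 µmol L⁻¹ = 10⁻³ mol m⁻³), times in seconds.

## Worked example

Characterise the transport system, generate a synthetic meal experiment
(15 samples, blood 5.6 ± 0.9 mmol L⁻¹, sweat ≈ 97 µmol L⁻¹, 5% measurement
noise), and invert it:

```r
library(sweat2blood)

params <- biophysical_params()          # literature values
h      <- impulse_response(params, sim_grid())
h
#> <impulse_response> gain = 0.00106, peak 1.34e-06 s^-1 at t = 23.75 s, t_end = 3600 s

theta0 <- fit_mlr_log(h$times, h$values)$params
theta0
#> <ldrw_params> A = 0.00114439, mu = 234.738 s, lambda = 0.445306

pd  <- generate_paired(builtin_experiments(seed = 7)$exp1, "ldrw")
res <- estimate_blood(pd$sweat_obs,
                      inverse_options(pd$generator_trace$theta_effective))
res
#> <estimation_result> n = 15 points, cycles = 0, converged = TRUE, final error = 0.000903
#> <ldrw_params> A = 0.017925, mu = 219.478 s, lambda = 0.471759

regression_metrics(res$blood_est$values, pd$blood_true$values)
#> <metrics_bundle> n = 15
#>   RMSE  = 0.3331 mmol/L   MAE = 0.2426 mmol/L   RMSPE = 6.63%
#>   R     = 0.9247          R^2 = 0.8532
```

Reading the output: the transport gain says 5.5 mmol L⁻¹ of blood glucose
sustains ~6 µmol L⁻¹ of passively stimulated sweat glucose; the fitted
`μ ≈ 235 s` is the transit-time scale of the sweat response, and the small
`λ` marks a strongly diffusion-shaped (skewed) response. The estimator
stops via the 0.001 error rule and reconstructs the meal excursion to
within ~0.33 mmol L⁻¹ RMSE on 5%-noise data; on noise-free data the
recovery is exact to a few percent (see `tests/testthat/test-acceptance.R`).

The same pipeline from the shell:

```sh
sweat2blood synth --exp exp1 --seed 7 --out-blood blood.csv --out-sweat sweat.csv
sweat2blood impulse --out h.csv
sweat2blood fit-ldrw --curve h.csv --out theta.yaml
sweat2blood estimate --sweat sweat.csv --theta theta.yaml --out est.csv
```

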