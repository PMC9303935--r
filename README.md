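# barkermh

Robust gradient-based MCMC with the **Barker proposal**, for statisticians
and computational scientists who need samplers that stay efficient while
their tuning parameters are still being learned — the situation every
adaptive MCMC run starts in, and the regime where the standard
gradient-based schemes are at their most fragile.

## The method

Metropolis–Hastings with a skew-symmetric, gradient-informed candidate.
Per coordinate, draw an increment and choose only its **sign** using the
gradient, through the logistic (Barker) weight:

    y_i = x_i + b_i z_i,   z_i ~ N(0, sigma_i^2),
    P(b_i = +1) = 1 / (1 + exp(-z_i * d_i log pi(x)))

The proposal density is `q(x -> y) ∝ 2 mu_sigma(z) / (1 + exp(-z' grad))`,
the Hastings correction is closed-form, and one iteration costs one fresh
log-density-plus-gradient evaluation, like MALA.  Because the gradient
enters only through a bounded probability, the spectral gap degrades
*linearly* in the scale mismatch `lambda` of a badly tuned direction —
same as random-walk Metropolis — where MALA's and HMC's gaps collapse
*exponentially*.  The same boundedness keeps the chain geometrically
ergodic under very light tails (e.g. `pi ∝ exp(-x^4)`), where MALA's
unbounded drift is rejected almost surely.  At the same time the scheme
is first-order *locally balanced* (balancing function `g(t) = t/(1+t)`,
satisfying `g(t) = t g(1/t)`), which makes the per-coordinate log
acceptance rate `O(sigma^3)` and gives MALA-like `d^(-1/3)` scaling with
dimension rather than the random walk's `d^(-1)`.

The package provides:

* `mh_step` / `run_chain` — Barker, RWM, MALA, fixed-length HMC and the
  global-flip Barker variant, with exact forward/reverse densities;
* `balancing_function`, `lb_density`, `lb_normalizer`, `lb_sample_1d`,
  `scaling_slope` — the generic locally balanced family `Q^(g)` and its
  acceptance-scaling analysis;
* `run_adaptive_chain`, `adapt_update` — Robbins–Monro adaptation of a
  global scale and diagonal pre-conditioner (`gamma_t = t^-0.6`, target
  rates 0.23 / 0.57 / 0.40 for RWM / MALA / Barker);
* `esjd`, `ess`, `dt_metric`, `tau_adapt`, `mse_first_moments`,
  `optimal_sigma` — performance diagnostics;
* `discretize_mh_kernel`, `spectral_gap`, `gap_scaling_curve`,
  `tv_distance_curve`, `prop5_check` — brute-force spectral oracles for
  the robustness claims;
* a target library (`make_iid_target`, `scale_target`,
  `make_scenario_target`, `generate_poisson_data`, `poisson_posterior`)
  covering iid product families, heterogeneous 100-dimensional
  benchmark scenarios, and a Bayesian Poisson random-effects posterior
  (51 parameters, 250 observations);
* experiment runners (`run_esjd_sweep`, `run_dim_scaling`,
  `run_scenario_experiment`, `run_poisson_bench`, `run_gap_sweep`) and a
  CLI front end in `inst/cli/barker_experiments.R`.

## Worked example

Adaptive Barker on the hardest simple heterogeneous target — a
100-dimensional Gaussian whose first coordinate has standard deviation
0.01 while all others have 1:

```r
library(barkermh)
target <- make_scenario_target(1)
run <- run_adaptive_chain(target, "barker", iters = 5000,
                          true_var = target$true_var_diag, seed = 1)
mean(run$accept_probs[2000:5000])   # 0.399
tau_adapt(run$dt)                   # 468
effective_scales(run$adapt)[1:3]    # 0.0065 0.7114 0.7458
run$dt[5000]                        # 0.305
```

The realized acceptance rate sits on the 0.40 target; the tuning
distance `d_t` (root-mean-square log-error of the learned variances)
crosses 1 after 468 iterations — the published value for this scenario,
averaged over ten runs, is 524, against roughly 10,800 for adaptive MALA
— and the learned per-coordinate proposal scales separate the 0.01
coordinate from the rest by two orders of magnitude.

Fixed-tuning comparison on an easy iid Gaussian (`d = 10`), showing why
Barker rather than RWM when well-tuned MALA is not an option:

```r
run_esjd_sweep(make_iid_target("gaussian", 10),
               sigma_grid = c(0.5, 1, 2), iters = 10000, seed = 2)
#>   sampler sigma  esjd
#> 1     rwm   0.5 1.015
#> 2     rwm   1.0 1.091
#> 3     rwm   2.0 0.142
#> 4    mala   0.5 2.538
#> 5    mala   1.0 8.444
#> 6    mala   2.0 0.376
#> 7  barker   0.5 2.215
#> 8  barker   1.0 4.905
#> 9  barker   2.0 2.142
```

MALA wins at its optimum (ESJD 8.4 vs 4.9) but loses a factor 22 when
the step doubles; Barker loses a factor 2.3.

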