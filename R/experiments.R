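# Configuration-driven experiment runners: ESJD step-size sweeps,
# dimension-scaling efficiency comparisons, adaptive runs on the
# heterogeneous scenarios, the Poisson random-effects benchmark, and
# spectral-gap sweeps.  Every runner is a pure function of its
# configuration (including seeds) and emits plain data frames.

# per-repetition seeds derived reproducibly from a base seed; without a
# base seed the draws come from the ambient RNG stream
derive_seeds <- function(base_seed, n) {
  with_seed(base_seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Parse a flat key=value run-configuration file
#'
#' One `key = value` pair per line; blank lines and lines starting with
#' `#` are ignored.  Values are converted to numeric where possible and
#' comma-separated values become vectors.
#'
#' @param path file path.
#' @return a named list.
#' @export
parse_run_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (any(is.na(num))) parts else num
  }
  out
}

#' ESJD step-size sweep
#'
#' Estimates the Rao-Blackwellised expected squared jump distance of each
#' sampler over a log-spaced grid of step sizes (default 0.01 to 100)
#' from stationary-start chains.
#'
#' @param target a `barker_target` with an exact sampler.
#' @param samplers character vector of sampler kinds.
#' @param sigma_grid step sizes; default 31 log-spaced points in
#'   `[0.01, 100]`.
#' @param iters Monte Carlo samples per grid point (default `1e4`).
#' @param seed base RNG seed.
#' @return data frame with columns `sampler`, `sigma`, `esjd`.
#' @export
run_esjd_sweep <- function(target, samplers = c("rwm", "mala", "barker"),
                           sigma_grid = NULL, iters = 10000L,
                           seed = NULL) {
  if (is.null(sigma_grid))
    sigma_grid <- exp(seq(log(0.01), log(100), length.out = 31L))
  seeds <- derive_seeds(seed, length(samplers) * length(sigma_grid))
  k <- 0L
  rows <- list()
  for (samp in samplers) {
    for (s in sigma_grid) {
      k <- k + 1L
      run <- run_chain(target, samp, s, iters, seed = seeds[k])
      rows[[k]] <- data.frame(sampler = samp, sigma = s, esjd = esjd(run))
    }
  }
  do.call(rbind, rows)
}

#' Optimally tuned ESJD across dimensions
#'
#' For each dimension, grid-searches the ESJD-maximizing step size per
#' sampler on an iid product target and records the optimum; used for
#' efficiency-ratio comparisons (e.g. MALA versus Barker) across
#' dimensions.
#'
#' @param kind_target `"gaussian"` or `"hyperbolic"`.
#' @param dims dimensions to sweep.
#' @param samplers sampler kinds.
#' @param iters iterations per grid point.
#' @param n_sigma grid points per dimension; the grid is centred on the
#'   `d^(-1/6)` optimal-scaling profile and spans about 1.5 decades.
#' @param seed base RNG seed.
#' @return data frame with columns `sampler`, `dim`, `sigma_opt`,
#'   `esjd`, `esjd_per_coord`, `at_endpoint`.
#' @export
run_dim_scaling <- function(kind_target = c("gaussian", "hyperbolic"),
                            dims = c(5L, 10L, 20L, 50L, 100L),
                            samplers = c("mala", "barker"),
                            iters = 10000L, n_sigma = 15L, seed = NULL) {
  kind_target <- match.arg(kind_target)
  seeds <- derive_seeds(seed, length(dims) * length(samplers))
  k <- 0L
  rows <- list()
  for (d in dims) {
    target <- make_iid_target(kind_target, d)
    grid <- exp(seq(log(0.3), log(5), length.out = n_sigma)) * d^(-1 / 6)
    for (samp in samplers) {
      k <- k + 1L
      opt <- optimal_sigma(target, samp, grid, iters, seed = seeds[k])
      rows[[k]] <- data.frame(sampler = samp, dim = d,
                              sigma_opt = opt$sigma_opt,
                              esjd = opt$esjd_opt,
                              esjd_per_coord = opt$esjd_opt / d,
                              at_endpoint = opt$at_endpoint)
    }
  }
  do.call(rbind, rows)
}

#' Adaptive-tuning experiment on a heterogeneous scenario
#'
#' Runs `reps` independent adaptive chains per sampler on one of the four
#' heterogeneous benchmark targets, averages the tuning distance `d_t`
#' across runs, and reports the adaptation time `tau_adapt(epsilon)` and
#' the burn-in MSE of standardized first moments at the requested
#' checkpoints.
#'
#' @param scenario scenario id 1-4.
#' @param samplers sampler kinds.
#' @param iters iterations per chain.
#' @param reps independent repetitions.
#' @param seed base RNG seed.
#' @param scale_seed seed for the scenario's random scales.
#' @param dim target dimension (default 100).
#' @param kappa learning-rate exponent.
#' @param epsilon adaptation-time threshold (default 1).
#' @param checkpoints iteration counts at which the MSE is reported
#'   (those exceeding `iters` are dropped).
#' @return list with `table` (one row per sampler: `tau_adapt` and one
#'   `mse_<t>` column per checkpoint), `dt` (iters x samplers matrix of
#'   across-run average tuning distances), and `protocol` (a record of
#'   `iters`/`reps` so reduced-scale runs are explicitly labelled).
#' @export
run_scenario_experiment <- function(scenario,
                                    samplers = c("rwm", "mala", "barker"),
                                    iters = 40000L, reps = 10L,
                                    seed = NULL, scale_seed = 1L,
                                    dim = 100L, kappa = 0.6,
                                    epsilon = 1,
                                    checkpoints = c(10000L, 20000L,
                                                    40000L)) {
  if (!scenario %in% 1:4) stop("invalid scenario: ", scenario)
  target <- make_scenario_target(scenario, dim = dim,
                                 scale_seed = scale_seed)
  checkpoints <- checkpoints[checkpoints <= iters]
  seeds <- matrix(derive_seeds(seed, reps * length(samplers)),
                  nrow = reps)
  dt_avg <- matrix(0, iters, length(samplers),
                   dimnames = list(NULL, samplers))
  rows <- list()
  for (si in seq_along(samplers)) {
    samp <- samplers[si]
    dt_sum <- numeric(iters)
    mse_sum <- numeric(length(checkpoints))
    for (r in seq_len(reps)) {
      run <- run_adaptive_chain(target, samp, iters, kappa = kappa,
                                true_var = target$true_var_diag,
                                seed = seeds[r, si])
      dt_sum <- dt_sum + run$dt
      mse_sum <- mse_sum + vapply(checkpoints, function(tt)
        mse_first_moments(run$chain, target, tt), numeric(1))
    }
    dt_avg[, si] <- dt_sum / reps
    mse <- mse_sum / reps
    row <- data.frame(sampler = samp,
                      tau_adapt = format(tau_adapt(dt_avg[, si],
                                                   epsilon)),
                      stringsAsFactors = FALSE)
    for (ci in seq_along(checkpoints))
      row[[sprintf("mse_%d", checkpoints[ci])]] <- mse[ci]
    rows[[si]] <- row
  }
  list(table = do.call(rbind, rows), dt = dt_avg,
       protocol = list(scenario = scenario, iters = iters, reps = reps,
                       dim = dim, kappa = kappa, seed = seed,
                       scale_seed = scale_seed))
}

poisson_scenario_params <- function(scenario) {
  switch(scenario,
         `1` = list(mu_star = 5, sigma_eta = 1),
         `2` = list(mu_star = 5, sigma_eta = 3),
         `3` = list(mu_star = 10, sigma_eta = 3),
         stop("invalid scenario: ", scenario))
}

#' Poisson random-effects posterior benchmark
#'
#' Generates count data from the hierarchical Poisson model (scenario 1:
#' `mu* = 5, sigma_eta = 1`; scenario 2: `mu* = 5, sigma_eta = 3`;
#' scenario 3: `mu* = 10, sigma_eta = 3`), runs adaptive chains
#' initialized from the model prior, discards the first half as burn-in,
#' and reports per-sampler minimum and median effective sample size
#' across the `I + 1` parameters, the gradient-call count, and the
#' minimum ESS per 100 gradient evaluations, averaged over repetitions.
#'
#' @param scenario data-generating scenario (1, 2 or 3).
#' @param samplers sampler kinds.
#' @param iters iterations per chain (default `5e4`).
#' @param reps independent sampler repetitions on the same dataset.
#' @param seed base RNG seed (also seeds the data draw).
#' @param I,n groups and observations per group.
#' @param kappa learning-rate exponent.
#' @return list with `table` (per sampler: `ess_min`, `ess_median`,
#'   `grad_calls`, `min_ess_per_100grad`, `sd_min_ess_per_100grad`),
#'   `data`, and `protocol`.
#' @export
run_poisson_bench <- function(scenario,
                              samplers = c("rwm", "mala", "barker"),
                              iters = 50000L, reps = 10L, seed = NULL,
                              I = 50L, n = 5L, kappa = 0.6) {
  pars <- poisson_scenario_params(as.character(scenario))
  all_seeds <- derive_seeds(seed, reps * length(samplers) + 1L)
  data <- generate_poisson_data(I, n, pars$mu_star, pars$sigma_eta,
                                seed = all_seeds[1L])
  target <- poisson_posterior(data)
  seeds <- matrix(all_seeds[-1L], nrow = reps)
  rows <- list()
  for (si in seq_along(samplers)) {
    samp <- samplers[si]
    ess_min <- ess_med <- eff <- numeric(reps)
    grad_calls <- numeric(reps)
    for (r in seq_len(reps)) {
      run <- with_seed(seeds[r, si], {
        init <- poisson_prior_draw(data)
        run_adaptive_chain(target, samp, iters, kappa = kappa,
                           init = init)
      })
      keep <- run$chain[(floor(iters / 2) + 1L):iters, , drop = FALSE]
      ess_all <- apply(keep, 2L, ess)
      ess_min[r] <- min(ess_all)
      ess_med[r] <- stats::median(ess_all)
      grad_calls[r] <- run$n_evals
      eff[r] <- 100 * ess_min[r] / grad_calls[r]
    }
    rows[[si]] <- data.frame(sampler = samp,
                             ess_min = mean(ess_min),
                             ess_median = mean(ess_med),
                             grad_calls = mean(grad_calls),
                             min_ess_per_100grad = mean(eff),
                             sd_min_ess_per_100grad = stats::sd(eff))
  }
  list(table = do.call(rbind, rows), data = data,
       protocol = list(scenario = scenario, iters = iters, reps = reps,
                       I = I, n = n, kappa = kappa, seed = seed))
}

#' Spectral-gap lambda sweep for several samplers
#'
#' Convenience wrapper around [gap_scaling_curve()] producing one tidy
#' table.
#'
#' @param samplers sampler kinds.
#' @param base_target 1-d `barker_target` (default standard Gaussian).
#' @param lam_grid lambda grid.
#' @param sigma named (or recycled) proposal scales at `lambda = 1`; the
#'   default uses 2.4 for the random-walk and Barker samplers and 1.2 for
#'   MALA, near each sampler's well-tuned regime on the unit Gaussian.
#' @param m grid points.
#' @return data frame with columns `sampler`, `lambda`, `gap`,
#'   `flagged`, `slope`.
#' @export
run_gap_sweep <- function(samplers = c("rwm", "mala", "barker"),
                          base_target = make_iid_target("gaussian", 1L),
                          lam_grid = 2^-(0:6), sigma = NULL, m = 400L) {
  if (is.null(sigma))
    sigma <- ifelse(samplers == "mala", 1.2, 2.4)
  sigma <- rep_len(sigma, length(samplers))
  rows <- lapply(seq_along(samplers), function(si) {
    samp <- samplers[si]
    res <- gap_scaling_curve(samp, base_target, lam_grid, sigma[si],
                             m = m)
    cbind(data.frame(sampler = samp, sigma = sigma[si]), res$curve,
          data.frame(slope = res$slope))
  })
  do.call(rbind, rows)
}

#' Write a result table with a metadata header block
#'
#' Emits `# key: value` comment lines followed by a tab-separated table,
#' so outputs are self-describing and reduced-scale protocols are always
#' labelled.
#'
#' @param table a data frame.
#' @param path output file.
#' @param meta named list of metadata values.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(table, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k,
                       paste(format(meta[[k]]), collapse = ",")), con)
  utils::write.table(table, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
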