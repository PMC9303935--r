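# Performance and convergence diagnostics: Rao-Blackwellised expected
# squared jump distance, autoregressive-spectral effective sample size,
# the tuning-distance metric d_t and its first-passage time, burn-in MSE
# of first-moment estimators, and step-size grid search.

#' Rao-Blackwellised expected squared jump distance
#'
#' `mean_t [ accept_prob_t * || Y_t - X_{t-1} ||^2 ]`, averaging the
#' acceptance probability rather than the accept indicator.
#'
#' @param run a `run_record` from [run_chain()].
#' @param per_coord divide by the dimension (for ESJD-per-coordinate
#'   curves).
#' @return scalar ESJD estimate.
#' @export
esjd <- function(run, per_coord = FALSE) {
  stopifnot(length(run$accept_probs) >= 2L)
  v <- mean(run$accept_probs * run$jump_sq)
  if (per_coord) v / ncol(run$chain) else v
}

# spectral density at frequency zero via an AR fit with AIC-chosen order;
# the construction used by the standard MCMC reference implementation
spectrum0_ar <- function(x) {
  x <- as.numeric(x)
  z <- seq_along(x)
  lm_out <- stats::lm(x ~ z)
  if (isTRUE(all.equal(stats::sd(stats::residuals(lm_out)), 0)))
    return(list(spec = 0, order = 0L))
  ar_out <- stats::ar(x, aic = TRUE)
  list(spec = ar_out$var.pred / (1 - sum(ar_out$ar))^2,
       order = ar_out$order)
}

#' Effective sample size
#'
#' `T * var(x) / S(0)`, with the spectral density at frequency zero
#' estimated from an autoregressive model whose order is chosen by AIC.
#' A constant series has ESS 0 (with a warning).
#'
#' @param series numeric vector (length >= 10).
#' @return scalar effective sample size.
#' @export
ess <- function(series) {
  stopifnot(length(series) >= 10L)
  s0 <- spectrum0_ar(series)$spec
  if (s0 == 0) {
    warning("zero-variance series; ESS defined as 0")
    return(0)
  }
  length(series) * stats::var(series) / s0
}

#' Tuning distance between adapted and true diagonal covariances
#'
#' `d_t = mean over runs of sqrt( (1/d) sum_i (log Sigma_t,ii -
#' log Sigma_ii)^2 )`; the expectation over the chain law is approximated
#' by the across-run average.
#'
#' @param var_diag adapted variances: a vector (one run) or a
#'   runs-by-d matrix.
#' @param true_var length-d vector of true variances.
#' @return scalar tuning distance.
#' @export
dt_metric <- function(var_diag, true_var) {
  if (is.null(dim(var_diag))) var_diag <- matrix(var_diag, nrow = 1L)
  if (any(var_diag <= 0) || any(true_var <= 0))
    stop("variances must be positive")
  lt <- log(true_var)
  mean(apply(var_diag, 1L, function(v) sqrt(mean((log(v) - lt)^2))))
}

#' First-passage adaptation time
#'
#' First index `t` with `d_t <= epsilon`; if the threshold is never
#' reached within the series, the sentinel string `">T"` is returned (as
#' printed in run summaries).
#'
#' @param d_series numeric vector of tuning distances per iteration.
#' @param epsilon threshold (> 0; default 1).
#' @return integer index, or the character sentinel `">T"`.
#' @export
tau_adapt <- function(d_series, epsilon = 1) {
  if (!length(d_series)) stop("empty d_t series")
  stopifnot(epsilon > 0)
  hit <- which(d_series <= epsilon)
  if (!length(hit)) paste0(">", length(d_series)) else hit[1L]
}

#' Average MSE of standardized first-moment estimators
#'
#' For the test functions `h_i(x) = x_i / eta_i`, estimates each
#' `E_pi[h_i]` from iterations `floor(t/2) + 1 .. t` of every run and
#' returns the squared error averaged across coordinates and runs.
#'
#' @param chains a list of T-by-d chain matrices (one per run), or a
#'   single matrix.
#' @param target a `barker_target` providing `true_mean` and `eta`.
#' @param t number of iterations to use (>= 2; burn-in is `floor(t/2)`).
#' @return scalar MSE.
#' @export
mse_first_moments <- function(chains, target, t) {
  if (is.matrix(chains)) chains <- list(chains)
  if (is.null(target$true_mean))
    stop("target does not provide true means")
  stopifnot(t >= 2)
  eta <- if (is.null(target$eta)) rep(1, target$dim) else target$eta
  truth <- target$true_mean / eta
  burn <- floor(t / 2)
  errs <- vapply(chains, function(ch) {
    stopifnot(nrow(ch) >= t)
    hhat <- colMeans(ch[(burn + 1L):t, , drop = FALSE]) / eta
    mean((hhat - truth)^2)
  }, numeric(1))
  mean(errs)
}

#' Grid search for the ESJD-optimal step size
#'
#' Runs one stationary-start chain per grid point and returns the step
#' size maximizing the Rao-Blackwellised ESJD together with the full
#' `(sigma, esjd)` curve.  An optimum at a grid endpoint is flagged.
#'
#' @param target a `barker_target` with an exact sampler (stationary
#'   starts).
#' @param kind sampler kind.
#' @param sigma_grid positive step sizes (log-spaced recommended).
#' @param iters iterations per grid point.
#' @param seed optional RNG seed.
#' @param L leapfrog steps for HMC.
#' @return list with `sigma_opt`, `esjd_opt`, `curve` (data frame), and
#'   `at_endpoint`.
#' @export
optimal_sigma <- function(target, kind, sigma_grid, iters = 10000L,
                          seed = NULL, L = 1L) {
  with_seed(seed, {
    vals <- vapply(sigma_grid, function(s)
      esjd(run_chain(target, kind, s, iters, L = L)), numeric(1))
    i <- which.max(vals)
    list(sigma_opt = sigma_grid[i],
         esjd_opt = vals[i],
         curve = data.frame(sigma = sigma_grid, esjd = vals),
         at_endpoint = i %in% c(1L, length(sigma_grid)))
  })
}
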