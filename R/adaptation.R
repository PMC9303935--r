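# Robbins-Monro adaptive tuning of the global proposal scale and a
# diagonal pre-conditioner.  At iteration t, with learning rate
# gamma_t = t^-kappa:
#   log sigma_t = log sigma_{t-1} + gamma_t (alpha(X_t, Y_t) - alpha*)
#   mu_t        = mu_{t-1} + gamma_t (X_t - mu_{t-1})
#   Sigma_t,ii  = Sigma_{t-1},ii + gamma_t ((X_t,i - mu_t-1,i)^2 -
#                 Sigma_{t-1},ii)
# The acceptance innovation is the Rao-Blackwellised acceptance
# probability, not the accept/reject indicator.  All three recursions read
# the time-(t-1) state (a simultaneous Robbins-Monro update): feeding the
# already-updated mean into the variance innovation would make the first
# update degenerate (gamma_1 = 1 forces mu_1 = X_1 and hence Sigma_1 = 0
# exactly), stalling the chain against the variance floor for thousands of
# iterations.  Off-diagonal covariance terms are constrained to zero.

#' Robbins-Monro learning rate
#'
#' `gamma_t = t^-kappa`.  Values `kappa` in (0.5, 1) make the adaptation
#' diminishing yet non-summable; boundary values are admitted with a
#' warning.
#'
#' @param t iteration index (>= 1).
#' @param kappa exponent.
#' @return scalar learning rate.
#' @export
learning_rate <- function(t, kappa) {
  if (any(t < 1)) stop("t must be >= 1")
  if (kappa <= 0.5 || kappa >= 1)
    warning("kappa outside (0.5, 1); adaptation guarantees weaken")
  t^(-kappa)
}

#' Initial adaptation state
#'
#' Starts from `Sigma_0 = I`, `mu_0 = 0`, `t = 0`.
#'
#' @param d dimension.
#' @param sigma0 initial global scale (see [initial_scales()]).
#' @param kappa learning-rate exponent (default 0.6).
#' @param target_rate ideal acceptance rate `alpha*` (see
#'   [target_rate()]).
#' @param var_floor lower bound applied to the adapted variances (default
#'   `1e-12`); prevents collapse when a chain stalls early.
#' @return an object of class `adapt_state`.
#' @export
adapt_state <- function(d, sigma0, kappa = 0.6, target_rate = 0.4,
                        var_floor = 1e-12) {
  stopifnot(sigma0 > 0, var_floor > 0)
  structure(list(t = 0L, log_sigma = log(sigma0),
                 mean = rep(0, d), var_diag = rep(1, d),
                 kappa = kappa, target_rate = target_rate,
                 var_floor = var_floor),
            class = "adapt_state")
}

#' One adaptation update
#'
#' Applies the three Robbins-Monro recursions (scale, mean, variance) with
#' the learning rate of the incremented iteration counter; every
#' innovation is formed from the time-(t-1) state.
#'
#' @param astate an `adapt_state`.
#' @param x_t current chain position.
#' @param accept_prob Rao-Blackwellised acceptance probability of the
#'   iteration, in `[0, 1]`.
#' @return the updated `adapt_state`.
#' @export
adapt_update <- function(astate, x_t, accept_prob) {
  stopifnot(accept_prob >= 0, accept_prob <= 1)
  t <- astate$t + 1L
  gamma <- t^(-astate$kappa)
  astate$t <- t
  astate$log_sigma <- astate$log_sigma +
    gamma * (accept_prob - astate$target_rate)
  mu_prev <- astate$mean
  astate$mean <- mu_prev + gamma * (x_t - mu_prev)
  astate$var_diag <- pmax(
    astate$var_diag + gamma * ((x_t - mu_prev)^2 - astate$var_diag),
    astate$var_floor)
  astate
}

#' Optimal-scaling initial global scale
#'
#' `sigma_0^2 = 2.4^2 / d` for random-walk Metropolis and
#' `sigma_0^2 = 2.4^2 / d^{1/3}` for MALA; the Barker and Hamiltonian
#' schemes use the MALA value.
#'
#' @param kind sampler kind.
#' @param d dimension.
#' @return the initial scale `sigma_0` (note: the *scale*, not its
#'   square).
#' @export
initial_scales <- function(kind = c("rwm", "mala", "barker", "hmc"), d) {
  kind <- match.arg(kind)
  stopifnot(d >= 1)
  if (kind == "rwm") sqrt(2.4^2 / d) else sqrt(2.4^2 / d^(1 / 3))
}

#' Ideal acceptance rates for adaptive tuning
#'
#' 0.23 for random-walk Metropolis, 0.57 for MALA, 0.40 for Barker.
#'
#' @param kind sampler kind.
#' @return scalar target acceptance rate.
#' @export
target_rate <- function(kind = c("rwm", "mala", "barker")) {
  kind <- match.arg(kind)
  switch(kind, rwm = 0.23, mala = 0.57, barker = 0.40)
}

#' Effective per-coordinate proposal scales of an adaptation state
#'
#' `exp(log sigma_t) * sqrt(Sigma_t,ii)`, with the variance floor applied.
#'
#' @param astate an `adapt_state`.
#' @return numeric vector of per-coordinate scales.
#' @export
effective_scales <- function(astate) {
  exp(astate$log_sigma) * sqrt(pmax(astate$var_diag, astate$var_floor))
}

#' Run an adaptive Metropolis-Hastings chain
#'
#' Interleaves [mh_step()] with [adapt_update()]: the proposal at
#' iteration t uses the global scale and diagonal pre-conditioner adapted
#' through iteration t - 1.
#'
#' @param target a `barker_target`.
#' @param kind sampler kind (`"barker"`, `"rwm"`, `"mala"`).
#' @param iters number of iterations.
#' @param kappa learning-rate exponent (default 0.6).
#' @param alpha_star ideal acceptance rate; default [target_rate()] of
#'   `kind`.
#' @param sigma0 initial global scale; default [initial_scales()] of
#'   `kind`.
#' @param init initial position; default iid `N(0, 10^2)` coordinates.
#' @param true_var optional vector of true per-coordinate variances; when
#'   given, the tuning distance `d_t` (root-mean-square log-discrepancy
#'   between the adapted and true variances) is recorded per iteration.
#' @param seed optional RNG seed.
#' @param var_floor variance floor.
#' @param adapt_thin record `(t, sigma_t, Sigma_t,ii)` every `adapt_thin`
#'   iterations (0 = never).
#' @return list with `chain`, `accept_probs`, `sigma_trace` (sigma_t per
#'   iteration), `dt` (when `true_var` given), `adapt` (final
#'   `adapt_state`), `adapt_trace` (optional thinned data frame),
#'   `n_evals`, `seed`.
#' @export
run_adaptive_chain <- function(target, kind, iters, kappa = 0.6,
                               alpha_star = NULL, sigma0 = NULL,
                               init = NULL, true_var = NULL, seed = NULL,
                               var_floor = 1e-12, adapt_thin = 0L) {
  with_seed(seed, {
    d <- target$dim
    if (is.null(alpha_star)) alpha_star <- target_rate(kind)
    if (is.null(sigma0)) sigma0 <- initial_scales(kind, d)
    if (is.null(init)) init <- stats::rnorm(d, 0, 10)
    astate <- adapt_state(d, sigma0, kappa, alpha_star, var_floor)
    state <- chain_state(target, init)
    chain <- matrix(NA_real_, iters, d)
    accept_probs <- numeric(iters)
    sigma_trace <- numeric(iters)
    dt <- if (!is.null(true_var)) numeric(iters) else NULL
    log_true <- if (!is.null(true_var)) log(true_var) else NULL
    trace_rows <- list()
    n_evals <- 0L
    for (t in seq_len(iters)) {
      scales <- proposal_scales(exp(astate$log_sigma),
                                sqrt(pmax(astate$var_diag,
                                          astate$var_floor)))
      step <- mh_step(state, target, kind, scales)
      state <- step$state
      astate <- adapt_update(astate, state$x, step$accept_prob)
      chain[t, ] <- state$x
      accept_probs[t] <- step$accept_prob
      sigma_trace[t] <- exp(astate$log_sigma)
      n_evals <- n_evals + step$n_evals
      if (!is.null(dt))
        dt[t] <- sqrt(mean((log(astate$var_diag) - log_true)^2))
      if (adapt_thin > 0L && t %% adapt_thin == 0L)
        trace_rows[[length(trace_rows) + 1L]] <-
          c(t, exp(astate$log_sigma), astate$var_diag)
    }
    adapt_trace <- NULL
    if (length(trace_rows)) {
      adapt_trace <- as.data.frame(do.call(rbind, trace_rows))
      names(adapt_trace) <- c("t", "sigma", paste0("var", seq_len(d)))
    }
    list(chain = chain, accept_probs = accept_probs,
         sigma_trace = sigma_trace, dt = dt, adapt = astate,
         adapt_trace = adapt_trace, n_evals = n_evals, seed = seed)
  })
}
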