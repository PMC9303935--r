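# Shared test oracles, independent of the package internals.

# central finite-difference gradient
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

expect_grad_matches <- function(target, points, rtol = 1e-5,
                                atol = 1e-8) {
  for (x in points) {
    g_an <- target$grad_log_density(x)
    g_fd <- fd_grad(target$log_density, x)
    expect_lt(max(abs(g_an - g_fd) / pmax(abs(g_fd), atol / rtol)), rtol)
  }
}

# numeric CDF of a 1-d density given as a vectorized function, for
# one-sample Kolmogorov-Smirnov checks
numeric_cdf <- function(dens, lower, upper, n = 8192L) {
  x <- seq(lower, upper, length.out = n)
  f <- dens(x)
  dx <- diff(x)
  cdf <- c(0, cumsum(dx * (f[-1] + f[-n]) / 2))
  cdf <- cdf / cdf[n]
  stats::approxfun(x, cdf, yleft = 0, yright = 1)
}

# brute-force spectral gap: minimize the Dirichlet form over centred
# unit-variance functions by multi-start BFGS on the unconstrained
# Rayleigh quotient
dirichlet_gap_oracle <- function(P, pi_w, n_starts = 20L) {
  n <- length(pi_w)
  rayleigh <- function(v) {
    f <- v - sum(pi_w * v)
    vr <- sum(pi_w * f^2)
    if (vr < 1e-14) return(1e6)
    num <- 0.5 * sum(pi_w * (outer(f, f, "-")^2 * t(P)))
    # outer(f,f,"-")[i,j] = f[i]-f[j]; weight pi_i P_ij
    num <- 0.5 * sum((pi_w * P) * outer(f, f, function(a, b) (b - a)^2))
    num / vr
  }
  best <- Inf
  for (s in seq_len(n_starts)) {
    v0 <- stats::rnorm(n)
    opt <- stats::optim(v0, rayleigh, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, opt$value)
  }
  best
}

# MH kernel on a small finite state space from target weights and a
# proposal matrix (rows normalized), for oracle tests
finite_mh_kernel <- function(pi_w, Q) {
  n <- length(pi_w)
  A <- pmin(1, outer(1 / pi_w, pi_w) * t(Q) / Q)
  P <- Q * A
  diag(P) <- 0
  diag(P) <- 1 - rowSums(P)
  list(P = P, pi_weights = pi_w)
}
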