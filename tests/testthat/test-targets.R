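# Target library: analytic gradients, scale family, heterogeneous
# scenarios, and the Poisson random-effects model.

test_that("analytic gradients match finite differences on every target", {
  set.seed(101)
  targets <- list(
    make_iid_target("gaussian", 3),
    make_iid_target("hyperbolic", 2),
    make_iid_target("exp_power", 2, beta = 4),
    scale_target(make_iid_target("gaussian", 3), 0.25, 2),
    make_scenario_target(1, dim = 12),
    make_scenario_target(2, dim = 12, scale_seed = 7),
    make_scenario_target(3, dim = 12, scale_seed = 7),
    make_scenario_target(4, dim = 12, scale_seed = 7))
  for (tg in targets) {
    pts <- lapply(1:5, function(i) rnorm(tg$dim))
    expect_grad_matches(tg, pts)
    expect_true(is.finite(tg$log_density(rep(0, tg$dim))))
    if (!is.null(tg$true_mean))
      expect_true(is.finite(tg$log_density(tg$true_mean)))
  }
})

test_that("iid targets have the documented score functions", {
  g1 <- make_iid_target("gaussian", 1)
  expect_equal(g1$grad_log_density(2), -2)
  h1 <- make_iid_target("hyperbolic", 1)
  expect_equal(h1$grad_log_density(0), 0)
  expect_equal(h1$grad_log_density(3), -3 / sqrt(9.1))
  expect_error(make_iid_target("gaussian", 0), "positive integer")
  expect_error(make_iid_target("exp_power", 2, beta = -1), "positive")
})

test_that("iid target variances agree with quadrature and samplers", {
  for (kind in c("gaussian", "hyperbolic", "exp_power")) {
    tg <- make_iid_target(kind, 1)
    mom <- local({
      f <- function(x) vapply(x, tg$log_density, numeric(1))
      z <- integrate(function(x) exp(f(x)), -Inf, Inf)$value
      m <- integrate(function(x) x * exp(f(x)), -Inf, Inf)$value / z
      v <- integrate(function(x) (x - m)^2 * exp(f(x)), -Inf,
                     Inf)$value / z
      c(m, v)
    })
    expect_lt(abs(mom[1] - tg$true_mean), 1e-3)
    expect_lt(abs(mom[2] - tg$true_var_diag) / tg$true_var_diag, 1e-3)
    set.seed(5)
    draws <- target_sample(tg, 40000)
    expect_lt(abs(var(drop(draws)) - tg$true_var_diag) /
                tg$true_var_diag, 0.05)
  }
})

test_that("scale family: identity, composition, and mass preservation", {
  base <- make_iid_target("gaussian", 3)
  set.seed(42)
  pts <- lapply(1:20, function(i) rnorm(3))
  s1 <- scale_target(base, 1, 2)
  for (x in pts) expect_equal(s1$log_density(x), base$log_density(x))

  s2 <- scale_target(base, 2, 1)
  expect_equal(s2$true_var_diag, c(4, 1, 1))
  comp <- scale_target(scale_target(base, 2, 1), 3, 1)
  direct <- scale_target(base, 6, 1)
  for (x in pts)
    expect_equal(comp$log_density(x), direct$log_density(x))

  # Jacobian factor keeps the integral invariant (1-d quadrature)
  b1 <- make_iid_target("gaussian", 1)
  sh <- scale_target(b1, 0.5, 1)
  mass <- integrate(function(x)
    vapply(x, function(xx) exp(sh$log_density(xx)), numeric(1)),
    -10, 10)$value
  expect_equal(mass, sqrt(2 * pi), tolerance = 1e-8)

  expect_error(scale_target(base, -1, 1), "positive")
  expect_error(scale_target(base, 1, 5), "k must")
})

test_that("scenario targets expose correct scales and variances", {
  s1 <- make_scenario_target(1, dim = 10)
  expect_equal(s1$true_var_diag[1], 1e-4)
  expect_equal(s1$true_var_diag[2], 1)

  # same scale_seed reproduces the same target instance
  a <- make_scenario_target(2, dim = 10, scale_seed = 3)
  b <- make_scenario_target(2, dim = 10, scale_seed = 3)
  expect_identical(a$eta, b$eta)

  s3 <- make_scenario_target(3, dim = 4, scale_seed = 3)
  expect_equal(s3$grad_log_density(rep(0, 4)), rep(0, 4))

  # skew-normal closed-form variance vs 1-d quadrature (eta=1, alpha=4)
  delta <- 4 / sqrt(17)
  lf <- function(x) -x^2 / 2 + pnorm(4 * x, log.p = TRUE)
  z <- integrate(function(x) exp(lf(x)), -Inf, Inf)$value
  m <- integrate(function(x) x * exp(lf(x)), -Inf, Inf)$value / z
  v <- integrate(function(x) (x - m)^2 * exp(lf(x)), -Inf, Inf)$value / z
  expect_equal(v, 1 - 2 * delta^2 / pi, tolerance = 1e-7)
  expect_equal(m, delta * sqrt(2 / pi), tolerance = 1e-7)

  s4 <- make_scenario_target(4, dim = 6, scale_seed = 3)
  expect_equal(s4$true_var_diag, s4$eta^2 * (1 - 2 * delta^2 / pi))
  set.seed(8)
  draws <- target_sample(s4, 20000)
  expect_lt(max(abs(colMeans(draws) - s4$true_mean) / s4$eta), 0.03)

  # skew-normal gradient stays finite far in the left tail
  g <- s4$grad_log_density(rep(-40, 6) * s4$eta)
  expect_true(all(is.finite(g)))

  expect_error(make_scenario_target(7), "unknown scenario")
})

test_that("poisson data generator respects the model and seeds", {
  d <- generate_poisson_data(50, 5, 5, 1, seed = 31)
  expect_equal(dim(d$y), c(50, 5))
  expect_true(all(d$y >= 0) && all(d$y == round(d$y)))
  expect_equal(poisson_posterior(d)$dim, 51)

  d2 <- generate_poisson_data(50, 5, 5, 1, seed = 31)
  expect_identical(d$y, d2$y)

  d0 <- generate_poisson_data(8, 3, 2, 0, seed = 1)
  expect_equal(d0$eta_star, rep(2, 8))

  # mean count approx exp(mu*) within 3 standard errors; counts are
  # Poisson-lognormal so the variance has both components
  big <- generate_poisson_data(200, 5, 5, 0.1, seed = 7)
  lam <- exp(5 + 0.1^2 / 2)
  v <- lam + (exp(0.1^2) - 1) * exp(2 * 5 + 0.1^2)
  se <- sqrt(v / length(big$y))
  expect_lt(abs(mean(big$y) - lam), 3 * se)

  expect_error(generate_poisson_data(5, 2, 800, 0, seed = 1),
               "integer count range")
})

test_that("poisson posterior gradient and mode are consistent", {
  set.seed(77)
  d <- generate_poisson_data(5, 3, 2, 0.7, seed = 19)
  post <- poisson_posterior(d)
  pts <- lapply(1:10, function(i) c(rnorm(1, 0, 2), rnorm(5, 2, 0.5)))
  expect_grad_matches(post, pts)

  opt <- optim(c(0, d$eta_star), function(x) -post$log_density(x),
               function(x) -post$grad_log_density(x), method = "BFGS",
               control = list(maxit = 500, reltol = 1e-15))
  expect_lt(sqrt(sum(post$grad_log_density(opt$par)^2)), 1e-6)

  # single group, all-zero counts, diffuse prior: d/d eta at 0 -> -n
  d1 <- generate_poisson_data(1, 4, 0, 1, seed = 2)
  d1$y[] <- 0
  d1$sigma_eta <- 1e8
  g <- poisson_posterior(d1)$grad_log_density(c(0, 0))
  expect_equal(g[2], -4, tolerance = 1e-6)
})

test_that("poisson data round-trips through delimited text", {
  d <- generate_poisson_data(7, 4, 3, 1.5, seed = 23)
  path <- tempfile(fileext = ".tsv")
  write_poisson_data(d, path)
  d2 <- read_poisson_data(path)
  expect_equal(d2$y, d$y, ignore_attr = TRUE)
  expect_equal(d2$eta_star, d$eta_star)
  expect_equal(d2$mu_star, d$mu_star)
  expect_equal(d2$sigma_eta, d$sigma_eta)
  expect_equal(d2$I, d$I)
  expect_equal(d2$n, d$n)
})
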