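# Proposal mechanisms and the Metropolis-Hastings step.

test_that("barker flip probability is the stable logistic", {
  expect_equal(barker_flip_prob(1, 0), 0.5)
  expect_equal(barker_flip_prob(0, 10), 0.5)
  expect_equal(barker_flip_prob(1, log(3)), 0.75)
  expect_equal(barker_flip_prob(1e6, 1e6), 1)
  expect_equal(barker_flip_prob(-1e6, 1e6), 0)
  expect_true(all(is.finite(barker_flip_prob(c(-1e8, 0, 1e8), 500))))
})

test_that("barker proposal density: identities and normalization", {
  sc <- proposal_scales(1.3)
  set.seed(21)
  # q(x -> x+z) + q(x -> x-z) = 2 mu_sigma(z) for any gradient
  for (i in 1:20) {
    z <- rnorm(1, 0, 2); g <- rnorm(1, 0, 20); x <- rnorm(1)
    lhs <- exp(barker_log_density(x, g, x + z, sc)) +
      exp(barker_log_density(x, g, x - z, sc))
    expect_equal(lhs, 2 * dnorm(z, 0, 1.3), tolerance = 1e-12)
  }
  # zero gradient reduces to the symmetric kernel
  expect_equal(barker_log_density(0.5, 0, 1.7, sc),
               dnorm(1.2, 0, 1.3, log = TRUE))
  # integrates to one
  mass <- integrate(function(y) vapply(y, function(yy)
    exp(barker_log_density(0, 3, yy, proposal_scales(1))), numeric(1)),
    -Inf, Inf)$value
  expect_equal(mass, 1, tolerance = 1e-9)
})

test_that("barker MH log-ratio is antisymmetric and matches densities", {
  tg <- make_iid_target("hyperbolic", 3)
  sc <- proposal_scales(0.8, c(1, 2, 0.5))
  set.seed(33)
  for (i in 1:10) {
    sx <- chain_state(tg, rnorm(3))
    sy <- chain_state(tg, rnorm(3))
    r_xy <- mh_log_ratio_barker(sx, sy, sc)
    expect_equal(r_xy, -mh_log_ratio_barker(sy, sx, sc),
                 tolerance = 1e-12)
    oracle <- sy$logpi +
      barker_log_density(sy$x, sy$grad, sx$x, sc) -
      sx$logpi -
      barker_log_density(sx$x, sx$grad, sy$x, sc)
    expect_equal(r_xy, oracle, tolerance = 1e-10)
  }
  sx <- chain_state(tg, c(1, 2, 3))
  expect_equal(mh_log_ratio_barker(sx, sx, sc), 0)
})

test_that("barker draws follow the skew-symmetric law", {
  tg <- new_target(1, function(x) 10 * x, function(x) 10,
                   label = "log-linear")
  st <- chain_state(tg, 0)
  sc <- proposal_scales(1)
  set.seed(91)
  n <- 50000
  draws <- vapply(seq_len(n), function(i) barker_propose(st, sc),
                  numeric(1))
  cdf <- numeric_cdf(function(z) 2 * dnorm(z) * plogis(10 * z), -6, 6)
  ks <- suppressWarnings(ks.test(draws, cdf))
  expect_gt(ks$p.value, 0.01)

  # zero gradient: the displacement law is the noise kernel
  tg0 <- new_target(1, function(x) 0, function(x) 0, label = "flat")
  st0 <- chain_state(tg0, 0)
  draws0 <- vapply(seq_len(n), function(i) barker_propose(st0, sc),
                   numeric(1))
  expect_gt(suppressWarnings(ks.test(draws0, pnorm))$p.value, 0.01)
})

test_that("strong gradients truncate the barker proposal", {
  tg <- new_target(2, function(x) sum(c(50, -50) * x),
                   function(x) c(50, -50), label = "steep")
  st <- chain_state(tg, c(0, 0))
  set.seed(14)
  pat <- replicate(4000, {
    y <- barker_propose(st, proposal_scales(1))
    y[1] > 0 && y[2] < 0
  })
  expect_gt(mean(pat), 0.95)
})

test_that("MALA proposal has the documented drift and closed-form ratio", {
  tg <- make_iid_target("gaussian", 2)
  st <- chain_state(tg, c(1.5, -0.5))
  s <- 0.7
  set.seed(3)
  drift <- rowMeans(replicate(40000,
    mala_propose(st, proposal_scales(s))$y - st$x))
  expect_lt(max(abs(drift - s^2 * st$grad / 2)),
            3 * s / sqrt(40000) + 1e-3)

  # with zero gradient MALA consumes the same normals as RWM
  tg0 <- new_target(2, function(x) 0, function(x) c(0, 0))
  st0 <- chain_state(tg0, c(0, 0))
  set.seed(8); y_mala <- mala_propose(st0, proposal_scales(s))$y
  set.seed(8); y_rwm <- rwm_propose(st0, proposal_scales(s))
  expect_identical(y_mala, y_rwm)

  # closed-form Gaussian transition densities on the 1-d standard normal
  t1 <- make_iid_target("gaussian", 1)
  set.seed(19)
  for (i in 1:10) {
    x <- rnorm(1); y <- rnorm(1)
    sx <- chain_state(t1, x); sy <- chain_state(t1, y)
    hand <- (x^2 - y^2) / 2 +
      dnorm(x, y - s^2 * y / 2, s, log = TRUE) -
      dnorm(y, x - s^2 * x / 2, s, log = TRUE)
    step_ratio <- sy$logpi - sx$logpi +
      sum(dnorm(sx$x, sy$x + s^2 * sy$grad / 2, s, log = TRUE)) -
      sum(dnorm(sy$x, sx$x + s^2 * sx$grad / 2, s, log = TRUE))
    expect_equal(step_ratio, hand, tolerance = 1e-10)
  }
})

test_that("HMC: L = 1 coincides with MALA, flat targets free-fly, energy
           error vanishes at second order or faster", {
  tg <- make_iid_target("gaussian", 3)
  st <- chain_state(tg, c(0.3, -1, 2))
  s <- 0.4
  set.seed(12); tr <- barkermh:::hmc_trajectory(st, tg,
                                                proposal_scales(s), 1L)
  set.seed(12); y_mala <- mala_propose(st, proposal_scales(s))$y
  expect_equal(tr$state$x, y_mala, tolerance = 1e-12)

  flat <- new_target(2, function(x) 0, function(x) c(0, 0))
  stf <- chain_state(flat, c(1, 1))
  set.seed(4)
  trf <- barkermh:::hmc_trajectory(stf, flat, proposal_scales(0.3), 5L)
  set.seed(4); xi0 <- rnorm(2)
  expect_equal(trf$state$x, c(1, 1) + 5 * 0.3 * xi0, tolerance = 1e-12)
  expect_equal(trf$accept_prob, 1)

  t1 <- make_iid_target("gaussian", 1)
  sig <- c(0.2, 0.1, 0.05, 0.025)
  err <- vapply(sig, function(ss) {
    set.seed(90)
    mean(abs(vapply(1:200, function(i) {
      st <- chain_state(t1, rnorm(1))
      barkermh:::hmc_trajectory(st, t1, proposal_scales(ss),
                                10L)$log_mh_ratio
    }, numeric(1))))
  }, numeric(1))
  slope <- unname(coef(lm(log(err) ~ log(sig)))[2])
  expect_gt(slope, 1.8)
  expect_lt(slope, 3.5)
})

test_that("global flip coincides with barker in one dimension", {
  tg <- make_iid_target("gaussian", 1)
  st <- chain_state(tg, 1.2)
  sc <- proposal_scales(0.9)
  set.seed(6); y1 <- global_flip_propose(st, sc)
  set.seed(6); y2 <- barker_propose(st, sc)
  expect_equal(y1, y2)
})

test_that("mh_step honours the acceptance contract", {
  flat <- new_target(2, function(x) 0, function(x) c(0, 0))
  st <- chain_state(flat, c(0, 0))
  sc <- proposal_scales(1)
  set.seed(2)
  for (i in 1:5)
    expect_equal(mh_step(st, flat, "rwm", sc)$accept_prob, 1)

  # a proposal landing outside the support is rejected with prob 0
  box <- new_target(1, function(x) if (abs(x) > 1) -Inf else 0,
                    function(x) 0)
  stb <- chain_state(box, 0.5)
  set.seed(10)
  out <- replicate(50, {
    s <- mh_step(stb, box, "rwm", proposal_scales(50))
    c(s$accept_prob, s$state$x)
  })
  rejected <- out[1, ] == 0
  expect_true(any(rejected))
  expect_true(all(out[2, rejected] == 0.5))

  # rejection leaves the cached state untouched
  tg <- make_iid_target("gaussian", 2)
  stg <- chain_state(tg, c(0.2, 0.1))
  set.seed(11)
  repeat {
    s <- mh_step(stg, tg, "mala", proposal_scales(8))
    if (!s$accepted) break
  }
  expect_identical(s$state$x, stg$x)
  expect_identical(s$state$logpi, stg$logpi)
  expect_identical(s$state$grad, stg$grad)
})

test_that("detailed balance holds at machine precision for all
           density-based kernels", {
  tg <- make_iid_target("hyperbolic", 2)
  set.seed(55)
  s <- c(0.7, 1.4)
  for (i in 1:8) {
    x <- rnorm(2); y <- rnorm(2)
    sx <- chain_state(tg, x); sy <- chain_state(tg, y)
    dl <- sy$logpi - sx$logpi
    ratios <- c(
      rwm = dl,
      mala = dl +
        barkermh:::mala_log_density(y, sy$grad, x, s) -
        barkermh:::mala_log_density(x, sx$grad, y, s),
      barker = mh_log_ratio_barker(sx, sy),
      global_flip = dl +
        barkermh:::global_flip_log_density(y, sy$grad, x, s) -
        barkermh:::global_flip_log_density(x, sx$grad, y, s))
    rev <- c(
      rwm = -dl,
      mala = -dl +
        barkermh:::mala_log_density(x, sx$grad, y, s) -
        barkermh:::mala_log_density(y, sy$grad, x, s),
      barker = mh_log_ratio_barker(sy, sx),
      global_flip = -dl +
        barkermh:::global_flip_log_density(x, sx$grad, y, s) -
        barkermh:::global_flip_log_density(y, sy$grad, x, s))
    expect_equal(ratios, -rev, tolerance = 1e-12)
  }
})

test_that("long chains preserve the target law (moment checks)", {
  t_g <- make_iid_target("gaussian", 1)
  for (kind in c("barker", "rwm", "mala", "global_flip")) {
    r <- run_chain(t_g, kind, 1.6, 100000, seed = 300 + match(kind,
      c("barker", "rwm", "mala", "global_flip")))
    x <- drop(r$chain)
    expect_lt(abs(mean(x)), 0.05)
    expect_lt(abs(var(x) - 1), 0.07)
    expect_lt(abs(mean(x^3)), 0.15)
    expect_lt(abs(mean(x^4) - 3), 0.35)
  }
  t_h <- make_iid_target("hyperbolic", 1)
  v <- t_h$true_var_diag
  for (kind in c("barker", "mala")) {
    r <- run_chain(t_h, kind, 1.6, 100000, seed = 42)
    x <- drop(r$chain)
    expect_lt(abs(mean(x)), 0.08)
    expect_lt(abs(var(x) - v) / v, 0.08)
  }
})

test_that("light-tail stability: barker keeps accepting where MALA
           collapses", {
  ep <- make_iid_target("exp_power", 1, beta = 4)
  rb <- run_chain(ep, "barker", 0.5, 2000, init = 10, seed = 3)
  rm_ <- run_chain(ep, "mala", 0.5, 2000, init = 10, seed = 3)
  expect_gt(mean(rb$accept_probs), 0.1)
  expect_lt(mean(rm_$accept_probs), 0.01)
})

test_that("run_chain is reproducible and accounts evaluations", {
  tg <- make_iid_target("gaussian", 3)
  a <- run_chain(tg, "barker", 0.8, 200, seed = 77)
  b <- run_chain(tg, "barker", 0.8, 200, seed = 77)
  expect_identical(a$chain, b$chain)
  expect_identical(a$accept_probs, b$accept_probs)
  expect_equal(a$n_evals, 200)
  h <- run_chain(tg, "hmc", 0.3, 50, L = 4, seed = 1)
  expect_equal(h$n_evals, 200)
})
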