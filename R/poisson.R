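# Bayesian Poisson random-effects model: synthetic data generator, the
# induced posterior as a target density, and plain-text round-trip.
#
# Model: y_ij | eta_i ~ Poisson(exp(eta_i)), j = 1..n_i,
#        eta_i | mu   ~ N(mu, sigma_eta^2),  i = 1..I,
#        mu           ~ N(0, 10^2),
# with sigma_eta treated as known.  The posterior over (mu, eta_1..eta_I)
# has light tails and potentially very large gradients when the counts are
# large, which is the stress case for gradient-based samplers.

#' Generate synthetic data from the Poisson random-effects model
#'
#' Group effects are drawn as `eta_i* ~ N(mu_star, sigma_eta^2)` and counts
#' as `y_ij ~ Poisson(exp(eta_i*))`, `j = 1..n` within each of `I` groups.
#'
#' @param I number of groups.
#' @param n observations per group.
#' @param mu_star data-generating mean of the group effects.
#' @param sigma_eta data-generating (and model) standard deviation of the
#'   group effects; `>= 0`.
#' @param seed optional RNG seed for reproducibility.
#' @return an object of class `poisson_re_data`: list with `y` (I x n
#'   numeric matrix of counts), `I`, `n`, `mu_star`, `sigma_eta`,
#'   `eta_star`, `seed`.
#' @export
generate_poisson_data <- function(I, n, mu_star, sigma_eta, seed = NULL) {
  stopifnot(I >= 1, n >= 1, sigma_eta >= 0)
  draw <- function() {
    eta_star <- stats::rnorm(I, mu_star, sigma_eta)
    lambda <- exp(eta_star)
    if (any(!is.finite(lambda)) || any(lambda > 2^31 - 1))
      stop("exp(eta) exceeds the integer count range; ",
           "reduce mu_star or sigma_eta")
    y <- matrix(stats::rpois(I * n, rep(lambda, n)), nrow = I, ncol = n)
    list(eta_star = eta_star, y = y)
  }
  d <- with_seed(seed, draw())
  structure(list(y = d$y, I = as.integer(I), n = as.integer(n),
                 mu_star = mu_star, sigma_eta = sigma_eta,
                 eta_star = d$eta_star, seed = seed),
            class = "poisson_re_data")
}

#' @export
print.poisson_re_data <- function(x, ...) {
  cat(sprintf(
    "<poisson_re_data> I=%d groups, n=%d obs/group, mu*=%g, sigma_eta=%g\n",
    x$I, x$n, x$mu_star, x$sigma_eta))
  invisible(x)
}

#' Posterior of the Poisson random-effects model as a target density
#'
#' The parameter vector is `(mu, eta_1, ..., eta_I)` (dimension `I + 1`).
#' Up to constants,
#' `log pi = sum_i [S_i eta_i - n exp(eta_i)] - sum_i (eta_i - mu)^2 /
#' (2 sigma_eta^2) - mu^2 / 200`, with `S_i = sum_j y_ij`, and the gradient
#' is analytic.
#'
#' @param data a `poisson_re_data` object.
#' @return a `barker_target` of dimension `I + 1`.
#' @export
poisson_posterior <- function(data) {
  stopifnot(inherits(data, "poisson_re_data"))
  I <- data$I; n <- data$n
  S <- rowSums(data$y)
  sig2 <- data$sigma_eta^2
  new_target(
    I + 1L,
    function(x) {
      mu <- x[1L]; eta <- x[-1L]
      sum(S * eta) - n * sum(exp(eta)) -
        sum((eta - mu)^2) / (2 * sig2) - mu^2 / 200
    },
    function(x) {
      mu <- x[1L]; eta <- x[-1L]
      dev <- (eta - mu) / sig2
      c(sum(dev) - mu / 100, S - n * exp(eta) - dev)
    },
    label = sprintf("poisson random-effects posterior (I=%d, n=%d)", I, n))
}

#' Draw an initial chain state from the model prior
#'
#' `mu ~ N(0, 10^2)`, then `eta_i ~ N(mu, sigma_eta^2)`; the standard
#' initialization for posterior sampling runs on this model.
#'
#' @param data a `poisson_re_data` object.
#' @return numeric vector `(mu, eta_1, ..., eta_I)`.
#' @export
poisson_prior_draw <- function(data) {
  mu <- stats::rnorm(1, 0, 10)
  c(mu, stats::rnorm(data$I, mu, data$sigma_eta))
}

#' Write / read Poisson count data as delimited text
#'
#' The file holds one row per group (tab-separated counts) preceded by
#' header comment lines recording `I`, `n`, `mu_star`, `sigma_eta`, `seed`
#' and the data-generating group effects, so a dataset round-trips exactly.
#'
#' @param data a `poisson_re_data` object.
#' @param path file path.
#' @return `write_poisson_data` returns `path` invisibly;
#'   `read_poisson_data` returns a `poisson_re_data`.
#' @export
write_poisson_data <- function(data, path) {
  stopifnot(inherits(data, "poisson_re_data"))
  hdr <- c(
    sprintf("# I=%d", data$I),
    sprintf("# n=%d", data$n),
    sprintf("# mu_star=%.17g", data$mu_star),
    sprintf("# sigma_eta=%.17g", data$sigma_eta),
    sprintf("# seed=%s", if (is.null(data$seed)) "NA" else
      format(data$seed)),
    paste0("# eta_star=",
           paste(sprintf("%.17g", data$eta_star), collapse = "\t")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(data$y, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_poisson_data
#' @export
read_poisson_data <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s=", key), "",
                           grep(sprintf("^# %s=", key), hdr, value = TRUE))
  y <- as.matrix(utils::read.table(text = grep("^#", lines, value = TRUE,
                                               invert = TRUE), sep = "\t"))
  dimnames(y) <- NULL
  seed <- get("seed")
  structure(list(y = y,
                 I = as.integer(get("I")),
                 n = as.integer(get("n")),
                 mu_star = as.numeric(get("mu_star")),
                 sigma_eta = as.numeric(get("sigma_eta")),
                 eta_star = as.numeric(strsplit(get("eta_star"),
                                                "\t")[[1]]),
                 seed = if (identical(seed, "NA")) NULL
                        else as.integer(seed)),
            class = "poisson_re_data")
}
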