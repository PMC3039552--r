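# independently coded sum-over-edges log posterior, kept deliberately naive
naive_log_posterior_bym <- function(state, data, graph, priors) {
  lp <- 0
  for (i in seq_len(graph$n_areas)) {
    lam <- data$e[i] * exp(state$alpha + state$u[i] + state$v[i])
    lp <- lp + data$y[i] * log(lam) - lam - lgamma(data$y[i] + 1)
  }
  s <- 0
  for (i in seq_len(graph$n_areas)) {
    for (j in graph$neighbours[[i]]) {
      if (j > i) s <- s + (state$u[i] - state$u[j])^2
    }
  }
  ncomp <- graph_components(graph)
  lp <- lp + 0.5 * (graph$n_areas - ncomp) *
    (log(state$tau_u) - log(2 * pi)) - 0.5 * state$tau_u * s
  for (i in seq_len(graph$n_areas)) {
    lp <- lp + dnorm(state$v[i], 0, 1 / sqrt(state$tau_v), log = TRUE)
  }
  lp <- lp + dnorm(state$alpha, 0, sqrt(priors$coef_variance), log = TRUE)
  lp + dgamma(state$tau_u, priors$tau_u$shape, priors$tau_u$rate, log = TRUE) +
    dgamma(state$tau_v, priors$tau_v$shape, priors$tau_v$rate, log = TRUE)
}

rand_state <- function(n, seed) {
  set.seed(seed)
  u <- rnorm(n)
  u <- u - mean(u)
  list(alpha = rnorm(1), u = u, v = rnorm(n),
       tau_u = rexp(1) + 0.5, tau_v = rexp(1) + 0.5)
}

test_that("log posterior matches an independent sum-over-edges oracle", {
  pri <- incidence_prior("prior3")
  for (seed in 1:5) {
    g <- path_graph(3)
    dat <- tibble::tibble(area_id = g$area_ids, y = c(2, 5, 9), e = c(4, 5, 6))
    st <- rand_state(3, seed)
    expect_equal(log_posterior_bym(st, dat, g, pri),
                 naive_log_posterior_bym(st, dat, g, pri), tolerance = 1e-10)
  }
  # two disconnected pairs: the ICAR quadratic splits into the two edges
  g4 <- area_graph(letters[1:4], neighbours = list(2L, 1L, 4L, 3L))
  dat4 <- tibble::tibble(area_id = letters[1:4], y = c(3, 1, 4, 2), e = rep(2, 4))
  st4 <- rand_state(4, 99)
  expect_equal(log_posterior_bym(st4, dat4, g4, pri),
               naive_log_posterior_bym(st4, dat4, g4, pri), tolerance = 1e-10)
})

test_that("log posterior at the null state reduces to the bare Poisson term", {
  g <- path_graph(3)
  dat <- tibble::tibble(area_id = g$area_ids, y = c(2, 5, 9), e = c(4, 5, 6))
  pri <- incidence_prior("prior3")
  st <- list(alpha = 0, u = rep(0, 3), v = rep(0, 3), tau_u = 1, tau_v = 1)
  pois <- sum(dat$y * log(dat$e) - dat$e - lgamma(dat$y + 1))
  non_lik <- 0.5 * 2 * (0 - log(2 * pi)) +          # ICAR at u = 0, tau = 1
    3 * dnorm(0, 0, 1, log = TRUE) +                # v terms
    dnorm(0, 0, sqrt(1e10), log = TRUE) +           # intercept prior
    dgamma(1, 0.1, 0.1, log = TRUE) + dgamma(1, 0.001, 0.001, log = TRUE)
  expect_equal(log_posterior_bym(st, dat, g, pri), pois + non_lik,
               tolerance = 1e-10)
})

test_that("states violating the sum-to-zero constraint are rejected", {
  g <- path_graph(3)
  dat <- tibble::tibble(area_id = g$area_ids, y = c(2, 5, 9), e = c(4, 5, 6))
  st <- list(alpha = 0, u = c(0.5, 0.5, 0.5), v = rep(0, 3),
             tau_u = 1, tau_v = 1)
  expect_error(log_posterior_bym(st, dat, g, incidence_prior()), "sum-to-zero")
})

test_that("fitting is deterministic given the seed and validates inputs", {
  g <- path_graph(3)
  dat <- tibble::tibble(area_id = g$area_ids, y = c(2, 5, 9), e = c(4, 5, 6))
  ctl <- mcmc_control(200, 200, 2, seed = 42)
  f1 <- fit_bym(dat, g, control = ctl)
  f2 <- fit_bym(dat, g, control = ctl)
  expect_identical(f1$draws, f2$draws)
  expect_equal(nrow(f1$theta), 100)
  expect_error(fit_bym(dplyr::mutate(dat, e = c(0, 5, 6)), g), "positive")
  expect_error(mcmc_control(-1, 100, 10), "burn_in")
  iso <- area_graph(c("x", "y", "z"), neighbours = list(2L, 1L, integer()))
  dat2 <- tibble::tibble(area_id = c("x", "y", "z"), y = 1:3, e = rep(2, 3))
  expect_error(fit_bym(dat2, iso), "isolated")
})

test_that("draws stored under sum-to-zero keep all SIR chains positive", {
  g <- lattice_graph(3, 3)
  dat <- tibble::tibble(area_id = g$area_ids, y = rpois(9, 20), e = rep(20, 9))
  fit <- fit_bym(dat, g, control = mcmc_control(500, 500, 5, seed = 3))
  expect_true(all(abs(rowSums(fit$draws$u)) < 1e-8))
  expect_true(all(fit$theta > 0))
  expect_true(all(fit$draws$tau_u > 0 & fit$draws$tau_v > 0))
})

test_that("uniform-on-sigma priors keep sigma inside its bounds", {
  g <- lattice_graph(3, 3)
  set.seed(1)
  dat <- tibble::tibble(area_id = g$area_ids, y = rpois(9, 20), e = rep(20, 9))
  fit <- fit_bym(dat, g, priors = incidence_prior("prior5"),
                 control = mcmc_control(500, 500, 5, seed = 3))
  expect_true(all(1 / sqrt(fit$draws$tau_u) < 1))
  expect_true(all(1 / sqrt(fit$draws$tau_v) < 1))
})

test_that("credible-interval summaries match closed-form order statistics", {
  g <- path_graph(2)
  chain <- cbind(seq_len(10000) / 1000, rep(1.3, 10000))
  fit <- fake_bym_fit(chain, g)
  s <- summarize_sir(fit)
  # type-7 order statistics of 1..10000 (scaled): h = (n-1)p + 1
  expect_equal(s$median[1], 5000.5 / 1000)
  expect_equal(s$lo95[1], 250.975 / 1000)
  expect_equal(s$hi95[1], 9750.025 / 1000)
  # constant chain collapses to a zero-width interval
  expect_equal(s$median[2], 1.3)
  expect_equal(s$lo95[2], 1.3)
  expect_equal(s$hi95[2], 1.3)
  # display scaling
  s100 <- summarize_sir(fit, scale = 100)
  expect_equal(s100$median[2], 130)
})

test_that("fit statistics behave at degenerate inputs", {
  g <- path_graph(3)
  # point-mass draws: pD = 0 and DIC equals that state's deviance
  th <- matrix(rep(c(1.2, 0.8, 1.0), each = 5), nrow = 5)
  fit <- fake_bym_fit(th, g, e = c(4, 5, 6), y = c(2, 5, 9))
  fit$draws$alpha <- rep(0, 5)
  fit$draws$u <- matrix(log(c(1.2, 0.8, 1.0)), 5, 3, byrow = TRUE)
  fit$draws$u <- fit$draws$u - rowMeans(fit$draws$u)
  fit$draws$alpha <- rep(mean(log(c(1.2, 0.8, 1.0))), 5)
  fit$draws$v <- matrix(0, 5, 3)
  st <- model_fit_stats(fit)
  dev <- -2 * sum(dpois(c(2, 5, 9), c(4, 5, 6) * c(1.2, 0.8, 1.0), log = TRUE))
  expect_equal(st$pD, 0, tolerance = 1e-8)
  expect_equal(st$DIC, dev, tolerance = 1e-8)
  # flat fit with u identically zero: no spatial share, ratio90 exactly 1
  flat <- fake_bym_fit(matrix(1, 5, 3), g)
  flat_st <- model_fit_stats(flat)
  expect_equal(flat_st$spatial_fraction, 0)
  expect_equal(flat_st$ratio90, 1)
})

test_that("small-count areas are shrunk toward their neighbours", {
  # centre area has a tiny expected count and an extreme raw ratio; its
  # smoothed estimate must land between the raw ratio and the overall level
  g <- lattice_graph(3, 3)
  e <- rep(50, 9)
  e[5] <- 0.5
  y <- c(48, 52, 47, 55, 3, 51, 49, 53, 50)  # raw ratio 6 at the centre
  dat <- tibble::tibble(area_id = g$area_ids, y = y, e = e)
  fit <- fit_bym(dat, g, control = mcmc_control(3000, 3000, 3, seed = 8))
  med <- summarize_sir(fit)$median
  raw <- y[5] / e[5]
  expect_lt(med[5], raw)
  expect_gt(med[5], min(y[-5] / e[-5]))
  expect_lt(abs(med[5] - 1), abs(raw - 1))
})
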