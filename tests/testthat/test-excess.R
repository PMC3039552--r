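toy_cells <- function() {
  tibble::tibble(
    area_id = c("a", "a", "b", "b"),
    age_band = c("0-59", "60+", "0-59", "60+"),
    fu_year = c(1, 2, 1, 2),
    y = c(10, 8, 12, 6),
    d = c(4, 5, 3, 4),
    dstar = c(0.5, 1.0, 0.6, 0.8))
}

pair_graph <- function() area_graph(c("a", "b"), neighbours = list(2L, 1L))

# deliberately naive cell-by-cell re-implementation
naive_log_posterior_excess <- function(state, cells, graph, priors) {
  bands <- c("0-59", "60+")
  lp <- 0
  for (r in seq_len(nrow(cells))) {
    i <- match(cells$area_id[r], graph$area_ids)
    j <- cells$fu_year[r]
    k <- match(cells$age_band[r], bands)
    mu <- cells$dstar[r] + cells$y[r] *
      exp(state$alpha_j[j] + state$beta_k[k] + state$u[i] + state$v[i])
    lp <- lp + dpois(cells$d[r], mu, log = TRUE)
  }
  s <- (state$u[1] - state$u[2])^2
  lp <- lp + 0.5 * (2 - 1) * (log(state$tau_u) - log(2 * pi)) -
    0.5 * state$tau_u * s
  lp <- lp + sum(dnorm(state$v, 0, 1 / sqrt(state$tau_v), log = TRUE))
  lp <- lp + sum(dnorm(state$alpha_j, 0, sqrt(priors$coef_variance), log = TRUE)) +
    dnorm(state$beta_k[2], 0, sqrt(priors$coef_variance), log = TRUE)
  lp + dgamma(state$tau_u, priors$tau_u$shape, priors$tau_u$rate, log = TRUE) +
    dgamma(state$tau_v, priors$tau_v$shape, priors$tau_v$rate, log = TRUE)
}

test_that("excess-mortality log posterior matches an independent oracle", {
  pri <- survival_prior("prior3")
  g <- pair_graph()
  cells <- toy_cells()
  for (seed in 1:5) {
    set.seed(seed)
    u1 <- rnorm(1)
    st <- list(alpha_j = rnorm(2), beta_k = c(0, rnorm(1)),
               u = c(u1, -u1), v = rnorm(2),
               tau_u = rexp(1) + 0.5, tau_v = rexp(1) + 0.5)
    expect_equal(log_posterior_excess(st, cells, g, pri),
                 naive_log_posterior_excess(st, cells, g, pri),
                 tolerance = 1e-10)
  }
})

test_that("the link keeps every cell mean above its background deaths", {
  g <- pair_graph()
  cells <- toy_cells()
  st <- list(alpha_j = c(0, 0), beta_k = c(0, 0), u = c(0, 0), v = c(0, 0),
             tau_u = 1, tau_v = 1)
  # with a unit excess hazard, mu = dstar + y exactly; check via likelihood
  lp0 <- log_posterior_excess(st, cells, g, survival_prior())
  mu <- cells$dstar + cells$y
  lik0 <- sum(dpois(cells$d, mu, log = TRUE))
  st_inf <- st
  st_inf$alpha_j <- c(-40, -40)  # excess hazard -> 0, mu -> dstar only
  lp_inf <- log_posterior_excess(st_inf, cells, g, survival_prior())
  lik_inf <- sum(dpois(cells$d, cells$dstar, log = TRUE))
  prior_shift <- 2 * (dnorm(0, 0, 1e3, log = TRUE) -
                        dnorm(-40, 0, 1e3, log = TRUE))
  expect_equal(lp0 - lp_inf, lik0 - lik_inf + prior_shift, tolerance = 1e-8)
  bad <- dplyr::mutate(toy_cells(), dstar = c(-0.1, 1, 1, 1))
  expect_error(log_posterior_excess(st, bad, g, survival_prior()), "negative")
  st_bad <- st
  st_bad$beta_k <- c(0.2, 0)
  expect_error(log_posterior_excess(st_bad, cells, g, survival_prior()),
               "reference")
})

test_that("posterior means on a 2-area toy match grid quadrature", {
  # informative tau priors keep the weakly identified toy posterior compact;
  # the comparison is on the posterior means of u_i + v_i
  g <- pair_graph()
  cells <- tibble::tibble(area_id = c("a", "b"), age_band = "0+", fu_year = 1,
                          y = c(50, 60), d = c(20, 30), dstar = c(5, 6))
  pri <- prior_spec(gamma_prior(2, 1), gamma_prior(2, 1), coef_variance = 1e6)
  oracle <- excess_quadrature_mean_w(c(50, 60), c(20, 30), c(5, 6),
                                     cv = 1e6, au = 2, bu = 1, av = 2, bv = 1)
  fit <- fit_excess_mortality(cells, g, priors = pri,
                              control = mcmc_control(20000, 100000, 10,
                                                     seed = 5))
  w <- log(fit$rer)
  pm <- colMeans(w)
  mcse <- apply(w, 2, chain_mcse)
  expect_lt(max(abs(pm - oracle) / mcse), 3)
})

test_that("fitting is deterministic given the seed", {
  g <- pair_graph()
  ctl <- mcmc_control(200, 200, 2, seed = 11)
  f1 <- fit_excess_mortality(toy_cells(), g, control = ctl)
  f2 <- fit_excess_mortality(toy_cells(), g, control = ctl)
  expect_identical(f1$draws, f2$draws)
})

test_that("RER summaries behave at degenerate chains", {
  g <- pair_graph()
  fit <- fit_excess_mortality(toy_cells(), g,
                              control = mcmc_control(100, 100, 1, seed = 1))
  # forge degenerate chains: u + v identically zero gives RER exactly 1
  fit$rer <- exp(matrix(0, 100, 2))
  colnames(fit$rer) <- g$area_ids
  s <- summarize_rer(fit)
  expect_equal(s$median, c(1, 1))
  expect_equal(s$lo95, c(1, 1))
  expect_true(all(s$category == "average"))
})

test_that("adjusted deaths reduce to the expected totals at a null RER", {
  g <- pair_graph()
  cells <- toy_cells()
  params <- list(alpha_j = c(-1, -1.5), beta_k = c(0, 0.4), rer = c(1, 1))
  ad <- adjusted_deaths(params, cells, g)
  expect_identical(ad$adjusted, ad$expected)
  # no person-time: only the background deaths remain
  empty <- dplyr::mutate(cells, y = 0)
  ad0 <- adjusted_deaths(list(alpha_j = c(-1, -1.5), beta_k = c(0, 0.4),
                              rer = c(1.7, 0.6)), empty, g)
  expect_equal(ad0$adjusted, c(1.5, 1.4))
  expect_equal(ad0$expected, c(1.5, 1.4))
})

test_that("adjusted deaths match a by-hand spreadsheet on a 2-cell example", {
  g <- pair_graph()
  cells <- tibble::tibble(area_id = c("a", "b"), age_band = "0-59",
                          fu_year = 1, y = c(10, 20), d = c(2, 3),
                          dstar = c(0.5, 0.7))
  params <- list(alpha_j = -1, beta_k = 0, rer = c(1.5, 0.8))
  ad <- adjusted_deaths(params, cells, g)
  expect_equal(ad$adjusted, c(10 * exp(-1) * 1.5 + 0.5,
                              20 * exp(-1) * 0.8 + 0.7))
  expect_equal(ad$expected, c(10 * exp(-1) + 0.5, 20 * exp(-1) + 0.7))
})

test_that("raising an area's RER raises its adjusted deaths only", {
  g <- pair_graph()
  cells <- toy_cells()
  p1 <- list(alpha_j = c(-1, -1.2), beta_k = c(0, 0.3), rer = c(1, 1))
  p2 <- list(alpha_j = c(-1, -1.2), beta_k = c(0, 0.3), rer = c(1.5, 1))
  a1 <- adjusted_deaths(p1, cells, g)
  a2 <- adjusted_deaths(p2, cells, g)
  expect_gt(a2$adjusted[1], a1$adjusted[1])
  expect_equal(a2$adjusted[2], a1$adjusted[2])
  expect_equal(a2$expected, a1$expected)
})
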