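#' @useDynLib epiatlas, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom generics tidy glance
NULL

# flatten neighbour lists to 0-based CSR arrays for the C++ samplers
.flatten_nb <- function(graph) {
  deg <- lengths(graph$neighbours)
  list(nb = as.integer(unlist(graph$neighbours, use.names = FALSE) - 1L),
       start = as.integer(cumsum(c(0L, deg))))
}

.tau_code <- function(p) {
  if (p$family == "gamma") list(kind = 0L, p1 = p$shape, p2 = p$rate)
  else list(kind = 1L, p1 = p$lower, p2 = p$upper)
}

.log_tau_prior <- function(tau, p) {
  if (p$family == "gamma") {
    stats::dgamma(tau, shape = p$shape, rate = p$rate, log = TRUE)
  } else {
    sigma <- 1 / sqrt(tau)
    if (sigma <= p$lower || sigma >= p$upper) return(-Inf)
    # uniform density on sigma, transformed to the tau scale
    -log(p$upper - p$lower) + log(0.5) - 1.5 * log(tau)
  }
}

#' Log posterior density of the BYM incidence model
#'
#' The model is `y_i ~ Poisson(e_i * theta_i)` with
#' `log(theta_i) = alpha + u_i + v_i`, where `u` carries the intrinsic CAR
#' prior (joint density proportional to
#' `tau_u^((n-c)/2) * exp(-tau_u/2 * sum_{i~j} (u_i - u_j)^2)` on the
#' sum-to-zero subspace, `c` = number of graph components) and
#' `v_i ~ N(0, 1/tau_v)`. Used as the reference density for the sampler and
#' for quadrature cross-checks.
#'
#' @param state List with elements `alpha`, `u`, `v`, `tau_u`, `tau_v`.
#' @param data Data frame with columns `y` (observed counts) and `e`
#'   (expected counts), one row per area in graph order.
#' @param graph An [area_graph()].
#' @param priors A [prior_spec()]; default [incidence_prior()] `"prior3"`.
#' @param sum_tol Tolerance on the sum-to-zero constraint for `u`.
#' @return The log posterior density (a scalar, up to the ICAR normalising
#'   constant which is fixed for a given graph).
#' @export
log_posterior_bym <- function(state, data, graph, priors = incidence_prior(),
                              sum_tol = 1e-6) {
  n <- graph$n_areas
  stopifnot(length(state$u) == n, length(state$v) == n,
            nrow(data) == n, state$tau_u > 0, state$tau_v > 0)
  if (abs(sum(state$u)) > sum_tol * max(1, n)) {
    stop("u violates the sum-to-zero constraint")
  }
  edges <- graph_edges(graph)
  s_u <- if (nrow(edges)) sum((state$u[edges$from] - state$u[edges$to])^2) else 0
  ncomp <- graph_components(graph)
  eta <- state$alpha + state$u + state$v
  ll <- sum(stats::dpois(data$y, data$e * exp(eta), log = TRUE))
  l_icar <- 0.5 * (n - ncomp) * (log(state$tau_u) - log(2 * pi)) -
    0.5 * state$tau_u * s_u
  l_v <- sum(stats::dnorm(state$v, 0, 1 / sqrt(state$tau_v), log = TRUE))
  l_alpha <- stats::dnorm(state$alpha, 0, sqrt(priors$coef_variance), log = TRUE)
  ll + l_icar + l_v + l_alpha +
    .log_tau_prior(state$tau_u, priors$tau_u) +
    .log_tau_prior(state$tau_v, priors$tau_v)
}

#' Fit the BYM model to area counts by MCMC
#'
#' Runs a single Metropolis-within-Gibbs chain: random-walk MH for the
#' intercept and each `u_i`, `v_i` (with `u` re-centred to sum to zero every
#' sweep, the shift absorbed into the intercept), and conjugate Gamma Gibbs
#' updates for the precisions under gamma priors (MH on log sigma under
#' uniform-on-sigma priors). Proposal scales adapt during burn-in only.
#'
#' @param data Data frame with columns `area_id`, `y`, `e`, one row per area;
#'   rows are matched to `graph$area_ids`.
#' @param graph An [area_graph()] with no isolates (see [repair_isolates()]).
#' @param priors A [prior_spec()].
#' @param control An [mcmc_control()]; the whole run is deterministic given
#'   its seed.
#' @return A `bym_fit` object holding the thinned draws of every parameter,
#'   the derived per-area SIR chains `theta = exp(alpha + u + v)`, and the
#'   configuration used. Methods: [tidy()], [glance()], [autoplot()].
#' @export
fit_bym <- function(data, graph, priors = incidence_prior(),
                    control = mcmc_desk_scale()) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("area_id", "y", "e") %in% names(data)))
  data <- data[match(graph$area_ids, data$area_id), ]
  if (anyNA(data$y)) stop("data missing for some graph areas")
  if (any(data$e <= 0)) stop("expected counts must be positive")
  if (any(data$y < 0)) stop("observed counts must be non-negative")
  if (length(isolates(graph))) {
    stop("graph has isolated areas; run repair_isolates() first")
  }
  fl <- .flatten_nb(graph)
  cu <- .tau_code(priors$tau_u)
  cv <- .tau_code(priors$tau_v)
  set.seed(control$seed)
  raw <- bym_mcmc_cpp(as.numeric(data$y), as.numeric(data$e),
                      fl$nb, fl$start, graph_components(graph),
                      cu$kind, cu$p1, cu$p2, cv$kind, cv$p1, cv$p2,
                      priors$coef_variance,
                      control$burn_in, control$kept, control$thin)
  theta <- exp(raw$alpha + raw$u + raw$v)  # column-recycled alpha
  colnames(theta) <- graph$area_ids
  colnames(raw$u) <- colnames(raw$v) <- graph$area_ids
  structure(
    list(draws = raw, theta = theta, data = data, graph = graph,
         priors = priors, control = control,
         n_draws = control$kept %/% control$thin),
    class = c("bym_fit", "atlas_fit"))
}

#' @export
print.bym_fit <- function(x, ...) {
  cat("<bym_fit> ", x$graph$n_areas, " areas, ", x$n_draws,
      " stored draws (burn-in ", x$control$burn_in, ", kept ",
      x$control$kept, ", thin ", x$control$thin, ")\n", sep = "")
  invisible(x)
}

.summarize_ratio_draws <- function(mat, area_ids, scale = 1) {
  qs <- apply(mat, 2, stats::quantile, probs = c(0.5, 0.025, 0.975),
              names = FALSE, type = 7)
  out <- tibble::tibble(
    area_id = area_ids,
    median = unname(qs[1, ]) * scale,
    lo95 = unname(qs[2, ]) * scale,
    hi95 = unname(qs[3, ]) * scale
  )
  out$category <- categorize_for_map(out$median / scale)
  class(out) <- c("smoothed_estimates", class(out))
  out
}

#' Summarise smoothed standardised incidence ratios
#'
#' Per-area posterior median of `theta_i = exp(alpha + u_i + v_i)` with the
#' central 95% credible interval (2.5th and 97.5th percentiles of the stored
#' chain) and the five-class map category. `scale = 100` reproduces the
#' display convention where 100 means the regional average.
#'
#' @param fit A `bym_fit`.
#' @param scale Display multiplier (1 or 100).
#' @return A tibble (`smoothed_estimates`) with columns `area_id`, `median`,
#'   `lo95`, `hi95`, `category`.
#' @export
summarize_sir <- function(fit, scale = 1) {
  stopifnot(inherits(fit, "bym_fit"), fit$n_draws > 0)
  .summarize_ratio_draws(fit$theta, fit$graph$area_ids, scale)
}

#' Model fit statistics for a BYM fit
#'
#' Reports `pD` (effective number of parameters: mean posterior deviance
#' minus deviance at the posterior means of alpha, u, v), `DIC` (mean
#' deviance + pD), the spatial fraction (posterior mean of
#' `sd(u) / (sd(u) + sd(v))` across draws, the share of total random-effect
#' variability carried by the structured component), and the 90% ratio (the
#' 95th over the 5th percentile of the per-area posterior-median SIRs, a
#' spread measure for the smoothed map).
#'
#' @param fit A `bym_fit`.
#' @return A one-row tibble with columns `pD`, `DIC`, `spatial_fraction`,
#'   `ratio90`.
#' @export
model_fit_stats <- function(fit) {
  stopifnot(inherits(fit, "bym_fit"))
  y <- fit$data$y
  e <- fit$data$e
  dev_of <- function(lin) {
    -2 * sum(stats::dpois(y, e * exp(lin), log = TRUE))
  }
  lam <- t(exp(t(log(fit$theta))))  # theta draws
  # mean deviance across draws
  dev_draws <- vapply(seq_len(fit$n_draws), function(t) {
    -2 * sum(stats::dpois(y, e * fit$theta[t, ], log = TRUE))
  }, numeric(1))
  dbar <- mean(dev_draws)
  lin_hat <- mean(fit$draws$alpha) + colMeans(fit$draws$u) + colMeans(fit$draws$v)
  dhat <- dev_of(lin_hat)
  pd <- dbar - dhat
  sd_u <- apply(fit$draws$u, 1, stats::sd)
  sd_v <- apply(fit$draws$v, 1, stats::sd)
  tot <- sd_u + sd_v
  frac <- ifelse(tot > 0, sd_u / tot, 0)
  med <- apply(fit$theta, 2, stats::median)
  q <- stats::quantile(med, c(0.05, 0.95), names = FALSE, type = 7)
  tibble::tibble(pD = pd, DIC = dbar + pd,
                 spatial_fraction = mean(frac),
                 ratio90 = q[2] / q[1])
}

#' @export
tidy.bym_fit <- function(x, scale = 1, ...) summarize_sir(x, scale = scale)

#' @export
glance.bym_fit <- function(x, ...) {
  dplyr::bind_cols(model_fit_stats(x),
                   tibble::tibble(n_areas = x$graph$n_areas,
                                  n_draws = x$n_draws))
}
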