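# internal: canonical ordering/indexing of a collapsed cell table
.index_cells <- function(cells, graph) {
  cells <- tibble::as_tibble(cells)
  stopifnot(all(c("area_id", "age_band", "fu_year", "y", "d", "dstar") %in%
                  names(cells)))
  if (any(cells$dstar < 0)) stop("negative expected background deaths")
  if (any(cells$y < 0)) stop("negative person-time")
  if (any(cells$d < 0) || any(cells$d != round(cells$d))) {
    stop("observed deaths must be non-negative integers")
  }
  i <- match(cells$area_id, graph$area_ids)
  if (anyNA(i)) {
    stop("cell areas not in graph: ",
         paste(unique(cells$area_id[is.na(i)]), collapse = ", "))
  }
  # age bands ordered by their leading number; youngest is the reference
  bands <- unique(cells$age_band)
  bands <- bands[order(as.numeric(sub("^([0-9.]+).*", "\\1", bands)))]
  j_levels <- sort(unique(cells$fu_year))
  list(cells = cells, i = i,
       j = match(cells$fu_year, j_levels),
       k = match(cells$age_band, bands),
       j_levels = j_levels, bands = bands)
}

#' Log posterior density of the spatial excess-mortality model
#'
#' Collapsed-cell relative-survival model: `d_kji ~ Poisson(mu_kji)` with
#' `mu_kji = dstar_kji + y_kji * exp(alpha_j + beta_k + u_i + v_i)`, i.e. the
#' background expected deaths plus a piecewise-constant excess hazard acting
#' on the cell's person-time. The link guarantees `mu > dstar` for every
#' admissible state. `u` has the intrinsic CAR prior, `v` the exchangeable
#' normal, `alpha_j` and `beta_k` vague N(0, 1e6) priors; `beta` for the
#' reference (youngest) age band is fixed at zero. Cells with zero
#' person-time carry no information and are dropped from the likelihood.
#'
#' @param state List with `alpha_j` (one per follow-up interval), `beta_k`
#'   (one per broad age band, first = reference = 0), `u`, `v`, `tau_u`,
#'   `tau_v`.
#' @param cells Collapsed cell table from [collapse_person_time()].
#' @param graph An [area_graph()].
#' @param priors A [prior_spec()]; default [survival_prior()] `"prior3"`.
#' @param sum_tol Tolerance on the sum-to-zero constraint for `u`.
#' @return Scalar log posterior density (up to the fixed ICAR constant).
#' @export
log_posterior_excess <- function(state, cells, graph, priors = survival_prior(),
                                 sum_tol = 1e-6) {
  ix <- .index_cells(cells, graph)
  n <- graph$n_areas
  stopifnot(length(state$u) == n, length(state$v) == n,
            length(state$alpha_j) == length(ix$j_levels),
            length(state$beta_k) == length(ix$bands),
            state$tau_u > 0, state$tau_v > 0)
  if (abs(state$beta_k[1]) > 0) stop("reference beta_k must be fixed at 0")
  if (abs(sum(state$u)) > sum_tol * max(1, n)) {
    stop("u violates the sum-to-zero constraint")
  }
  keep <- ix$cells$y > 0
  eta <- state$alpha_j[ix$j] + state$beta_k[ix$k] +
    state$u[ix$i] + state$v[ix$i]
  mu <- ix$cells$dstar + ix$cells$y * exp(eta)
  ll <- sum(stats::dpois(ix$cells$d[keep], mu[keep], log = TRUE))
  edges <- graph_edges(graph)
  s_u <- if (nrow(edges)) sum((state$u[edges$from] - state$u[edges$to])^2) else 0
  ncomp <- graph_components(graph)
  l_icar <- 0.5 * (n - ncomp) * (log(state$tau_u) - log(2 * pi)) -
    0.5 * state$tau_u * s_u
  l_v <- sum(stats::dnorm(state$v, 0, 1 / sqrt(state$tau_v), log = TRUE))
  sd_coef <- sqrt(priors$coef_variance)
  l_coef <- sum(stats::dnorm(state$alpha_j, 0, sd_coef, log = TRUE)) +
    sum(stats::dnorm(state$beta_k[-1], 0, sd_coef, log = TRUE))
  ll + l_icar + l_v + l_coef +
    .log_tau_prior(state$tau_u, priors$tau_u) +
    .log_tau_prior(state$tau_v, priors$tau_v)
}

#' Fit the spatial excess-mortality model by MCMC
#'
#' Same sampler architecture as [fit_bym()] with additional single-site
#' random-walk updates for the follow-up-year intercepts `alpha_j` and the
#' broad-age-group coefficients `beta_k` (youngest band fixed at zero as the
#' reference). Sexes are fitted separately by the caller. Cells with zero
#' person-time are dropped before fitting.
#'
#' @param cells Collapsed cell table from [collapse_person_time()] (one sex).
#' @param graph An [area_graph()] with no isolates.
#' @param priors A [prior_spec()].
#' @param control An [mcmc_control()].
#' @return An `excess_fit` with thinned draws of all parameters and derived
#'   per-area relative excess risk chains `rer = exp(u + v)`.
#' @export
fit_excess_mortality <- function(cells, graph, priors = survival_prior(),
                                 control = mcmc_desk_scale()) {
  ix <- .index_cells(cells, graph)
  keep <- ix$cells$y > 0
  if (!any(keep)) stop("no cells with positive person-time")
  if (length(isolates(graph))) {
    stop("graph has isolated areas; run repair_isolates() first")
  }
  fl <- .flatten_nb(graph)
  cu <- .tau_code(priors$tau_u)
  cv <- .tau_code(priors$tau_v)
  set.seed(control$seed)
  raw <- excess_mcmc_cpp(
    as.numeric(ix$cells$d[keep]), as.numeric(ix$cells$y[keep]),
    as.numeric(ix$cells$dstar[keep]),
    ix$j[keep] - 1L, ix$k[keep] - 1L, ix$i[keep] - 1L,
    length(ix$j_levels), length(ix$bands), graph$n_areas,
    fl$nb, fl$start, graph_components(graph),
    cu$kind, cu$p1, cu$p2, cv$kind, cv$p1, cv$p2,
    priors$coef_variance, control$burn_in, control$kept, control$thin)
  rer <- exp(raw$u + raw$v)
  colnames(rer) <- colnames(raw$u) <- colnames(raw$v) <- graph$area_ids
  colnames(raw$alpha_j) <- paste0("year", ix$j_levels)
  colnames(raw$beta_k) <- ix$bands
  structure(
    list(draws = raw, rer = rer, cells = ix$cells, graph = graph,
         priors = priors, control = control,
         j_levels = ix$j_levels, bands = ix$bands,
         n_draws = control$kept %/% control$thin),
    class = c("excess_fit", "atlas_fit"))
}

#' @export
print.excess_fit <- function(x, ...) {
  cat("<excess_fit> ", x$graph$n_areas, " areas, ",
      nrow(x$cells), " cells, ", x$n_draws, " stored draws\n", sep = "")
  invisible(x)
}

#' Summarise smoothed relative excess risks
#'
#' Per-area posterior median of `RER_i = exp(u_i + v_i)` with the central 95%
#' credible interval and the five-class map category. The RER compares each
#' area's excess (cancer-attributable) mortality with the regional average.
#'
#' @param fit An `excess_fit`.
#' @param scale Display multiplier (1 or 100).
#' @return A `smoothed_estimates` tibble: `area_id`, `median`, `lo95`,
#'   `hi95`, `category`.
#' @export
summarize_rer <- function(fit, scale = 1) {
  stopifnot(inherits(fit, "excess_fit"), fit$n_draws > 0)
  .summarize_ratio_draws(fit$rer, fit$graph$area_ids, scale)
}

#' Per-area adjusted and expected death totals
#'
#' For each area, `adjusted = sum_cells(y * exp(alpha_j) * exp(beta_k) *
#' RER_i) + sum_cells(dstar)` and `expected` is the same total with the RER
#' set to 1. These are the modelled observed and expected inputs to the
#' global clustering test; with a point estimate they use the posterior
#' medians of each parameter.
#'
#' @param fit An `excess_fit`, or a list with elements `alpha_j` (named or in
#'   follow-up order), `beta_k` (in band order, reference first), `rer`
#'   (per-area, in graph order).
#' @param cells Cell table; defaults to the one stored in the fit.
#' @param graph Area graph; defaults to the one stored in the fit.
#' @return A tibble with columns `area_id`, `adjusted`, `expected`.
#' @export
adjusted_deaths <- function(fit, cells = NULL, graph = NULL) {
  if (inherits(fit, "excess_fit")) {
    if (is.null(cells)) cells <- fit$cells
    if (is.null(graph)) graph <- fit$graph
    params <- list(
      alpha_j = apply(fit$draws$alpha_j, 2, stats::median),
      beta_k = apply(fit$draws$beta_k, 2, stats::median),
      rer = apply(fit$rer, 2, stats::median))
  } else {
    params <- fit
    if (is.null(cells) || is.null(graph)) {
      stop("`cells` and `graph` are required with explicit parameters")
    }
  }
  ix <- .index_cells(cells, graph)
  excess <- ix$cells$y * exp(params$alpha_j[ix$j] + params$beta_k[ix$k])
  adj <- excess * params$rer[ix$i] + ix$cells$dstar
  exp0 <- excess + ix$cells$dstar
  A <- E <- numeric(graph$n_areas)
  agg <- rowsum(cbind(adj, exp0), ix$i)
  idx <- as.integer(rownames(agg))
  A[idx] <- agg[, 1]
  E[idx] <- agg[, 2]
  tibble::tibble(area_id = graph$area_ids, adjusted = A, expected = E)
}

#' @export
tidy.excess_fit <- function(x, scale = 1, ...) summarize_rer(x, scale = scale)

#' @export
glance.excess_fit <- function(x, ...) {
  med <- apply(x$rer, 2, stats::median)
  q <- stats::quantile(med, c(0.05, 0.95), names = FALSE, type = 7)
  sd_u <- apply(x$draws$u, 1, stats::sd)
  sd_v <- apply(x$draws$v, 1, stats::sd)
  tot <- sd_u + sd_v
  tibble::tibble(
    spatial_fraction = mean(ifelse(tot > 0, sd_u / tot, 0)),
    ratio90 = q[2] / q[1],
    n_areas = x$graph$n_areas, n_cells = nrow(x$cells), n_draws = x$n_draws)
}
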