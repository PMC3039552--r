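# spectral density at zero via an AIC-selected AR fit (canonical estimator
# of the long-run variance for the Geweke diagnostic)
.spectrum0_ar <- function(x, order_max = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (stats::var(x) == 0) return(0)
  if (is.null(order_max)) order_max <- min(n - 1L, floor(10 * log10(n)), 30L)
  fit <- stats::ar(x, aic = TRUE, order.max = order_max,
                   method = "yule-walker")
  if (length(fit$ar) == 0) fit$var.pred else fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence diagnostic for one chain
#'
#' Compares the mean of the first `first_n` stored draws against the mean of
#' the final `last_n` draws (by default the first 1,000 and last 5,000 of a
#' 10,000-draw chain, i.e. 10% and 50%), dividing their difference by the
#' asymptotic standard error of the difference. Each window's standard error
#' uses the spectral density at zero, so autocorrelation within the window is
#' accounted for. Under convergence z is approximately standard normal.
#'
#' @param chain Numeric vector of stored (post-thinning) draws.
#' @param first_n,last_n Window sizes; `length(chain)` must be at least their
#'   sum.
#' @return A one-row tibble with `z` and the two-sided normal `p`. A
#'   zero-variance chain returns `z = 0`, `p = 1`.
#' @export
geweke_z <- function(chain, first_n = 1000, last_n = 5000) {
  n <- length(chain)
  if (n < first_n + last_n) {
    stop("chain of length ", n, " is shorter than first_n + last_n = ",
         first_n + last_n)
  }
  w1 <- chain[seq_len(first_n)]
  w2 <- chain[seq(n - last_n + 1, n)]
  if (stats::var(chain) == 0) {
    return(tibble::tibble(z = 0, p = 1))
  }
  se2 <- .spectrum0_ar(w1) / first_n + .spectrum0_ar(w2) / last_n
  z <- if (se2 > 0) (mean(w1) - mean(w2)) / sqrt(se2) else 0
  tibble::tibble(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Sample autocorrelation of a chain
#'
#' @param chain Numeric vector.
#' @param max_lag Largest lag (must be below the chain length).
#' @return A tibble with columns `lag` (0..max_lag) and `acf`; lag 0 is 1.
#' @export
autocorrelation <- function(chain, max_lag) {
  stopifnot(max_lag < length(chain))
  a <- stats::acf(chain, lag.max = max_lag, plot = FALSE, demean = TRUE)
  tibble::tibble(lag = 0:max_lag, acf = as.numeric(a$acf))
}

#' Convergence screening report across all per-area chains
#'
#' Applies [geweke_z()] to every area's SIR or RER chain and flags those
#' with p below `alpha` (default 0.01) as unlikely to have converged. A plot
#' sample of about `plot_fraction` of areas is selected for visual checking
#' — the areas with the smallest total counts (where convergence problems
#' concentrate) topped up with a seeded random selection — and trace,
#' density and autocorrelation data tables are emitted for them.
#'
#' @param chains Matrix of stored draws (rows) by areas (columns, named), or
#'   a fitted `bym_fit` / `excess_fit` whose SIR / RER chains are used.
#' @param counts Optional per-area total observed counts, used to pick the
#'   small-count half of the plot sample (fit objects supply their own).
#' @param alpha Flagging threshold on the Geweke p-value.
#' @param plot_fraction Fraction of areas in the plot sample.
#' @param seed Seed for the random half of the plot sample.
#' @param first_n,last_n Geweke windows, passed to [geweke_z()].
#' @param max_lag Autocorrelation lags for the plot tables.
#' @return A list: `report` (tibble `area_id`, `z`, `p`, `flagged`),
#'   `fraction_flagged`, `plot_sample` (area ids), and `plot_data` with
#'   `trace`, `density` and `acf` tibbles for the sampled areas.
#' @export
convergence_report <- function(chains, counts = NULL, alpha = 0.01,
                               plot_fraction = 0.05, seed = 1L,
                               first_n = 1000, last_n = 5000, max_lag = 40) {
  if (inherits(chains, "bym_fit")) {
    if (is.null(counts)) counts <- chains$data$y
    chains <- chains$theta
  } else if (inherits(chains, "excess_fit")) {
    if (is.null(counts)) {
      counts <- stats::aggregate(d ~ area_id, data = chains$cells, sum)
      counts <- counts$d[match(colnames(chains$rer), counts$area_id)]
    }
    chains <- chains$rer
  }
  chains <- as.matrix(chains)
  ids <- colnames(chains)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(chains)))
  gw <- purrr::map_dfr(seq_len(ncol(chains)), function(i) {
    geweke_z(chains[, i], first_n = first_n, last_n = last_n)
  })
  report <- tibble::tibble(area_id = ids, z = gw$z, p = gw$p,
                           flagged = gw$p < alpha)
  n <- length(ids)
  n_plot <- min(n, ceiling(plot_fraction * n))
  n_small <- n_plot %/% 2
  small_ids <- if (!is.null(counts) && n_small > 0) {
    ids[order(counts, ids)][seq_len(n_small)]
  } else character()
  pool <- setdiff(ids, small_ids)
  set.seed(seed)
  rand_ids <- sample(pool, min(length(pool), n_plot - length(small_ids)))
  sample_ids <- union(small_ids, rand_ids)

  plot_data <- list(
    trace = purrr::map_dfr(sample_ids, function(id) {
      tibble::tibble(area_id = id, iter = seq_len(nrow(chains)),
                     value = chains[, id])
    }),
    density = purrr::map_dfr(sample_ids, function(id) {
      d <- stats::density(chains[, id])
      tibble::tibble(area_id = id, value = d$x, density = d$y)
    }),
    acf = purrr::map_dfr(sample_ids, function(id) {
      dplyr::mutate(autocorrelation(chains[, id], max_lag), area_id = id,
                    .before = 1)
    })
  )
  list(report = report,
       fraction_flagged = mean(report$flagged),
       plot_sample = sample_ids,
       plot_data = plot_data)
}
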