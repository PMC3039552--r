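#' Modelled observed and expected inputs for the clustering test
#'
#' For incidence, the modelled observed count of an area is its smoothed
#' posterior-median SIR multiplied by its expected count; the expected input
#' is the expected count itself. For survival, the inputs are the per-area
#' adjusted deaths and their RER = 1 companion totals from
#' [adjusted_deaths()] (posterior-median parameters).
#'
#' @param estimates A `smoothed_estimates` tibble on the ratio scale
#'   (`scale = 1`), as from [summarize_sir()].
#' @param expected Data frame with columns `area_id`, `e`.
#' @return A tibble with columns `area_id`, `O`, `E`.
#' @export
modelled_observed_incidence <- function(estimates, expected) {
  expected <- tibble::as_tibble(expected)
  stopifnot(all(c("area_id", "e") %in% names(expected)))
  m <- match(estimates$area_id, expected$area_id)
  if (anyNA(m)) stop("expected counts missing for some areas")
  tibble::tibble(area_id = estimates$area_id,
                 O = estimates$median * expected$e[m],
                 E = expected$e[m])
}

#' @param fit An `excess_fit`.
#' @rdname modelled_observed_incidence
#' @export
modelled_observed_survival <- function(fit) {
  ad <- adjusted_deaths(fit)
  tibble::tibble(area_id = ad$area_id, O = ad$adjusted, E = ad$expected)
}

#' Tango's maximised excess events test (MEET)
#'
#' Global clustering test on area-level observed and expected event totals.
#' For each spatial scale lambda the excess-events statistic is
#' `C(lambda) = sum_ij exp(-d_ij / lambda) (O_i/O. - E_i/E.)(O_j/O. - E_j/E.)`
#' with `d_ij` the centroid distance. Each `C(lambda)` is converted to a
#' p-value against multinomial null replicates (total `round(sum(O))` events
#' allocated with probabilities `E/sum(E)`), the test statistic is the
#' minimum p over the lambda grid, and the adjusted p-value is the
#' proportion of a second, independent replicate set whose own minimum p is
#' at most the observed one — a nested scheme that avoids using the same
#' replicates for calibration and adjustment. Deterministic given `seed`.
#'
#' @param oe Data frame with columns `area_id`, `O`, `E` (`E > 0`,
#'   `sum(O) > 0`), as from [modelled_observed_incidence()].
#' @param centroids Data frame `area_id`, `x`, `y`, or an [area_graph()]
#'   carrying centroids.
#' @param lambda_grid Positive increasing vector of kernel scales; default 10
#'   log-spaced values spanning the 1st-99th percentile of pairwise centroid
#'   distances.
#' @param n_rep Monte-Carlo replicates per set (default 999); the reported p
#'   is `(1 + #{replicates <= observed}) / (1 + n_rep)`.
#' @param seed Integer seed.
#' @return A list of class `meet_result`: `p` (adjusted p-value), `category`
#'   (see [classify_evidence()]), `min_p` (observed minimum per-lambda p),
#'   `by_lambda` (tibble `lambda`, `C`, `p`), `n_rep`, `seed`.
#' @export
tango_meet <- function(oe, centroids, lambda_grid = NULL, n_rep = 999,
                       seed = 1L) {
  oe <- tibble::as_tibble(oe)
  stopifnot(all(c("area_id", "O", "E") %in% names(oe)))
  if (inherits(centroids, "area_graph")) centroids <- centroids$centroids
  centroids <- tibble::as_tibble(centroids)
  m <- match(oe$area_id, centroids$area_id)
  if (anyNA(m)) stop("centroids missing for some areas")
  xy <- cbind(centroids$x[m], centroids$y[m])
  O <- oe$O
  E <- oe$E
  if (sum(O) <= 0) stop("sum of observed values must be positive")
  if (any(E <= 0)) stop("all expected values must be positive")
  n <- length(O)
  D <- as.matrix(stats::dist(xy))
  if (is.null(lambda_grid)) {
    dpos <- D[upper.tri(D)]
    qs <- stats::quantile(dpos[dpos > 0], c(0.01, 0.99), names = FALSE, type = 7)
    lambda_grid <- exp(seq(log(qs[1]), log(qs[2]), length.out = 10))
  }
  if (any(lambda_grid <= 0) || is.unsorted(lambda_grid, strictly = TRUE)) {
    stop("lambda_grid must be positive and strictly increasing")
  }
  nl <- length(lambda_grid)
  kernels <- lapply(lambda_grid, function(l) exp(-D / l))

  p_vec <- E / sum(E)
  r_obs <- O / sum(O) - p_vec
  C_obs <- vapply(kernels, function(K) drop(crossprod(r_obs, K %*% r_obs)),
                  numeric(1))

  N <- max(1L, round(sum(O)))
  set.seed(seed)
  draw_C <- function() {
    R <- stats::rmultinom(n_rep, N, p_vec) / N - p_vec  # n x n_rep residuals
    vapply(kernels, function(K) colSums((K %*% R) * R), numeric(n_rep))
  }
  C_A <- draw_C()  # calibration set: n_rep x nl
  C_B <- draw_C()  # adjustment set

  sorted_A <- apply(C_A, 2, sort)
  p_of <- function(Cvals) {
    # per-lambda p: share of calibration replicates at least as extreme
    vapply(seq_len(nl), function(l) {
      ge <- n_rep - findInterval(Cvals[l], sorted_A[, l], left.open = TRUE)
      (1 + ge) / (1 + n_rep)
    }, numeric(1))
  }
  by_lambda_p <- p_of(C_obs)
  minp_obs <- min(by_lambda_p)
  minp_B <- vapply(seq_len(n_rep), function(b) min(p_of(C_B[b, ])), numeric(1))
  p_adj <- (1 + sum(minp_B <= minp_obs)) / (1 + n_rep)

  structure(list(
    p = p_adj,
    category = classify_evidence(p_adj),
    min_p = minp_obs,
    by_lambda = tibble::tibble(lambda = lambda_grid, C = C_obs, p = by_lambda_p),
    n_rep = n_rep, seed = seed),
    class = "meet_result")
}

#' @export
print.meet_result <- function(x, ...) {
  cat("<meet_result> adjusted p = ", format(x$p), " (", as.character(x$category),
      " evidence), ", x$n_rep, " replicates\n", sep = "")
  invisible(x)
}

#' Evidence classification of clustering p-values
#'
#' `p < 0.01` is strong evidence of spatial variation, `0.01 <= p < 0.05`
#' moderate, `0.05 <= p < 0.10` weak, and `p >= 0.10` none.
#'
#' @param p Numeric vector of adjusted p-values in `[0, 1]`.
#' @return An ordered factor with levels strong < moderate < weak < none.
#' @export
classify_evidence <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  bands <- meet_evidence_bands()
  cut(p, breaks = c(-Inf, bands, Inf), right = FALSE,
      labels = c("strong", "moderate", "weak", "none"),
      ordered_result = TRUE)
}

#' Stability-checked clustering classification
#'
#' Because the test is Monte-Carlo based, the classification is repeated
#' with distinct seeds (6 runs by default: the initial run plus 5 more).
#' When the runs disagree, the final category is the more conservative,
#' less significant one observed.
#'
#' @inheritParams tango_meet
#' @param runs Number of repetitions (default [meet_stability_runs()], 6).
#' @param seed Base seed; run r uses `seed + r - 1`.
#' @return A list: `category` (final), `runs` (tibble `run`, `seed`, `p`,
#'   `category`).
#' @export
stable_classify <- function(oe, centroids, lambda_grid = NULL, n_rep = 999,
                            runs = meet_stability_runs(), seed = 1L) {
  res <- purrr::map(seq_len(runs), function(r) {
    tango_meet(oe, centroids, lambda_grid = lambda_grid, n_rep = n_rep,
               seed = seed + r - 1L)
  })
  tab <- tibble::tibble(
    run = seq_len(runs),
    seed = seed + seq_len(runs) - 1L,
    p = vapply(res, `[[`, numeric(1), "p"),
    category = vapply(res, function(x) as.character(x$category), character(1)))
  levels_ord <- c("strong", "moderate", "weak", "none")
  final <- levels_ord[max(match(tab$category, levels_ord))]
  list(category = factor(final, levels = levels_ord, ordered = TRUE),
       runs = tab)
}
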