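#' Build a stratum assignment from area scores
#'
#' Assigns each area a socioeconomic quintile by ranking a supplied
#' disadvantage score (quintile 1 = most disadvantaged fifth) and carries a
#' rurality label through unchanged. If `ses_quintile` is already present it
#' is used as-is.
#'
#' @param df Data frame with `area_id`, `rurality`, and either `ses_score`
#'   (lower = more disadvantaged) or `ses_quintile` (1..5).
#' @return A tibble `area_id`, `ses_quintile`, `rurality`.
#' @export
make_stratum_assignment <- function(df) {
  df <- tibble::as_tibble(df)
  stopifnot("area_id" %in% names(df), "rurality" %in% names(df))
  if (!"ses_quintile" %in% names(df)) {
    if (!"ses_score" %in% names(df)) {
      stop("need either ses_quintile or ses_score")
    }
    df$ses_quintile <- dplyr::ntile(df$ses_score, 5)
  }
  stopifnot(all(df$ses_quintile %in% 1:5))
  df[, c("area_id", "ses_quintile", "rurality")]
}

# per-draw adjusted deaths matrix (draws x areas) and fixed expected totals
.adjusted_deaths_draws <- function(fit) {
  ix <- .index_cells(fit$cells, fit$graph)
  nd <- fit$n_draws
  eta <- fit$draws$alpha_j[, ix$j, drop = FALSE] +
    fit$draws$beta_k[, ix$k, drop = FALSE]
  EX <- exp(eta) * matrix(ix$cells$y, nrow = nd, ncol = length(ix$i),
                          byrow = TRUE)
  S <- t(rowsum(t(EX), ix$i))  # draws x present-areas, excess part
  present <- as.integer(colnames(S))
  A <- matrix(0, nd, fit$graph$n_areas)
  A[, present] <- S
  dstar_area <- numeric(fit$graph$n_areas)
  ds <- rowsum(ix$cells$dstar, ix$i)
  dstar_area[as.integer(rownames(ds))] <- ds[, 1]
  A <- A * fit$rer + matrix(dstar_area, nd, fit$graph$n_areas, byrow = TRUE)
  colnames(A) <- fit$graph$area_ids
  A
}

#' Aggregate posterior draws to strata
#'
#' For every stored draw the modelled observed value of each area is
#' computed (incidence: `theta_i * e_i`; survival: the adjusted deaths under
#' that draw's parameters), summed within each stratum, and divided by the
#' stratum's summed expected value (incidence: `e_i`; survival: the
#' RER = 1 expected totals at the posterior-median parameters). The chain of
#' stratum ratios is summarised by its median and 2.5/97.5 percentiles.
#'
#' @param fit A `bym_fit` or `excess_fit`.
#' @param assignment Stratum assignment from [make_stratum_assignment()]
#'   covering every modelled area.
#' @param by Assignment column to group by (`"ses_quintile"` or
#'   `"rurality"`).
#' @return A tibble with columns `stratum`, `n_areas`, `median`, `lo95`,
#'   `hi95`.
#' @export
group_estimates <- function(fit, assignment, by = "ses_quintile") {
  assignment <- tibble::as_tibble(assignment)
  stopifnot(by %in% names(assignment))
  ids <- fit$graph$area_ids
  m <- match(ids, assignment$area_id)
  if (anyNA(m)) {
    stop("assignment missing for areas: ",
         paste(ids[is.na(m)][1:min(3, sum(is.na(m)))], collapse = ", "))
  }
  strata <- assignment[[by]][m]
  if (inherits(fit, "bym_fit")) {
    e <- fit$data$e
    O <- fit$theta * matrix(e, fit$n_draws, length(e), byrow = TRUE)
    E <- e
  } else if (inherits(fit, "excess_fit")) {
    O <- .adjusted_deaths_draws(fit)
    E <- adjusted_deaths(fit)$expected
  } else {
    stop("fit must be a bym_fit or excess_fit")
  }
  groups <- split(seq_along(ids), strata)
  if (any(lengths(groups) == 0)) stop("empty stratum")
  purrr::map_dfr(names(groups), function(g) {
    idx <- groups[[g]]
    ratio <- rowSums(O[, idx, drop = FALSE]) / sum(E[idx])
    q <- stats::quantile(ratio, c(0.5, 0.025, 0.975), names = FALSE, type = 7)
    tibble::tibble(stratum = g, n_areas = length(idx),
                   median = q[1], lo95 = q[2], hi95 = q[3])
  })
}

#' Classify a smoothed ratio into the five map classes
#'
#' Cut-offs are 10% and 30% above the regional average and their inverses
#' below it: classes (0, 1/1.3), \[1/1.3, 1/1.1), \[1/1.1, 1.1\],
#' (1.1, 1.3\], (1.3, Inf), labelled well below / below / average / above /
#' well above. The central class is closed on both sides.
#'
#' @param x Positive numeric vector of ratios (regional average = 1).
#' @return Ordered factor of the five class labels.
#' @export
categorize_for_map <- function(x) {
  if (any(!is.finite(x) | x <= 0)) stop("ratios must be positive and finite")
  lab <- ifelse(x < 1 / 1.3, "well below",
         ifelse(x < 1 / 1.1, "below",
         ifelse(x <= 1.1, "average",
         ifelse(x <= 1.3, "above", "well above"))))
  factor(lab, levels = c("well below", "below", "average", "above",
                         "well above"), ordered = TRUE)
}

#' Export atlas products
#'
#' Writes the map and graph products for one set of smoothed estimates: a
#' GeoJSON choropleth (geometry plus median, interval and category
#' properties), a caterpillar CSV of areas ranked by median with their
#' credible intervals, and, when a stratum assignment is given, box-plot
#' summary CSVs (min, q1, median, q3, max of the area medians) per
#' socioeconomic quintile and rurality category.
#'
#' @param polygons Tidy polygon coordinates (`area_id`, `part`, `x`, `y`).
#' @param estimates A `smoothed_estimates` tibble.
#' @param dir Output directory (created if needed).
#' @param assignment Optional stratum assignment.
#' @param prefix File-name prefix.
#' @return Named character vector of the files written, invisibly.
#' @export
export_products <- function(polygons, estimates, dir, assignment = NULL,
                            prefix = "atlas") {
  poly_ids <- unique(polygons$area_id)
  if (!setequal(poly_ids, estimates$area_id)) {
    stop("polygon and estimate area ids do not match")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  props <- dplyr::mutate(estimates, category = as.character(.data$category))
  f_geo <- file.path(dir, paste0(prefix, "_choropleth.geojson"))
  write_geojson_areas(polygons, props, f_geo)
  files["choropleth"] <- f_geo
  cat_tbl <- estimates |>
    dplyr::arrange(.data$median, .data$area_id) |>
    dplyr::mutate(rank = dplyr::row_number())
  f_cat <- file.path(dir, paste0(prefix, "_caterpillar.csv"))
  readr::write_csv(cat_tbl, f_cat)
  files["caterpillar"] <- f_cat
  if (!is.null(assignment)) {
    for (by in c("ses_quintile", "rurality")) {
      m <- match(estimates$area_id, assignment$area_id)
      box <- tibble::tibble(stratum = assignment[[by]][m],
                            median = estimates$median) |>
        dplyr::group_by(.data$stratum) |>
        dplyr::summarise(
          min = min(.data$median),
          q1 = stats::quantile(.data$median, 0.25, names = FALSE, type = 7),
          med = stats::median(.data$median),
          q3 = stats::quantile(.data$median, 0.75, names = FALSE, type = 7),
          max = max(.data$median), .groups = "drop")
      f_box <- file.path(dir, paste0(prefix, "_box_", by, ".csv"))
      readr::write_csv(box, f_box)
      files[paste0("box_", by)] <- f_box
    }
  }
  invisible(files)
}
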