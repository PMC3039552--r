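#' Synthetic lattice geography with detached islands
#'
#' Builds a grid of unit-square areas plus `n_islands` detached square
#' polygons placed beyond any boundary contact, mimicking a coastal mosaic
#' of contiguous small areas with offshore islands. The queen graph is
#' returned pre-repair, so the islands appear as isolates.
#'
#' @param n_rows,n_cols Lattice dimensions.
#' @param n_islands Number of detached areas.
#' @param seed Seed (controls the island jitter only).
#' @return A list with `polygons` (tidy coordinates) and `graph` (the queen
#'   [area_graph()], isolates included).
#' @export
make_geography <- function(n_rows, n_cols, n_islands = 0, seed = 1L) {
  if (n_rows * n_cols + n_islands < 2) stop("need at least 2 areas")
  set.seed(seed)
  unit_square <- function(x0, y0) {
    tibble::tibble(x = c(x0, x0 + 1, x0 + 1, x0), y = c(y0, y0, y0 + 1, y0 + 1))
  }
  cells <- tidyr::expand_grid(row = seq_len(n_rows), col = seq_len(n_cols))
  n_lattice <- nrow(cells)
  pad <- nchar(as.character(n_lattice + n_islands))
  polys <- purrr::pmap_dfr(
    list(cells$row, cells$col, seq_len(n_lattice)),
    function(r, c, k) {
      dplyr::mutate(unit_square(c - 1, r - 1),
                    area_id = sprintf("A%0*d", pad, k), part = 1L)
    })
  if (n_islands > 0) {
    isl <- purrr::map_dfr(seq_len(n_islands), function(k) {
      x0 <- n_cols + 2 + 2 * ((k - 1) %% 6) + stats::runif(1, -0.3, 0.3)
      y0 <- 2 * ((k - 1) %/% 6) + stats::runif(1, -0.3, 0.3)
      dplyr::mutate(unit_square(x0, y0),
                    area_id = sprintf("A%0*d", pad, n_lattice + k), part = 1L)
    })
    polys <- dplyr::bind_rows(polys, isl)
  }
  polys <- polys[, c("area_id", "part", "x", "y")]
  list(polygons = polys, graph = build_queen_adjacency(polys))
}

.age_groups <- function() {
  lower <- seq(0, 85, by = 5)
  labels <- c(paste0(lower[-18], "-", lower[-18] + 4), "85+")
  tibble::tibble(age_group = labels, age_lower = lower, age_mid = lower + 2.5)
}

#' Synthetic populations and a population life table
#'
#' Populations cover 18 five-year age groups (0-4 ... 85+), both sexes and
#' every study year, with log-normal variation in area size and a fixed,
#' gently declining age pyramid. The life table holds all-cause mortality
#' rates rising Gompertz-like with age (slightly higher for males), constant
#' across areas and years.
#'
#' @param graph An [area_graph()].
#' @param mean_pop Mean total population per area (all ages/sexes, one year).
#' @param dispersion Log-scale SD of area size (0 makes all areas equal).
#' @param base_mortality Multiplier on the life-table rates.
#' @param years Study years.
#' @param seed Seed.
#' @return A list with `populations` (`area_id`, `sex`, `age_group`, `year`,
#'   `person_years`) and `life_table` (`sex`, `age`, `year`, `rate`).
#' @export
simulate_populations_and_lifetable <- function(graph, mean_pop = 5000,
                                               dispersion = 0.5,
                                               base_mortality = 1,
                                               years = 1998:2007, seed = 1L) {
  stopifnot(mean_pop > 0, dispersion >= 0, base_mortality > 0)
  set.seed(seed)
  ag <- .age_groups()
  w <- exp(-0.018 * ag$age_mid)
  w <- w / sum(w)
  mult <- exp(stats::rnorm(graph$n_areas, log(mean_pop) - dispersion^2 / 2,
                           dispersion))
  pops <- tidyr::expand_grid(area_id = graph$area_ids, sex = c("female", "male"),
                             age_group = ag$age_group, year = years) |>
    dplyr::left_join(ag[, c("age_group", "age_mid")], by = "age_group") |>
    dplyr::mutate(
      person_years = mult[match(.data$area_id, graph$area_ids)] *
        w[match(.data$age_group, ag$age_group)] / 2) |>
    dplyr::select(-"age_mid")
  lt <- tidyr::expand_grid(sex = c("female", "male"), age = ag$age_lower,
                           year = years) |>
    dplyr::mutate(
      rate = base_mortality * 2e-5 * exp(0.095 * (.data$age + 2.5)) *
        ifelse(.data$sex == "male", 1.3, 0.85))
  list(populations = pops, life_table = lt)
}

# draw an intrinsic CAR field and rescale to an empirical SD of sigma
.draw_icar <- function(graph, sigma, sweeps = 200) {
  if (sigma <= 0) return(numeric(graph$n_areas))
  fl <- .flatten_nb(graph)
  u <- icar_gibbs_cpp(fl$nb, fl$start, graph$n_areas, 1.0, sweeps)
  s <- stats::sd(u)
  if (s > 0) u * sigma / s else u
}

#' Simulate area counts from the BYM generative model
#'
#' Draws a spatially structured field `u` (intrinsic CAR, rescaled to an
#' empirical SD of `sigma_u`), unstructured noise `v ~ N(0, sigma_v^2)`, and
#' Poisson counts `y_i ~ Poisson(e_i * exp(alpha + u_i + v_i))`. Expected
#' counts come from the populations and age/sex-specific baseline rates;
#' age-level case counts are also returned so the indirect-standardisation
#' step can be exercised end to end.
#'
#' @param graph A repaired [area_graph()].
#' @param alpha Overall log relative risk.
#' @param sigma_u,sigma_v Marginal scales of the spatial and unstructured
#'   effects (0 switches the component off).
#' @param populations Population table from
#'   [simulate_populations_and_lifetable()]; may be omitted when `expected`
#'   is given directly.
#' @param base_rates Optional baseline incidence rates (`sex`, `age_group`,
#'   `rate` per person-year); the default rises exponentially with age.
#' @param expected Optional per-area expected counts (a scalar, or a vector
#'   in graph order) used directly instead of populations and rates; no
#'   age-level case table is produced in that case.
#' @param seed Seed.
#' @return A list: `data` (tibble `area_id`, `y`, `e`), `cases` (age-level
#'   counts, `NULL` when `expected` was given), and `truth` (`theta`, `u`,
#'   `v`, `alpha`).
#' @export
simulate_incidence <- function(graph, alpha = 0, sigma_u = 0.3, sigma_v = 0.1,
                               populations = NULL, base_rates = NULL,
                               expected = NULL, seed = 1L) {
  stopifnot(sigma_u >= 0, sigma_v >= 0)
  set.seed(seed)
  if (!is.null(expected)) {
    e <- rep_len(expected, graph$n_areas)
    u <- .draw_icar(graph, sigma_u)
    v <- stats::rnorm(graph$n_areas, 0, sigma_v)
    theta <- exp(alpha + u + v)
    names(theta) <- graph$area_ids
    data <- tibble::tibble(area_id = graph$area_ids,
                           y = stats::rpois(graph$n_areas, e * theta), e = e)
    return(list(data = data, cases = NULL,
                truth = list(theta = theta, u = u, v = v, alpha = alpha)))
  }
  ag <- .age_groups()
  if (is.null(base_rates)) {
    base_rates <- tidyr::expand_grid(sex = c("female", "male"),
                                     age_group = ag$age_group) |>
      dplyr::left_join(ag[, c("age_group", "age_mid")], by = "age_group") |>
      dplyr::mutate(rate = 1.2e-5 * exp(0.075 * .data$age_mid)) |>
      dplyr::select(-"age_mid")
  }
  u <- .draw_icar(graph, sigma_u)
  v <- stats::rnorm(graph$n_areas, 0, sigma_v)
  theta <- exp(alpha + u + v)
  names(theta) <- graph$area_ids
  strata <- tibble::as_tibble(populations) |>
    dplyr::left_join(base_rates, by = c("sex", "age_group")) |>
    dplyr::mutate(
      mu0 = .data$person_years * .data$rate,
      theta = theta[match(.data$area_id, graph$area_ids)],
      n = stats::rpois(dplyr::n(), .data$mu0 * .data$theta))
  data <- strata |>
    dplyr::group_by(area_id = .data$area_id) |>
    dplyr::summarise(y = sum(.data$n), e = sum(.data$mu0), .groups = "drop")
  data <- data[match(graph$area_ids, data$area_id), ]
  list(data = data,
       cases = strata[, c("area_id", "sex", "age_group", "year", "n")],
       truth = list(theta = theta, u = u, v = v, alpha = alpha))
}

#' Simulate individual survival records with a spatial excess hazard
#'
#' Each case's total hazard during follow-up year `j` is the background
#' life-table mortality at its attained age plus a piecewise-constant excess
#' hazard `exp(alpha_j + beta_k + u_i + v_i)` (k = broad age group at
#' diagnosis, i = area). Event times are drawn piecewise-exponentially
#' across follow-up-year boundaries; survivors past `max_followup_years` or
#' the window end are censored at the window end. A configurable fraction of
#' records is marked death-certificate-only, autopsy-only, or aged 90+, so
#' the exclusion rules can be exercised.
#'
#' @param graph A repaired [area_graph()].
#' @param alpha_j Follow-up-year log excess-hazard intercepts (length 5 by
#'   default usage).
#' @param beta_k Broad-age-group coefficients, reference (first) = 0; bands
#'   are defined by `broad_age_breaks`.
#' @param sigma_u,sigma_v Scales of the area effects.
#' @param populations,life_table From
#'   [simulate_populations_and_lifetable()].
#' @param n_cases Number of records to generate.
#' @param window_start,window_end Study window; diagnoses accrue from
#'   `accrual_start` (default two years before the window) to `window_end`.
#' @param broad_age_breaks Lower bounds of the broad age groups.
#' @param accrual_start Optional first diagnosis date.
#' @param prop_dco,prop_autopsy,prop_old Fractions of records flagged
#'   death-certificate-only / autopsy-only / aged 90+.
#' @param log_rer_shift Scalar or per-area vector added to `u_i + v_i`, for
#'   planting known relative-excess-risk signal (e.g. `log(2)` at one area
#'   doubles its excess hazard).
#' @param seed Seed.
#' @return A list: `records` (tibble in the layout
#'   [apply_survival_exclusions()] expects) and `truth` (`rer`, `u`, `v`,
#'   `alpha_j`, `beta_k`).
#' @export
simulate_survival_records <- function(graph, alpha_j, beta_k,
                                      sigma_u = 0.2, sigma_v = 0.1,
                                      populations, life_table, n_cases,
                                      window_start, window_end,
                                      broad_age_breaks = c(0, 60, 70, 80),
                                      accrual_start = NULL,
                                      prop_dco = 0.01, prop_autopsy = 0.005,
                                      prop_old = 0.02, log_rer_shift = 0,
                                      seed = 1L) {
  stopifnot(length(beta_k) >= 1, beta_k[1] == 0)
  window_start <- .as_date(window_start)
  window_end <- .as_date(window_end)
  if (is.null(accrual_start)) accrual_start <- window_start - round(2 * 365.25)
  accrual_start <- .as_date(accrual_start)
  set.seed(seed)
  n <- graph$n_areas
  u <- .draw_icar(graph, sigma_u)
  v <- stats::rnorm(n, 0, sigma_v) + rep_len(log_rer_shift, n)
  rer <- exp(u + v)
  names(rer) <- graph$area_ids

  pop_area <- tibble::as_tibble(populations) |>
    dplyr::group_by(.data$area_id) |>
    dplyr::summarise(p = sum(.data$person_years), .groups = "drop")
  p_area <- pop_area$p[match(graph$area_ids, pop_area$area_id)]
  area_idx <- sample.int(n, n_cases, replace = TRUE, prob = p_area)

  ages <- 15:89
  age_at_dx <- sample(ages, n_cases, replace = TRUE,
                      prob = exp(0.055 * (ages - 15)))
  old <- stats::runif(n_cases) < prop_old
  age_at_dx[old] <- sample(90:99, sum(old), replace = TRUE)
  sex <- sample(c("female", "male"), n_cases, replace = TRUE)
  diag_date <- accrual_start +
    floor(stats::runif(n_cases) *
            (as.numeric(window_end - accrual_start) + 1))
  k_band <- findInterval(age_at_dx, sort(broad_age_breaks))
  max_fu <- length(alpha_j)

  lt_years <- range(life_table$year)
  excess <- exp(outer(rep(1, n_cases), alpha_j) +
                  beta_k[k_band] + u[area_idx] + v[area_idx])
  # piecewise-exponential event times across follow-up-year boundaries
  t_death <- rep(Inf, n_cases)
  alive <- rep(TRUE, n_cases)
  for (j in seq_len(max_fu)) {
    mid_age <- age_at_dx + j - 0.5
    mid_year <- as.integer(format(diag_date + round((j - 0.5) * 365.25), "%Y"))
    mid_year <- pmin(pmax(mid_year, lt_years[1]), lt_years[2])
    h_bg <- life_table_rate(life_table, sex, mid_age, mid_year)
    h <- h_bg + excess[, j]
    tj <- stats::rexp(n_cases, rate = h)
    died_now <- alive & tj < 1
    t_death[died_now] <- (j - 1) + tj[died_now]
    alive <- alive & !died_now
  }
  death_date <- diag_date + round(t_death * 365.25)
  died <- is.finite(t_death) & death_date <= window_end
  exit_date <- dplyr::if_else(died, death_date, window_end)

  records <- tibble::tibble(
    area_id = graph$area_ids[area_idx],
    sex = sex,
    age_years = age_at_dx,
    diag_date = diag_date,
    exit_date = exit_date,
    died = died,
    dco = stats::runif(n_cases) < prop_dco,
    autopsy = stats::runif(n_cases) < prop_autopsy)
  list(records = records,
       truth = list(rer = rer, u = u, v = v,
                    alpha_j = alpha_j, beta_k = beta_k))
}
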