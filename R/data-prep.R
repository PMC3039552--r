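#' Expected incidence counts by indirect standardisation
#'
#' Computes, per area and sex, the observed count `y` and the expected count
#' `e = sum_age rate(age, sex) * person_years(area, age, sex)`, where the
#' age- and sex-specific reference rates are by default the pooled rates of
#' the supplied data themselves (so `sum(e) = sum(y)` within each sex and a
#' raw ratio of 1 means the regional average). An external reference-rate
#' table can be supplied instead, in which case the totals need not balance.
#'
#' @param cases Data frame with columns `area_id`, `sex`, `age_group`,
#'   `year`, `n`.
#' @param populations Data frame with columns `area_id`, `sex`, `age_group`,
#'   `year`, `person_years`.
#' @param reference_rates Optional data frame `sex`, `age_group`, `rate`
#'   (cases per person-year) replacing the internal pooled rates.
#' @return A tibble with columns `area_id`, `sex`, `y`, `e`.
#' @export
expected_incidence_counts <- function(cases, populations, reference_rates = NULL) {
  cases <- tibble::as_tibble(cases)
  populations <- tibble::as_tibble(populations)
  stopifnot(all(c("area_id", "sex", "age_group", "year", "n") %in% names(cases)),
            all(c("area_id", "sex", "age_group", "year", "person_years") %in%
                  names(populations)))
  agg_cases <- cases |>
    dplyr::group_by(.data$area_id, .data$sex, .data$age_group) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  agg_pop <- populations |>
    dplyr::group_by(.data$area_id, .data$sex, .data$age_group) |>
    dplyr::summarise(person_years = sum(.data$person_years), .groups = "drop")
  joined <- dplyr::full_join(agg_pop, agg_cases,
                             by = c("area_id", "sex", "age_group")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0),
                  person_years = dplyr::coalesce(.data$person_years, 0))
  bad <- joined |> dplyr::filter(.data$person_years <= 0, .data$n > 0)
  if (nrow(bad)) {
    stop("cases recorded in strata with zero population, e.g. area ",
         bad$area_id[1], " age group ", bad$age_group[1])
  }
  if (is.null(reference_rates)) {
    reference_rates <- joined |>
      dplyr::group_by(.data$sex, .data$age_group) |>
      dplyr::summarise(rate = sum(.data$n) / sum(.data$person_years),
                       .groups = "drop") |>
      dplyr::mutate(rate = ifelse(is.finite(.data$rate), .data$rate, 0))
  }
  joined |>
    dplyr::left_join(reference_rates, by = c("sex", "age_group")) |>
    dplyr::mutate(rate = dplyr::coalesce(.data$rate, 0)) |>
    dplyr::group_by(.data$area_id, .data$sex) |>
    dplyr::summarise(y = sum(.data$n),
                     e = sum(.data$rate * .data$person_years),
                     .groups = "drop")
}

.as_date <- function(x) if (inherits(x, "Date")) x else as.Date(x)

#' Apply the relative-survival inclusion and exclusion rules
#'
#' Drops records aged `max_age` (90) or older at diagnosis, those whose
#' diagnosis was based on a death certificate or autopsy only, and those with
#' a survival time of zero days or less. A record is kept only if it
#' contributes at-risk time inside the study window within the first
#' `max_followup_years` of follow-up (the follow-up clock always starts at
#' diagnosis, so cases diagnosed before the window can still contribute).
#' Survivors at the window end are censored downstream, in
#' [collapse_person_time()].
#'
#' @param records Data frame with columns `area_id`, `sex`, `age_years`,
#'   `diag_date`, `exit_date` (ISO-8601 or `Date`), `died`, `dco`, `autopsy`
#'   (logical or 0/1).
#' @param window_start,window_end Study window bounds (dates).
#' @param max_followup_years Follow-up cap in years (default 5).
#' @param max_age Exclusion threshold for age at diagnosis (default 90).
#' @return A list with `records` (the included rows) and `tally`, a tibble of
#'   exclusion counts per reason.
#' @export
apply_survival_exclusions <- function(records, window_start, window_end,
                                      max_followup_years = 5, max_age = 90) {
  records <- tibble::as_tibble(records)
  req <- c("area_id", "sex", "age_years", "diag_date", "exit_date",
           "died", "dco", "autopsy")
  stopifnot(all(req %in% names(records)))
  records$diag_date <- .as_date(records$diag_date)
  records$exit_date <- .as_date(records$exit_date)
  records$died <- as.logical(records$died)
  records$dco <- as.logical(records$dco)
  records$autopsy <- as.logical(records$autopsy)
  window_start <- .as_date(window_start)
  window_end <- .as_date(window_end)

  corrupt <- records$exit_date < records$diag_date & !records$died
  if (any(corrupt)) {
    stop("corrupt record(s): exit before diagnosis without a death flag (row ",
         which(corrupt)[1], ")")
  }
  surv_days <- as.numeric(records$exit_date - records$diag_date)
  fu_end <- records$diag_date + round(max_followup_years * 365.25)
  reason <- dplyr::case_when(
    records$age_years >= max_age ~ "age",
    records$dco ~ "death_certificate_only",
    records$autopsy ~ "autopsy_only",
    surv_days <= 0 ~ "zero_survival",
    pmin(records$exit_date, fu_end) <= window_start |
      records$diag_date > window_end ~ "no_time_at_risk",
    TRUE ~ "included"
  )
  tally <- tibble::tibble(reason = reason) |>
    dplyr::count(.data$reason, name = "n")
  list(records = records[reason == "included", ],
       tally = tally)
}

#' Look up all-cause mortality rates in a life table
#'
#' @param life_table Data frame with columns `sex`, `age` (lower bound of an
#'   age band, single-year or 5-year), `year`, `rate` (deaths per
#'   person-year).
#' @param sex,age,year Vectors of equal length to look up.
#' @return Numeric vector of rates; an error identifies any (sex, year)
#'   absent from the table or ages below its youngest band.
#' @export
life_table_rate <- function(life_table, sex, age, year) {
  life_table <- tibble::as_tibble(life_table)
  stopifnot(all(c("sex", "age", "year", "rate") %in% names(life_table)))
  key <- paste(life_table$sex, life_table$year)
  groups <- split(seq_len(nrow(life_table)), key)
  qkey <- paste(sex, year)
  out <- numeric(length(qkey))
  for (k in unique(qkey)) {
    rows <- groups[[k]]
    if (is.null(rows)) stop("life table has no entry for sex/year ", k)
    sub <- life_table[rows, ]
    sub <- sub[order(sub$age), ]
    sel <- qkey == k
    band <- findInterval(age[sel], sub$age)
    if (any(band == 0)) stop("attained age below the life table domain for ", k)
    out[sel] <- sub$rate[band]
  }
  out
}

#' Collapse survival records into person-time cells
#'
#' Splits each record's at-risk follow-up exactly at the annual anniversaries
#' of diagnosis into follow-up intervals `j = 1..max_followup_years` and at
#' the study-window boundaries, using day-precision durations (person-years =
#' days / 365.25). Each cell is indexed by broad age group at diagnosis `k`,
#' follow-up interval `j`, and area `i`, and accumulates person-years `y`,
#' observed deaths `d`, and expected background deaths
#' `dstar = sum(segment person-time * life-table rate)`, the rate looked up
#' at the person's attained age and calendar year at the segment midpoint.
#'
#' @param records Included records, as returned by
#'   [apply_survival_exclusions()].
#' @param life_table See [life_table_rate()].
#' @param broad_age_breaks Lower bounds of the broad age groups at diagnosis
#'   (default `c(0, 60, 70, 80)`, i.e. <60, 60-69, 70-79, 80-89).
#' @param window_start,window_end Study window bounds (dates).
#' @param max_followup_years Follow-up cap (default 5).
#' @return A tibble with columns `area_id`, `age_band` (k), `fu_year` (j),
#'   `y` (person-years), `d` (deaths), `dstar` (expected background deaths).
#' @export
collapse_person_time <- function(records, life_table,
                                 broad_age_breaks = c(0, 60, 70, 80),
                                 window_start, window_end,
                                 max_followup_years = 5) {
  records <- tibble::as_tibble(records)
  records$diag_date <- .as_date(records$diag_date)
  records$exit_date <- .as_date(records$exit_date)
  window_start <- .as_date(window_start)
  window_end <- .as_date(window_end)
  n_rec <- nrow(records)
  if (n_rec == 0L) stop("no records to collapse")

  diag_num <- as.numeric(records$diag_date)
  exit_num <- as.numeric(records$exit_date)
  # follow-up position (years since diagnosis) of the at-risk span
  s_start <- pmax(as.numeric(window_start) - diag_num, 0) / 365.25
  s_stop <- pmin(exit_num, as.numeric(window_end)) - diag_num
  s_stop <- pmin(s_stop / 365.25, max_followup_years)
  # death only counts if the exit is a death inside the at-risk span
  death_time <- ifelse(
    records$died &
      exit_num <= as.numeric(window_end) &
      (exit_num - diag_num) / 365.25 <= max_followup_years,
    (exit_num - diag_num) / 365.25, NA_real_)

  k_band <- findInterval(records$age_years, sort(broad_age_breaks))
  if (any(k_band == 0)) stop("age at diagnosis below the first broad age break")
  band_labels <- {
    b <- sort(broad_age_breaks)
    up <- c(b[-1] - 1, Inf)
    ifelse(is.finite(up), paste0(b, "-", up), paste0(b, "+"))
  }

  segs <- tidyr::expand_grid(rec = seq_len(n_rec), j = seq_len(max_followup_years)) |>
    dplyr::mutate(
      lo = pmax(s_start[.data$rec], .data$j - 1),
      hi = pmin(s_stop[.data$rec], .data$j)
    ) |>
    dplyr::filter(.data$hi > .data$lo)
  if (nrow(segs) == 0L) stop("records contribute no at-risk person-time")

  mid <- (segs$lo + segs$hi) / 2
  rec <- segs$rec
  attained_age <- records$age_years[rec] + mid
  mid_year <- as.integer(format(
    as.Date(diag_num[rec] + mid * 365.25, origin = "1970-01-01"), "%Y"))
  rate <- life_table_rate(life_table, records$sex[rec], attained_age, mid_year)

  segs |>
    dplyr::mutate(
      area_id = records$area_id[rec],
      age_band = band_labels[k_band[rec]],
      py = .data$hi - .data$lo,
      death = as.integer(!is.na(death_time[rec]) &
                           abs(death_time[rec] - .data$hi) < 1e-12),
      dstar = .data$py * rate
    ) |>
    dplyr::group_by(.data$area_id, .data$age_band, fu_year = .data$j) |>
    dplyr::summarise(y = sum(.data$py), d = sum(.data$death),
                     dstar = sum(.data$dstar), .groups = "drop")
}
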