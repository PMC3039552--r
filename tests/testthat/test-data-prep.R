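make_toy_inputs <- function() {
  # 3 areas x 2 age groups x 1 sex, rates differing by age
  cases <- tibble::tibble(
    area_id = rep(c("a", "b", "c"), each = 2),
    sex = "male",
    age_group = rep(c("young", "old"), 3),
    year = 2000,
    n = c(2, 6, 1, 3, 3, 9))
  pops <- tibble::tibble(
    area_id = rep(c("a", "b", "c"), each = 2),
    sex = "male",
    age_group = rep(c("young", "old"), 3),
    year = 2000,
    person_years = c(1000, 500, 800, 200, 1200, 700))
  list(cases = cases, pops = pops)
}

test_that("expected counts match a by-hand indirect standardisation", {
  toy <- make_toy_inputs()
  out <- expected_incidence_counts(toy$cases, toy$pops)
  # hand-computed pooled rates
  r_young <- (2 + 1 + 3) / (1000 + 800 + 1200)
  r_old <- (6 + 3 + 9) / (500 + 200 + 700)
  e_hand <- c(a = r_young * 1000 + r_old * 500,
              b = r_young * 800 + r_old * 200,
              c = r_young * 1200 + r_old * 700)
  expect_equal(out$e[match(names(e_hand), out$area_id)], unname(e_hand))
  expect_equal(sum(out$e), sum(out$y))  # internal standardisation balances
})

test_that("identical areas give expected counts proportional to population", {
  pops <- tibble::tibble(area_id = rep(c("a", "b"), each = 1), sex = "f",
                         age_group = "all", year = 2000,
                         person_years = c(100, 300))
  cases <- tibble::tibble(area_id = c("a", "b"), sex = "f", age_group = "all",
                          year = 2000, n = c(10, 30))
  out <- expected_incidence_counts(cases, pops)
  expect_equal(out$e, out$y)  # raw SIR exactly 1 everywhere
  expect_equal(out$e[2] / out$e[1], 3)
})

test_that("an area holding all the population gets the whole expected total", {
  pops <- tibble::tibble(area_id = c("a", "b"), sex = "f", age_group = "all",
                         year = 2000, person_years = c(500, 0))
  cases <- tibble::tibble(area_id = "a", sex = "f", age_group = "all",
                          year = 2000, n = 42)
  out <- expected_incidence_counts(cases, pops)
  expect_equal(out$e[out$area_id == "a"], 42)
})

test_that("cases in a zero-population stratum are rejected", {
  pops <- tibble::tibble(area_id = "a", sex = "f", age_group = "all",
                         year = 2000, person_years = 0)
  cases <- tibble::tibble(area_id = "a", sex = "f", age_group = "all",
                          year = 2000, n = 1)
  expect_error(expected_incidence_counts(cases, pops), "zero population")
})

base_record <- function(...) {
  defaults <- list(area_id = "a", sex = "male", age_years = 60,
                   diag_date = "2000-06-15", exit_date = "2003-06-15",
                   died = TRUE, dco = FALSE, autopsy = FALSE)
  tibble::as_tibble(utils::modifyList(defaults, list(...)))
}

test_that("survival exclusion rules drop the right records for the right reasons", {
  recs <- dplyr::bind_rows(
    base_record(),                                    # included
    base_record(age_years = 92),                      # age
    base_record(dco = TRUE),                          # death certificate only
    base_record(autopsy = TRUE),                      # autopsy only
    base_record(exit_date = "2000-06-15"),            # zero survival
    base_record(diag_date = "1996-03-01",             # pre-window diagnosis,
                exit_date = "1999-05-01"),            # alive into the window
    base_record(diag_date = "1990-01-01",             # >5y follow-up finished
                exit_date = "1991-01-01"))            # before the window
  out <- apply_survival_exclusions(recs, "1998-01-01", "2007-12-31")
  tally <- tibble::deframe(out$tally)
  expect_equal(unname(tally["included"]), 2L)
  expect_equal(unname(tally["age"]), 1L)
  expect_equal(unname(tally["death_certificate_only"]), 1L)
  expect_equal(unname(tally["autopsy_only"]), 1L)
  expect_equal(unname(tally["zero_survival"]), 1L)
  expect_equal(unname(tally["no_time_at_risk"]), 1L)
  expect_true("1996-03-01" %in% as.character(out$records$diag_date))
})

test_that("an exit before diagnosis without a death flag is corrupt", {
  recs <- base_record(exit_date = "1999-01-01", died = FALSE)
  expect_error(apply_survival_exclusions(recs, "1998-01-01", "2007-12-31"),
               "corrupt")
})

flat_life_table <- function(rate, years = 1995:2013) {
  tidyr::expand_grid(sex = c("female", "male"), age = seq(0, 85, 5),
                     year = years) |>
    dplyr::mutate(rate = rate)
}

test_that("follow-up splits exactly at anniversaries of diagnosis", {
  # survives ~2.5 years (913 days, the closest day count): person-years
  # 1.0 + 1.0 + remainder in j = 1, 2, 3
  days <- round(2.5 * 365.25)
  rec <- base_record(diag_date = "2000-01-01",
                     exit_date = as.Date("2000-01-01") + days)
  cells <- collapse_person_time(rec, flat_life_table(0),
                                window_start = "1998-01-01",
                                window_end = "2007-12-31")
  expect_equal(cells$fu_year, c(1, 2, 3))
  expect_equal(cells$y, c(1, 1, days / 365.25 - 2), tolerance = 1e-9)
  expect_equal(sum(cells$d), 1)
  expect_equal(cells$d[cells$fu_year == 3], 1)
  expect_equal(cells$dstar, c(0, 0, 0))
})

test_that("background deaths scale with the life-table rate", {
  rec <- base_record(diag_date = "2000-01-01", exit_date = "2002-01-01",
                     died = FALSE)
  c0 <- collapse_person_time(rec, flat_life_table(0),
                             window_start = "1998-01-01",
                             window_end = "2007-12-31")
  c1 <- collapse_person_time(rec, flat_life_table(0.02),
                             window_start = "1998-01-01",
                             window_end = "2007-12-31")
  expect_true(all(c0$dstar == 0))
  expect_equal(c1$dstar, c1$y * 0.02, tolerance = 1e-9)
  # d* monotonicity: a higher rate never decreases any cell's d*
  c2 <- collapse_person_time(rec, flat_life_table(0.05),
                             window_start = "1998-01-01",
                             window_end = "2007-12-31")
  expect_true(all(c2$dstar >= c1$dstar))
})

test_that("cell person-time agrees with an independent interval formula", {
  g <- lattice_graph(2, 2)
  sim <- simulate_populations_and_lifetable(g, seed = 4)
  sv <- simulate_survival_records(
    g, alpha_j = c(-1, -1.5, -2, -2.2, -2.5), beta_k = c(0, 0.5, 0.8, 1.2),
    populations = sim$populations, life_table = sim$life_table, n_cases = 20,
    window_start = "1998-01-01", window_end = "2007-12-31", seed = 9)
  inc <- apply_survival_exclusions(sv$records, "1998-01-01", "2007-12-31")
  cells <- collapse_person_time(inc$records, sim$life_table,
                                window_start = "1998-01-01",
                                window_end = "2007-12-31")
  r <- inc$records
  diag_n <- as.numeric(r$diag_date)
  s_start <- pmax(as.numeric(as.Date("1998-01-01")) - diag_n, 0) / 365.25
  s_stop <- pmin((pmin(as.numeric(r$exit_date),
                       as.numeric(as.Date("2007-12-31"))) - diag_n) / 365.25, 5)
  # independent per-interval overlap arithmetic, no grouping machinery
  for (j in 1:5) {
    y_j <- sum(pmax(0, pmin(s_stop, j) - pmax(s_start, j - 1)))
    expect_equal(sum(cells$y[cells$fu_year == j]), y_j, tolerance = 1e-6)
  }
  # person-time conservation across the whole partition
  expect_equal(sum(cells$y), sum(s_stop - s_start), tolerance = 1e-6)
  fu <- (as.numeric(r$exit_date) - diag_n) / 365.25
  expect_equal(sum(cells$d),
               sum(r$died & fu <= 5 &
                     as.numeric(r$exit_date) <=
                       as.numeric(as.Date("2007-12-31"))))
})

test_that("life-table lookups outside the domain are rejected", {
  lt <- flat_life_table(0.01, years = 2000:2001)
  expect_error(life_table_rate(lt, "male", 50, 1999), "no entry")
  rec <- base_record(diag_date = "2000-06-15", exit_date = "2003-06-15")
  expect_error(
    collapse_person_time(rec, lt, window_start = "1998-01-01",
                         window_end = "2007-12-31"),
    "no entry")
})
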