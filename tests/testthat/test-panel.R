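make_survey <- function(person_id, wave_years, status, birth_year = 1970L,
                        group = "b", eligible = FALSE) {
  data.frame(person_id = person_id, wave_year = wave_years,
             birth_year = birth_year, employment_status = status,
             group = group, perinatal_eligible = eligible,
             stringsAsFactors = FALSE)
}

test_that("a skipped survey wave drops exactly the years it covers", {
  sv <- make_survey("p1", c(2004L, 2006L, 2008L),
                    c("employed", NA, "employed"))
  rec <- data.frame(person_id = "p1",
                    service_date = c("2004-03-01", "2006-05-01", "2009-07-01"),
                    item_code = 23L)
  panel <- build_panel(rec, sv)
  expect_setequal(panel$year, c(2004L, 2005L, 2008L, 2009L))
  expect_equal(panel$count[panel$year == 2004], 1L)
  expect_equal(panel$count[panel$year == 2009], 1L)
  expect_equal(panel$count[panel$year == 2005], 0L)
})

test_that("persons with no claims are retained with zero counts", {
  sv <- make_survey(c("p1", "p2"), 2004L, "employed")
  rec <- data.frame(person_id = "p1", service_date = "2004-03-01",
                    item_code = 23L)
  panel <- build_panel(rec, sv)
  expect_setequal(panel$person_id, c("p1", "p2"))
  expect_equal(sum(panel$count[panel$person_id == "p2"]), 0L)
  expect_true(all(panel$age == panel$year - panel$birth_year))
})

test_that("orphan claimants are excluded with a warning; inconsistent birth years are an error", {
  sv <- make_survey("p1", 2004L, "employed")
  rec <- data.frame(person_id = c("p1", "ghost"),
                    service_date = "2004-03-01", item_code = 23L)
  expect_warning(panel <- build_panel(rec, sv), "ghost")
  expect_setequal(panel$person_id, "p1")

  sv_bad <- make_survey("p1", c(2004L, 2006L), "employed",
                        birth_year = c(1970L, 1971L))
  expect_error(build_panel(rec[1L, ], sv_bad), "inconsistent birth_year")
})

test_that("panel counts equal an independent per-year episode tally", {
  sim <- small_panel(n_persons = 50L, seed = 31)
  recs <- panel_to_records(sim$panel, gap_days = 1, seed = 5)
  sv <- panel_to_survey(sim$panel)
  panel <- build_panel(recs, sv, gap_days = 1)

  # brute-force tally: collapse each person's dates by hand and count starts
  for (pid in unique(panel$person_id)) {
    dates <- sort(unique(as.Date(recs$service_date[
      recs$person_id == pid & recs$item_code %in% default_gp_items()])))
    if (!length(dates)) next
    runs <- split(dates, cumsum(c(TRUE, diff(dates) > 1)))
    starts <- as.integer(format(as.Date(
      vapply(runs, function(r) format(min(r)), character(1L))), "%Y"))
    for (yr in unique(panel$year[panel$person_id == pid])) {
      expect_equal(panel$count[panel$person_id == pid & panel$year == yr],
                   sum(starts == yr),
                   info = paste(pid, yr))
    }
  }

  # total counts add up over the retained person-years
  expect_equal(sum(panel$count), sum(sim$panel$count))
})

test_that("the perinatal flag propagates from emitted codes within the window", {
  sc <- apc_scenario(n_persons = 40L, perinatal_eligible = TRUE,
                     perinatal_rate = 0.3, seed = 12)
  sim <- simulate_panel(sc)
  recs <- panel_to_records(sim$panel, seed = 3)
  sv <- panel_to_survey(sim$panel)
  panel <- build_panel(recs, sv)
  key <- paste(panel$person_id, panel$year)
  skey <- paste(sim$panel$person_id, sim$panel$year)
  # every originally flagged person-year must be flagged after the round trip
  flagged <- skey[sim$panel$perinatal]
  expect_true(all(panel$perinatal[key %in% flagged]))
  # flags only appear for eligible persons
  elig <- unique(sim$panel$person_id[sim$panel$perinatal])
  expect_true(all(panel$person_id[panel$perinatal] %in% elig))
})
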