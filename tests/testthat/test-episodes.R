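test_that("item filtering keeps exactly the whitelisted codes, in order", {
  rec <- data.frame(
    person_id = "a",
    service_date = c("2004-01-10", "2004-02-01", "2004-03-05"),
    item_code = c(23L, 16500L, 104L)
  )
  out <- filter_items(rec, whitelist = 23)
  expect_equal(out$item_code, 23L)

  # whitelist covering everything is the identity
  expect_equal(filter_items(rec, c(23, 16500, 104)), rec)

  expect_error(filter_items(rec, integer()), "non-empty")
})

test_that("item filtering matches a brute-force membership scan", {
  set.seed(71)
  rec <- data.frame(
    person_id = sample(letters, 1000, replace = TRUE),
    service_date = format(random_dates(1000, seed = 2), "%Y-%m-%d"),
    item_code = sample(c(3L, 23L, 36L, 104L, 16500L, 721L), 1000,
                       replace = TRUE)
  )
  wl <- c(23L, 104L, 721L)
  keep <- vapply(seq_len(nrow(rec)),
                 function(i) rec$item_code[i] %in% wl, logical(1L))
  expect_equal(filter_items(rec, wl), rec[keep, ])
})

test_that("consecutive-day claims collapse into the printed worked examples", {
  one <- collapse_episodes(c("2004-01-01", "2004-01-02", "2004-01-03"),
                           gap_days = 1)
  expect_equal(nrow(one), 1L)
  expect_equal(one$start_date, as.Date("2004-01-01"))
  expect_equal(one$end_date, as.Date("2004-01-03"))

  two <- collapse_episodes(c("2004-01-01", "2004-01-02", "2004-01-04"),
                           gap_days = 1)
  expect_equal(nrow(two), 2L)

  # the 30-day sensitivity rule merges the same dates into one episode
  expect_equal(nrow(collapse_episodes(
    c("2004-01-01", "2004-01-02", "2004-01-04"), gap_days = 30)), 1L)
})

test_that("episode collapsing equals the union-find oracle on random instances", {
  set.seed(100)
  for (case in seq_len(200L)) {
    n <- sample(1:25, 1L)
    dates <- as.Date("2004-01-01") + sample.int(400L, n, replace = TRUE)
    gap <- sample(c(1L, 5L, 30L), 1L)
    expect_equal(nrow(collapse_episodes(dates, gap)),
                 oracle_episode_count(dates, gap),
                 info = paste("case", case, "gap", gap))
  }
})

test_that("episode collapsing is order/duplication invariant with valid bounds", {
  set.seed(7)
  for (rep in 1:25) {
    dates <- as.Date("2004-01-01") + sample.int(300L, 12, replace = TRUE)
    base <- collapse_episodes(dates, 1)
    shuffled <- collapse_episodes(sample(c(dates, dates)), 1)
    expect_equal(base, shuffled)
    nd <- length(unique(dates))
    expect_gte(nrow(base), 1L)
    expect_lte(nrow(base), nd)
    # episode count is non-increasing in gap_days
    counts <- vapply(c(1L, 5L, 15L, 30L),
                     function(g) nrow(collapse_episodes(dates, g)),
                     integer(1L))
    expect_true(all(diff(counts) <= 0L))
  }
  expect_equal(nrow(collapse_episodes(character())), 0L)
  expect_error(collapse_episodes(c("2004-01-01", "not-a-date")),
               "not-a-date")
})

test_that("episodes of one person are separated by more than the gap", {
  set.seed(11)
  dates <- as.Date("2004-01-01") + sample.int(200L, 40, replace = TRUE)
  for (gap in c(1L, 7L, 30L)) {
    ep <- collapse_episodes(dates, gap)
    expect_true(all(ep$start_date <= ep$end_date))
    if (nrow(ep) > 1L) {
      sep <- as.integer(ep$start_date[-1L]) -
        as.integer(ep$end_date[-nrow(ep)])
      expect_true(all(sep > gap))
    }
  }
})

test_that("peri-natal indicator follows the code range and two-year window", {
  rec <- function(code, date) {
    data.frame(person_id = "w", service_date = date, item_code = code)
  }
  expect_true(perinatal_indicator(rec(16500L, "2003-06-01"), year = 2004))
  expect_true(perinatal_indicator(rec(16400L, "2004-02-01"), year = 2004))
  expect_true(perinatal_indicator(rec(16573L, "2004-02-01"), year = 2004))
  expect_false(perinatal_indicator(rec(16500L, "2001-06-01"), year = 2004))
  expect_false(perinatal_indicator(rec(16500L, "2005-01-01"), year = 2004))
  expect_false(perinatal_indicator(rec(16399L, "2004-06-01"), year = 2004))
  expect_false(perinatal_indicator(rec(16574L, "2004-06-01"), year = 2004))
})
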