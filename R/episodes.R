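#' Filter claim records to a schedule-item whitelist
#'
#' Restricts claim-level service records to the item codes used by general
#' practitioners for billing, excluding hospital procedures and specialist
#' services. The whitelist is the operational definition of "a GP visit".
#'
#' @param records Data frame with at least columns `person_id`,
#'   `service_date`, `item_code`.
#' @param whitelist Non-empty vector of integer schedule item codes to keep.
#'
#' @return The subset of `records` whose `item_code` is in `whitelist`, in
#'   the original row order.
#' @seealso [default_gp_items()], [build_panel()]
#' @export
#' @examples
#' rec <- data.frame(person_id = "a",
#'                   service_date = c("2004-01-10", "2004-02-01"),
#'                   item_code = c(23L, 16500L))
#' filter_items(rec, whitelist = 23)
filter_items <- function(records, whitelist) {
  records <- validate_records(records)
  if (length(whitelist) == 0L) {
    stop("'whitelist' must be a non-empty set of item codes", call. = FALSE)
  }
  records[records$item_code %in% as.integer(whitelist), , drop = FALSE]
}

#' Example GP schedule-item whitelist
#'
#' A small set of Medicare Benefits Schedule style attendance item numbers
#' used as the packaged default whitelist for GP consultations. Real analyses
#' should supply the full item list appropriate to their claims extract.
#'
#' @return Integer vector of item codes.
#' @export
default_gp_items <- function() {
  c(3L, 23L, 36L, 44L, 52L, 53L, 54L, 57L, 5000L, 5020L, 5040L, 5060L)
}

#' Collapse service dates into episodes of care
#'
#' Service records occurring on the same day or within `gap_days` days of
#' each other are treated as a single episode of care: the dates are sorted,
#' de-duplicated, and maximal runs whose consecutive gaps are all at most
#' `gap_days` become one episode. With the default `gap_days = 1`,
#' consecutive-day claims merge: visits on Jan 01, Jan 02 and Jan 03 form
#' one episode, while Jan 01, Jan 02 and Jan 04 form two. `gap_days = 30`
#' gives the coarser 30-day episode measure used for sensitivity analysis.
#'
#' @param dates Vector of calendar dates for one person: `Date` values or
#'   ISO 8601 (`YYYY-MM-DD`) strings. May be empty.
#' @param gap_days Positive integer; maximal within-episode gap in whole
#'   days. Default 1 (consecutive-day rule).
#'
#' @return Data frame with columns `start_date`, `end_date` (class `Date`),
#'   one row per episode, ordered by `start_date`. Zero rows if `dates` is
#'   empty.
#' @export
#' @examples
#' collapse_episodes(c("2004-01-01", "2004-01-02", "2004-01-03"))  # 1 episode
#' collapse_episodes(c("2004-01-01", "2004-01-02", "2004-01-04"))  # 2 episodes
collapse_episodes <- function(dates, gap_days = 1L) {
  gap_days <- as.integer(gap_days)
  if (length(gap_days) != 1L || is.na(gap_days) || gap_days < 1L) {
    stop("'gap_days' must be a single integer >= 1", call. = FALSE)
  }
  d <- parse_dates(dates)
  if (length(d) == 0L) {
    return(data.frame(start_date = as.Date(character()),
                      end_date = as.Date(character())))
  }
  d <- sort(unique(d))
  gaps <- diff(as.integer(d))
  new_episode <- c(TRUE, gaps > gap_days)
  id <- cumsum(new_episode)
  data.frame(
    start_date = d[new_episode],
    end_date = as.Date(as.vector(tapply(as.integer(d), id, max)),
                       origin = "1970-01-01"),
    row.names = NULL
  )
}

#' Peri-natal service indicator
#'
#' Flags whether any claim with an item code in the ante-/peri-natal range
#' (Medicare items 16400 to 16573 by default) was recorded in the queried
#' calendar year or the year before. Used as a binary adjustment covariate
#' for women, to separate childbirth-related service use from routine GP
#' engagement.
#'
#' @param records Data frame of claim records for one person (columns
#'   `service_date`, `item_code`).
#' @param year Calendar year of the interview/panel row.
#' @param code_range Inclusive integer interval of peri-natal item codes.
#'
#' @return `TRUE` if any matching record falls in `year` or `year - 1`.
#' @export
perinatal_indicator <- function(records, year, code_range = c(16400L, 16573L)) {
  records <- validate_records(records)
  year <- as.integer(year)
  stopifnot(length(year) == 1L, !is.na(year), length(code_range) == 2L)
  if (nrow(records) == 0L) return(FALSE)
  code_ok <- records$item_code >= code_range[1L] & records$item_code <= code_range[2L]
  if (!any(code_ok)) return(FALSE)
  yr <- year_of(parse_dates(records$service_date[code_ok]))
  any(yr == year | yr == year - 1L)
}

# -- internal helpers ---------------------------------------------------------

# Parse ISO-8601 date input; error names the offending values.
parse_dates <- function(dates) {
  if (inherits(dates, "Date")) {
    if (anyNA(dates)) stop("missing (NA) service dates", call. = FALSE)
    return(dates)
  }
  d <- as.Date(as.character(dates), format = "%Y-%m-%d")
  bad <- is.na(d) & !is.na(dates)
  if (any(bad) || anyNA(dates)) {
    offending <- unique(as.character(dates[is.na(d)]))
    stop("unparseable service dates (expected YYYY-MM-DD): ",
         paste(utils::head(offending, 5L), collapse = ", "), call. = FALSE)
  }
  d
}

year_of <- function(d) as.integer(format(d, "%Y"))

validate_records <- function(records) {
  if (!is.data.frame(records)) {
    stop("'records' must be a data frame", call. = FALSE)
  }
  need <- c("person_id", "service_date", "item_code")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("'records' is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records)) {
    records$item_code <- as.integer(records$item_code)
    if (anyNA(records$item_code) || any(records$item_code <= 0L)) {
      stop("'item_code' must be positive integers", call. = FALSE)
    }
  }
  records
}
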