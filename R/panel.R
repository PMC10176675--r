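#' Build the person-year analysis panel
#'
#' Turns claim-level service records and survey responses into the
#' person-year panel analysed by [apc_fit()]. Claim lines are restricted to
#' the GP item whitelist, collapsed into episodes of care (see
#' [collapse_episodes()]), and counted by the calendar year of the episode
#' start date. A person-year enters the panel only when the survey wave
#' covering that year reports an employment status ("complete information"):
#' a person who reported employment in the 2004 and 2008 waves but skipped
#' 2006 contributes 2004-2005 and 2008-2009 rows, but not 2006-2007.
#' Persons with zero claims but complete survey responses are retained with
#' count zero. The peri-natal indicator is evaluated (against the full,
#' unfiltered record set) only for persons whose survey rows are flagged
#' `perinatal_eligible`.
#'
#' @param records Data frame of claim lines: columns `person_id`,
#'   `service_date` (ISO 8601), `item_code`.
#' @param survey Data frame of survey responses: columns `person_id`,
#'   `wave_year`, `birth_year`, `employment_status` (one of `"employed"`,
#'   `"unemployed"`, `"nilf"`, or `NA` when not reported), and optionally
#'   `group` and `perinatal_eligible`.
#' @param items Item-code whitelist defining a GP visit; defaults to the
#'   packaged example list [default_gp_items()].
#' @param gap_days Episode collapse threshold in days (1 primary, 30 for
#'   the sensitivity measure).
#' @param year_range Length-2 inclusive calendar-year range retained in the
#'   panel; the terminal incomplete year of an extract should be excluded
#'   here.
#' @param wave_coverage Number of consecutive calendar years covered by one
#'   survey wave, starting at `wave_year`. Default 2 (biennial waves; the
#'   even-year wave covers that year and the next).
#'
#' @return Data frame of class `c("apc_panel", "data.frame")` with columns
#'   `person_id`, `year`, `birth_year`, `age`, `employment_status`,
#'   `perinatal`, `count`, `group`, sorted by person then year. `age` always
#'   equals `year - birth_year`.
#' @export
build_panel <- function(records, survey,
                        items = default_gp_items(),
                        gap_days = 1L,
                        year_range = c(2002L, 2016L),
                        wave_coverage = 2L) {
  records <- validate_records(records)
  survey <- validate_survey(survey)
  year_range <- as.integer(year_range)
  stopifnot(length(year_range) == 2L, year_range[1L] <= year_range[2L])
  wave_coverage <- as.integer(wave_coverage)
  stopifnot(wave_coverage >= 1L)

  # birth-year consistency per person is a hard error
  by_tab <- unique(survey[, c("person_id", "birth_year")])
  if (anyDuplicated(by_tab$person_id)) {
    dup <- unique(by_tab$person_id[duplicated(by_tab$person_id)])
    stop("inconsistent birth_year across survey rows for person(s): ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }

  orphan <- setdiff(unique(records$person_id), unique(survey$person_id))
  if (length(orphan)) {
    warning(length(orphan), " person(s) present in records but absent from ",
            "survey were excluded: ",
            paste(utils::head(orphan, 5L), collapse = ", "), call. = FALSE)
    records <- records[!(records$person_id %in% orphan), , drop = FALSE]
  }

  gp <- filter_items(records, items)
  gp$service_date <- parse_dates(gp$service_date)
  records$service_date <- parse_dates(records$service_date)

  # episode tally per person x start-year
  tally <- new.env(parent = emptyenv())
  if (nrow(gp)) {
    for (pid in unique(gp$person_id)) {
      ep <- collapse_episodes(gp$service_date[gp$person_id == pid], gap_days)
      yrs <- year_of(ep$start_date)
      assign(as.character(pid), table(yrs), envir = tally)
    }
  }

  # expand survey waves with reported employment into covered person-years
  keep <- !is.na(survey$employment_status)
  sv <- survey[keep, , drop = FALSE]
  rows <- vector("list", nrow(sv))
  for (i in seq_len(nrow(sv))) {
    yrs <- sv$wave_year[i] + 0:(wave_coverage - 1L)
    yrs <- yrs[yrs >= year_range[1L] & yrs <= year_range[2L]]
    if (!length(yrs)) next
    rows[[i]] <- data.frame(
      person_id = sv$person_id[i],
      year = yrs,
      birth_year = sv$birth_year[i],
      employment_status = sv$employment_status[i],
      group = sv$group[i],
      perinatal_eligible = sv$perinatal_eligible[i],
      stringsAsFactors = FALSE
    )
  }
  panel <- do.call(rbind, rows)
  if (is.null(panel) || nrow(panel) == 0L) {
    stop("no person-years with complete information inside 'year_range'",
         call. = FALSE)
  }
  if (anyDuplicated(panel[, c("person_id", "year")])) {
    stop("overlapping survey waves: duplicated person-year coverage",
         call. = FALSE)
  }

  panel$age <- panel$year - panel$birth_year
  panel$count <- 0L
  for (i in seq_len(nrow(panel))) {
    tb <- tally[[as.character(panel$person_id[i])]]
    if (!is.null(tb)) {
      hit <- tb[as.character(panel$year[i])]
      if (!is.na(hit)) panel$count[i] <- as.integer(hit)
    }
  }

  panel$perinatal <- FALSE
  elig <- which(panel$perinatal_eligible)
  for (i in elig) {
    rec_i <- records[records$person_id == panel$person_id[i], , drop = FALSE]
    panel$perinatal[i] <- perinatal_indicator(rec_i, panel$year[i])
  }

  panel <- panel[order(panel$person_id, panel$year),
                 c("person_id", "year", "birth_year", "age",
                   "employment_status", "perinatal", "count", "group")]
  rownames(panel) <- NULL
  class(panel) <- c("apc_panel", "data.frame")
  panel
}

validate_survey <- function(survey) {
  if (!is.data.frame(survey)) stop("'survey' must be a data frame", call. = FALSE)
  need <- c("person_id", "wave_year", "birth_year", "employment_status")
  miss <- setdiff(need, names(survey))
  if (length(miss)) {
    stop("'survey' is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  survey$wave_year <- as.integer(survey$wave_year)
  survey$birth_year <- as.integer(survey$birth_year)
  es <- as.character(survey$employment_status)
  es[!is.na(es) & es == ""] <- NA_character_
  bad <- !is.na(es) & !(es %in% c("employed", "unemployed", "nilf"))
  if (any(bad)) {
    stop("unknown employment_status value(s): ",
         paste(unique(es[bad]), collapse = ", "),
         " (expected employed/unemployed/nilf or NA)", call. = FALSE)
  }
  survey$employment_status <- es
  if (is.null(survey$group)) survey$group <- "all"
  if (is.null(survey$perinatal_eligible)) survey$perinatal_eligible <- FALSE
  survey$perinatal_eligible <- as.logical(survey$perinatal_eligible)
  survey
}

validate_panel <- function(panel) {
  if (!is.data.frame(panel)) stop("'panel' must be a data frame", call. = FALSE)
  need <- c("person_id", "year", "birth_year", "employment_status", "count")
  miss <- setdiff(need, names(panel))
  if (length(miss)) {
    stop("'panel' is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(panel$perinatal)) panel$perinatal <- FALSE
  if (is.null(panel$age)) panel$age <- panel$year - panel$birth_year
  if (any(panel$age != panel$year - panel$birth_year)) {
    stop("panel violates age = year - birth_year", call. = FALSE)
  }
  if (any(panel$count < 0)) stop("negative counts in panel", call. = FALSE)
  panel
}

#' Read and write panel CSV files
#'
#' Thin CSV wrappers for the panel interchange format (columns `person_id`,
#' `year`, `birth_year`, `age`, `employment_status`, `perinatal`, `count`,
#' `group`).
#'
#' @param path File path.
#' @param panel Panel data frame as produced by [build_panel()] or
#'   [simulate_panel()].
#' @return `read_panel` returns the panel data frame; `write_panel` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  panel <- validate_panel(panel)
  class(panel) <- c("apc_panel", "data.frame")
  panel
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE)
  invisible(path)
}
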