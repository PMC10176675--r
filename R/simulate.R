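#' Define a simulation scenario
#'
#' Collects the parameters of the synthetic data-generating process that
#' mirrors the structure assumed by the hierarchical Poisson model: counts
#' y_it ~ Poisson(mu_it) with log(mu_it) = alpha + u_i + g(C_i, t) +
#' beta_nilf * nilf_it + beta_unemployed * unemployed_it
#' (+ beta_perinatal * perinatal_it for the eligible stratum), with person
#' frailty u_i ~ N(0, sigma_u) on the log scale.
#'
#' Defaults emulate a male parental panel of the linked survey-claims study
#' design: biennial survey waves over 2002-2016, birth years 1950-1985, a
#' baseline rate of 3 visits per year, about 94% employed with first-order
#' Markov persistence, and a 10% chance of skipping any given wave.
#'
#' @param n_persons Number of persons.
#' @param year_range Inclusive calendar-year range of the panel.
#' @param birth_year_range Inclusive birth-year (cohort) range; birth years
#'   are drawn uniformly.
#' @param alpha Log baseline rate for the reference person (employed, no
#'   peri-natal services, u = 0) at g = 0.
#' @param surface Ground-truth log-rate surface: a name accepted by
#'   [builtin_surface()] or a vectorised function g(C, t).
#' @param sigma_u Standard deviation of the Normal person frailty on the
#'   log scale (>= 0).
#' @param beta_nilf,beta_unemployed,beta_perinatal Log relative rates for
#'   not-in-labour-force, unemployed, and peri-natal status. Defaults
#'   log(1.12), log(1.02), log(1.06).
#' @param employment_stationary Named probabilities of
#'   employed/unemployed/nilf; the stationary distribution of the
#'   employment Markov chain.
#' @param employment_persistence Probability of keeping the previous wave's
#'   status; with probability 1 - persistence a fresh draw from the
#'   stationary distribution is made (first-order Markov dynamics).
#' @param perinatal_eligible Logical: does this stratum (e.g. women) have
#'   peri-natal indicator events?
#' @param perinatal_rate Per person-year probability of a peri-natal flag in
#'   the eligible stratum.
#' @param missing_wave_prob Probability a person skips any given survey
#'   wave (those person-years drop out of the panel).
#' @param group Stratum label carried through to the panel.
#' @param seed Integer seed; all randomness flows through it.
#'
#' @return A list of class `apc_scenario`.
#' @seealso [simulate_panel()], [builtin_surface()]
#' @export
apc_scenario <- function(n_persons = 1000L,
                         year_range = c(2002L, 2016L),
                         birth_year_range = c(1950L, 1985L),
                         alpha = log(3),
                         surface = "flat",
                         sigma_u = 0.5,
                         beta_nilf = log(1.12),
                         beta_unemployed = log(1.02),
                         beta_perinatal = log(1.06),
                         employment_stationary = c(employed = 0.94,
                                                   unemployed = 0.02,
                                                   nilf = 0.04),
                         employment_persistence = 0.8,
                         perinatal_eligible = FALSE,
                         perinatal_rate = 0.1,
                         missing_wave_prob = 0.1,
                         group = "synthetic",
                         seed = 1L) {
  if (is.character(surface)) surface <- builtin_surface(surface)
  stopifnot(is.function(surface))
  sc <- list(
    n_persons = as.integer(n_persons),
    year_range = as.integer(year_range),
    birth_year_range = as.integer(birth_year_range),
    alpha = alpha, surface = surface, sigma_u = sigma_u,
    beta_nilf = beta_nilf, beta_unemployed = beta_unemployed,
    beta_perinatal = beta_perinatal,
    employment_stationary = employment_stationary,
    employment_persistence = employment_persistence,
    perinatal_eligible = isTRUE(perinatal_eligible),
    perinatal_rate = perinatal_rate,
    missing_wave_prob = missing_wave_prob,
    group = group, seed = as.integer(seed)
  )
  with(sc, {
    stopifnot(n_persons >= 1L,
              length(year_range) == 2L, year_range[1L] <= year_range[2L],
              length(birth_year_range) == 2L,
              birth_year_range[1L] <= birth_year_range[2L],
              sigma_u >= 0,
              employment_persistence >= 0, employment_persistence <= 1,
              perinatal_rate >= 0, perinatal_rate <= 1,
              missing_wave_prob >= 0, missing_wave_prob <= 1)
    if (!setequal(names(employment_stationary),
                  c("employed", "unemployed", "nilf")) ||
        any(employment_stationary < 0) ||
        abs(sum(employment_stationary) - 1) > 1e-8) {
      stop("'employment_stationary' must be probabilities over ",
           "employed/unemployed/nilf summing to 1", call. = FALSE)
    }
  })
  class(sc) <- "apc_scenario"
  sc
}

#' Read a simulation scenario from a YAML file
#'
#' Flat key-value YAML mirroring the arguments of [apc_scenario()]; the
#' `surface` entry is a [builtin_surface()] name.
#'
#' @param path YAML file path.
#' @return An `apc_scenario` object.
#' @export
read_scenario <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading scenario files requires the 'yaml' package", call. = FALSE)
  }
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$employment_stationary)) {
    vals$employment_stationary <- unlist(vals$employment_stationary)
  }
  do.call(apc_scenario, vals)
}

#' Simulate a person-year panel with known ground truth
#'
#' Draws a synthetic analysis panel from the generative model described in
#' [apc_scenario()]: uniform birth years, Normal log-scale person frailty,
#' a first-order Markov employment chain over biennial survey waves,
#' Bernoulli peri-natal flags in the eligible stratum, Poisson counts with
#' the exact linear predictor, and wave skipping that removes the covered
#' person-years. Deterministic given the scenario seed; the global RNG
#' state is left untouched.
#'
#' @param scenario An `apc_scenario` object.
#'
#' @return A list with elements `panel` (person-year data frame as from
#'   [build_panel()], plus a `mu` column of true means) and `truth` (list:
#'   `u` named per-person frailty draws, `surface` function, `surface_grid`
#'   data frame of g on the cohort x period grid, and the scenario).
#' @export
simulate_panel <- function(scenario) {
  stopifnot(inherits(scenario, "apc_scenario"))
  sc <- scenario
  with_seed(sc$seed, {
    yrs <- sc$year_range[1L]:sc$year_range[2L]
    wave_years <- yrs[yrs %% 2L == 0L]
    if (!length(wave_years)) wave_years <- yrs[1L]
    ids <- sprintf("p%05d", seq_len(sc$n_persons))
    birth <- sample(sc$birth_year_range[1L]:sc$birth_year_range[2L],
                    sc$n_persons, replace = TRUE)
    u <- stats::rnorm(sc$n_persons, 0, sc$sigma_u)
    names(u) <- ids

    statuses <- c("employed", "unemployed", "nilf")
    p_stat <- sc$employment_stationary[statuses]

    rows <- vector("list", sc$n_persons)
    for (i in seq_len(sc$n_persons)) {
      # employment Markov chain over waves
      st <- character(length(wave_years))
      st[1L] <- sample(statuses, 1L, prob = p_stat)
      for (w in seq_along(wave_years)[-1L]) {
        st[w] <- if (stats::runif(1) < sc$employment_persistence) st[w - 1L]
                 else sample(statuses, 1L, prob = p_stat)
      }
      attended <- stats::runif(length(wave_years)) >= sc$missing_wave_prob
      if (!any(attended)) attended[sample(length(wave_years), 1L)] <- TRUE
      w_idx <- rep(seq_along(wave_years), each = 2L)
      yr <- rep(wave_years, each = 2L) + c(0L, 1L)
      keep <- attended[w_idx] & yr >= sc$year_range[1L] & yr <= sc$year_range[2L]
      if (!any(keep)) next
      rows[[i]] <- data.frame(
        person_id = ids[i], year = yr[keep], birth_year = birth[i],
        employment_status = st[w_idx][keep], stringsAsFactors = FALSE
      )
    }
    panel <- do.call(rbind, rows)
    panel$age <- panel$year - panel$birth_year
    panel$perinatal <- if (sc$perinatal_eligible) {
      stats::runif(nrow(panel)) < sc$perinatal_rate
    } else FALSE
    panel$group <- sc$group

    g <- sc$surface
    eta <- sc$alpha + u[panel$person_id] +
      g(panel$birth_year, panel$year) +
      sc$beta_nilf * (panel$employment_status == "nilf") +
      sc$beta_unemployed * (panel$employment_status == "unemployed") +
      sc$beta_perinatal * panel$perinatal
    panel$mu <- exp(eta)
    panel$count <- stats::rpois(nrow(panel), panel$mu)

    panel <- panel[order(panel$person_id, panel$year),
                   c("person_id", "year", "birth_year", "age",
                     "employment_status", "perinatal", "count", "group", "mu")]
    rownames(panel) <- NULL
    class(panel) <- c("apc_panel", "data.frame")

    grid <- expand.grid(
      birth_year = sc$birth_year_range[1L]:sc$birth_year_range[2L],
      year = yrs
    )
    grid$g <- g(grid$birth_year, grid$year)

    list(panel = panel,
         truth = list(u = u, surface = g, surface_grid = grid,
                      scenario = sc))
  })
}

#' Expand a panel back into claim-level records
#'
#' Inverse of [build_panel()] for end-to-end testing: each person-year with
#' count k receives k episode start dates inside that year, spaced far
#' enough apart (and far enough from year boundaries) that episode
#' collapsing at the same `gap_days` can never merge them, each expanded
#' into 1-3 same-or-consecutive-day claim lines with whitelisted item
#' codes. Person-years flagged `perinatal` additionally emit one claim with
#' an item code in the peri-natal range. Round-tripping through
#' [build_panel()] with the same `gap_days` recovers the original counts
#' exactly.
#'
#' @param panel Person-year panel data frame.
#' @param gap_days Episode threshold the records must survive unchanged.
#' @param items GP item whitelist to draw codes from; must not overlap the
#'   peri-natal range.
#' @param seed Integer seed.
#'
#' @return Data frame of claim lines (`person_id`, `service_date`,
#'   `item_code`). Counts too large to place in one year are truncated with
#'   a warning (only reachable at extreme counts).
#' @seealso [panel_to_survey()]
#' @export
panel_to_records <- function(panel, gap_days = 1L, items = default_gp_items(),
                             seed = 1L) {
  panel <- validate_panel(panel)
  gap_days <- as.integer(gap_days)
  stopifnot(gap_days >= 1L)
  geo <- episode_geometry(gap_days)
  s <- geo$spacing
  margin_lead <- geo$margin_lead
  margin_tail <- geo$margin_tail
  usable <- geo$usable
  max_k <- geo$max_k

  with_seed(seed, {
    out <- vector("list", nrow(panel))
    truncated <- 0L
    for (i in seq_len(nrow(panel))) {
      k <- panel$count[i]
      if (k > max_k) { truncated <- truncated + 1L; k <- max_k }
      recs <- NULL
      if (k > 0L) {
        # k sorted starts with successive gaps >= s, uniform via stars-and-bars
        slack <- usable - 3L - (k - 1L) * s
        base <- sort(sample.int(slack + 1L, k, replace = TRUE)) - 1L
        starts <- margin_lead + base + (seq_len(k) - 1L) * s
        day0 <- as.Date(sprintf("%d-01-01", panel$year[i])) - 1L
        claim_days <- unlist(lapply(starts, function(d) {
          d + 0:(sample.int(3L, 1L) - 1L)
        }))
        recs <- data.frame(
          person_id = panel$person_id[i],
          service_date = day0 + claim_days,
          item_code = sample(as.integer(items), length(claim_days),
                             replace = TRUE),
          stringsAsFactors = FALSE
        )
      }
      if (isTRUE(panel$perinatal[i])) {
        peri <- data.frame(
          person_id = panel$person_id[i],
          service_date = as.Date(sprintf("%d-01-01", panel$year[i])) - 1L +
            sample(margin_lead:(365L - margin_tail), 1L),
          item_code = sample(16400:16573, 1L),
          stringsAsFactors = FALSE
        )
        recs <- rbind(recs, peri)
      }
      out[[i]] <- recs
    }
    if (truncated > 0L) {
      warning(truncated, " person-year(s) had counts too large to place as ",
              "separated episodes in one year; truncated to ", max_k,
              call. = FALSE)
    }
    recs <- do.call(rbind, out)
    if (is.null(recs)) {
      recs <- data.frame(person_id = character(),
                         service_date = as.Date(character()),
                         item_code = integer())
    }
    recs$service_date <- format(recs$service_date, "%Y-%m-%d")
    rownames(recs) <- NULL
    recs
  })
}

#' Reconstruct the survey table implied by a panel
#'
#' Builds the survey data frame (`person_id`, `wave_year`, `birth_year`,
#' `employment_status`, `group`, `perinatal_eligible`) whose wave coverage
#' reproduces exactly the person-years present in `panel`, assuming waves
#' cover `wave_coverage` consecutive years starting at even years. Used
#' together with [panel_to_records()] for round-trip tests of
#' [build_panel()].
#'
#' @param panel Person-year panel data frame (years must align with wave
#'   coverage blocks).
#' @param wave_coverage Years covered per wave (default 2).
#' @param perinatal_eligible Eligibility flag to record per person; default
#'   marks persons with any `perinatal` row.
#' @return Survey data frame accepted by [build_panel()].
#' @export
panel_to_survey <- function(panel, wave_coverage = 2L,
                            perinatal_eligible = NULL) {
  panel <- validate_panel(panel)
  wave_coverage <- as.integer(wave_coverage)
  wave_of <- panel$year - (panel$year %% wave_coverage)
  key <- paste(panel$person_id, wave_of, sep = "\r")
  first <- !duplicated(key)
  sv <- data.frame(
    person_id = panel$person_id[first],
    wave_year = wave_of[first],
    birth_year = panel$birth_year[first],
    employment_status = panel$employment_status[first],
    group = if (is.null(panel$group)) "all" else panel$group[first],
    stringsAsFactors = FALSE
  )
  if (is.null(perinatal_eligible)) {
    has_peri <- tapply(panel$perinatal, panel$person_id, any)
    sv$perinatal_eligible <- as.logical(has_peri[sv$person_id])
  } else {
    sv$perinatal_eligible <- perinatal_eligible
  }
  rownames(sv) <- NULL
  sv
}

# Year-placement geometry for well-separated episodes: spacing between
# successive starts (episodes span up to 3 claim days, so a gap strictly
# greater than gap_days after the last claim needs gap_days + 4), lead/tail
# margins whose sum exceeds gap_days so episodes never merge across a year
# boundary, and the resulting per-year capacity.
episode_geometry <- function(gap_days) {
  gap_days <- as.integer(gap_days)
  margin_lead <- gap_days %/% 2L + 2L
  margin_tail <- gap_days - (margin_lead - 1L) + 3L
  usable <- 365L - margin_tail - margin_lead + 1L
  list(spacing = gap_days + 4L, margin_lead = margin_lead,
       margin_tail = margin_tail, usable = usable,
       max_k = (usable - 3L) %/% (gap_days + 4L) + 1L)
}

#' Maximum representable episode count per year
#'
#' The largest number of episodes of care that can physically occur within
#' one calendar year under a given collapse threshold: episodes must be
#' separated by more than `gap_days` days (and, for [panel_to_records()],
#' placed clear of the year boundaries). Under the 30-day sensitivity
#' measure this is 10; the episode definition itself bounds observable
#' annual counts.
#'
#' @param gap_days Episode collapse threshold in days.
#' @return Integer capacity.
#' @export
max_episodes_per_year <- function(gap_days = 1L) {
  episode_geometry(gap_days)$max_k
}

# Evaluate `expr` under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
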