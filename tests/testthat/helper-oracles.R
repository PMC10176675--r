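# Independent oracles and small fixture builders shared across tests.

# Union-find episode counter: connected components of the graph joining any
# two dates at most `gap_days` apart. Independent of the run-based
# implementation in collapse_episodes().
oracle_episode_count <- function(dates, gap_days) {
  d <- unique(as.integer(as.Date(dates)))
  n <- length(d)
  if (n == 0L) return(0L)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && abs(d[i] - d[j]) <= gap_days) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1L))))
}

# Textbook Cox-de Boor recursion, written directly from the recurrence.
oracle_bspline <- function(x, knots, degree, j) {
  B <- function(j, d, x) {
    if (d == 0L) {
      # right-continuous indicator; closed on the right at the last interval
      hi <- knots[length(knots) - 0L]
      if (knots[j] <= x && x < knots[j + 1L]) return(1)
      if (x == hi && knots[j] < knots[j + 1L] && knots[j + 1L] == hi) return(1)
      return(0)
    }
    a <- 0
    if (knots[j + d] > knots[j]) {
      a <- (x - knots[j]) / (knots[j + d] - knots[j]) * B(j, d - 1L, x)
    }
    b <- 0
    if (knots[j + d + 1L] > knots[j + 1L]) {
      b <- (knots[j + d + 1L] - x) / (knots[j + d + 1L] - knots[j + 1L]) *
        B(j + 1L, d - 1L, x)
    }
    a + b
  }
  B(j, degree, x)
}

# A quick small panel for fitting tests.
small_panel <- function(n_persons = 150L, sigma_u = 0.5, surface = "flat",
                        seed = 1L, ...) {
  simulate_panel(apc_scenario(n_persons = n_persons, sigma_u = sigma_u,
                              surface = surface, seed = seed, ...))
}

random_dates <- function(n, seed) {
  with_seed(seed, {
    as.Date("2004-01-01") + sample.int(730L, n, replace = TRUE)
  })
}

with_seed <- apcvisits:::with_seed
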