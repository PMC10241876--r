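# Builders for hand-sized cohorts used across the suite.

# One individual row in the individuals schema.
ind_row <- function(id, treatment, fate = "adult", sex = "female",
                    durs = c(8L, 3L, 2L, 2L, 3L, 5L), longevity = NA) {
  durs <- as.integer(durs)
  length(durs) <- 6L
  df <- data.frame(id = id, treatment = treatment, fate = fate, sex = sex,
                   stringsAsFactors = FALSE)
  df[paste0("dur_", STAGES)] <- as.list(durs)
  df$adult_longevity <- as.integer(longevity)
  df
}

# Cohort from a compact description. `females` is a list; each element may
# have durs (6 stage durations), lon (adult longevity) and eggs (numeric
# vector of daily counts, index = adult day; padded record rows are written
# for every adult day). Extra males / immature deaths / lost records are
# appended.
toy_cohort <- function(treatment = "T", females = list(), n_males = 0,
                       n_deaths = 0, n_lost = 0, n_initial = NULL) {
  rows <- list(); fec <- list(); k <- 0
  nid <- function() { k <<- k + 1; sprintf("%s-%02d", treatment, k) }
  for (f in females) {
    durs <- if (is.null(f$durs)) c(8L, 3L, 2L, 2L, 3L, 5L) else f$durs
    eggs <- if (is.null(f$eggs)) numeric() else f$eggs
    lon <- if (is.null(f$lon)) max(length(eggs), 1L) else f$lon
    id <- nid()
    rows[[length(rows) + 1]] <- ind_row(id, treatment, durs = durs,
                                        longevity = lon)
    if (lon > 0) {
      counts <- rep(0L, lon)
      counts[seq_along(eggs)] <- as.integer(eggs)
      fec[[length(fec) + 1]] <- data.frame(id = id, age_day = seq_len(lon),
                                           eggs = counts,
                                           stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(n_males)) {
    rows[[length(rows) + 1]] <- ind_row(nid(), treatment, sex = "male")
  }
  for (i in seq_len(n_deaths)) {
    rows[[length(rows) + 1]] <- ind_row(nid(), treatment,
                                        fate = "died_immature",
                                        sex = "unknown",
                                        durs = c(8L, 3L, rep(NA, 4)))
  }
  for (i in seq_len(n_lost)) {
    rows[[length(rows) + 1]] <- ind_row(nid(), treatment, fate = "lost",
                                        sex = "unknown",
                                        durs = c(8L, rep(NA, 5)))
  }
  ind <- do.call(rbind, rows)
  fec <- if (length(fec)) do.call(rbind, fec) else NULL
  cohort_study(treatment, ind, fec,
               n_initial_eggs = if (is.null(n_initial)) nrow(ind) else n_initial)
}

# Deterministic all-identical-female configuration (degenerate chain).
identical_female_config <- function(n_eggs = 5L, seed = 1L) {
  cohort_config(
    "ident", n_eggs = n_eggs,
    stage_means = stats::setNames(lapply(c(8, 3, 2, 2, 3, 5), dist_fixed),
                                  STAGES),
    sex_ratio_p = 1,
    preoviposition = dist_fixed(3), oviposition = dist_fixed(5),
    postoviposition = dist_fixed(2),
    eggs_per_day = 4, dispersion = Inf, seed = seed)
}

# Small stochastic config for property tests (quick to simulate).
small_config <- function(seed = 1L, n_eggs = 20L, eggs_per_day = 6,
                         treatment = "small") {
  cohort_config(
    treatment, n_eggs = n_eggs,
    stage_means = c(egg = 5, n1 = 2, n2 = 2, n3 = 2, n4 = 2, n5 = 3),
    stage_survival = stats::setNames(c(1, 1, 1, 1, 0.95, 0.95), STAGES),
    sex_ratio_p = 0.5,
    preoviposition = 3, oviposition = 10, postoviposition = 2,
    eggs_per_day = eggs_per_day, dispersion = 2,
    p_never_oviposit = 0.1, seed = seed)
}

# The conservation identity: sum(lx mx) == SURV * SR * total_eggs / NF.
conservation_gap <- function(cohort, age_origin = "egg") {
  sc <- build_schedule(cohort, age_origin)
  cen <- sc$census
  abs(sum(sc$lx * sc$mx) - cen$SURV * (cen$NF / cen$n_adults) *
        sc$total_eggs / cen$NF)
}
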