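# Synthetic cohort generator and its exact analytic expectation.
#
# The generator emulates a daily-census rearing experiment: each egg draws
# integer stage durations (shifted Poisson, minimum 1 day, truncated at
# mean + 6 SD so supports stay finite), survives each stage with a stated
# probability, is sexed at emergence, and adult females run through
# preoviposition / oviposition / postoviposition phases laying
# negative-binomial daily egg counts during the oviposition window. A stated
# fraction of females never lays. Each individual has its own RNG substream
# derived from the root seed, so removing one individual never perturbs the
# draws of the others.

#' Duration distributions for the generator
#'
#' `dist_fixed(days)` is a point mass; `dist_shifted_pois(mean)` is
#' 1 + Poisson(mean - 1), truncated at mean + 6 SD and renormalised (so both
#' simulation and the analytic oracle share the same finite support).
#'
#' @param days,mean Duration in days (mean >= 1).
#' @return A `duration_dist`: integer `support` (>= 1) with `prob`.
#' @export
dist_fixed <- function(days) {
  days <- as.integer(days)
  stopifnot(length(days) == 1L, days >= 1L)
  structure(list(support = days, prob = 1), class = "duration_dist")
}

#' @rdname dist_fixed
#' @export
dist_shifted_pois <- function(mean) {
  stopifnot(mean >= 1)
  lambda <- mean - 1
  if (lambda == 0) return(dist_fixed(1))
  cap <- as.integer(ceiling(mean + 6 * sqrt(lambda)))
  support <- 1:cap
  prob <- stats::dpois(support - 1L, lambda)
  structure(list(support = support, prob = prob / sum(prob)),
            class = "duration_dist")
}

#' @rdname dist_fixed
#' @param x A `duration_dist`, a numeric mean (becomes shifted-Poisson), or a
#'   `list(support=, prob=)`.
#' @export
as_duration_dist <- function(x) {
  if (inherits(x, "duration_dist")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(dist_shifted_pois(x))
  if (is.list(x) && all(c("support", "prob") %in% names(x))) {
    support <- as.integer(x$support)
    prob <- as.numeric(x$prob)
    stopifnot(length(support) == length(prob), all(support >= 1L),
              all(prob >= 0), sum(prob) > 0)
    return(structure(list(support = support, prob = prob / sum(prob)),
                     class = "duration_dist"))
  }
  stop("cannot interpret duration distribution")
}

.dist_mean <- function(d) sum(d$support * d$prob)

.dist_draw <- function(d) {
  if (length(d$support) == 1L) return(d$support)
  sample(d$support, 1L, prob = d$prob)
}

#' Generative configuration of a synthetic cohort
#'
#' @param treatment Treatment label.
#' @param n_eggs Initial cohort size (default 20, the usual per-treatment
#'   cohort of a rearing study).
#' @param stage_means Durations of egg and the five nymphal instars: named
#'   numeric vector/list (`egg`, `n1`..`n5`) of means, or of `duration_dist`
#'   objects.
#' @param stage_survival Per-stage survival probabilities (named, same
#'   stages; default all 1).
#' @param sex_ratio_p Probability an emerging adult is female.
#' @param preoviposition,oviposition,postoviposition Adult phase durations
#'   (mean or `duration_dist`).
#' @param eggs_per_day Mean daily egg count during the oviposition window.
#' @param dispersion Negative-binomial size parameter of the daily counts
#'   (smaller = more overdispersed; default 2). `Inf` makes the daily count
#'   deterministic (exactly `eggs_per_day`, which must then be an integer).
#' @param p_never_oviposit Probability a female lays nothing at all.
#' @param p_lost Probability a record is lost during the experiment.
#' @param seed Integer root seed.
#' @return A `cohort_config`.
#' @export
cohort_config <- function(treatment, n_eggs = 20L,
                          stage_means,
                          stage_survival = NULL,
                          sex_ratio_p = 0.5,
                          preoviposition, oviposition, postoviposition,
                          eggs_per_day, dispersion = 2,
                          p_never_oviposit = 0, p_lost = 0, seed = 1L) {
  if (is.null(stage_survival)) {
    stage_survival <- stats::setNames(rep(1, length(STAGES)), STAGES)
  }
  stopifnot(all(STAGES %in% names(stage_means)),
            all(STAGES %in% names(stage_survival)))
  stage_dists <- lapply(stage_means[STAGES], as_duration_dist)
  stage_survival <- vapply(stage_survival[STAGES], as.numeric, numeric(1))
  stopifnot(all(stage_survival >= 0 & stage_survival <= 1),
            sex_ratio_p >= 0, sex_ratio_p <= 1,
            p_never_oviposit >= 0, p_never_oviposit <= 1,
            p_lost >= 0, p_lost <= 1,
            eggs_per_day >= 0, dispersion > 0, n_eggs >= 1)
  if (is.infinite(dispersion) && eggs_per_day != round(eggs_per_day)) {
    stop("deterministic daily counts (dispersion = Inf) need integer eggs_per_day")
  }
  structure(
    list(treatment = as.character(treatment), n_eggs = as.integer(n_eggs),
         stage_dists = stage_dists, stage_survival = stage_survival,
         sex_ratio_p = sex_ratio_p,
         preoviposition = as_duration_dist(preoviposition),
         oviposition = as_duration_dist(oviposition),
         postoviposition = as_duration_dist(postoviposition),
         eggs_per_day = eggs_per_day, dispersion = dispersion,
         p_never_oviposit = p_never_oviposit, p_lost = p_lost,
         seed = as.integer(seed)),
    class = "cohort_config")
}

# Per-individual substream seed: mixes root seed, treatment label and the
# individual counter; kept below 2^31.
.ind_seed <- function(config, i) {
  h <- sum(utf8ToInt(config$treatment) * seq_along(utf8ToInt(config$treatment)))
  raw <- (abs(config$seed) %% 1000003) * 2011 + (h %% 7919) * 104729 +
    i * 48271  # doubles: stays well below 2^53
  as.integer(raw %% 2147483647)
}

#' Simulate a cohort from a generative configuration
#'
#' Reproducible: the same config (including seed) yields a byte-identical
#' cohort, and each individual uses its own RNG substream.
#'
#' @param config A [cohort_config()].
#' @return A [cohort_study].
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  rows <- vector("list", config$n_eggs)
  fec <- vector("list", config$n_eggs)
  for (i in seq_len(config$n_eggs)) {
    set.seed(.ind_seed(config, i))
    id <- sprintf("%s-%03d", config$treatment, i)
    lost <- stats::runif(1) < config$p_lost
    durs <- stats::setNames(rep(NA_integer_, length(STAGES)), .dur_cols)
    fate <- "adult"
    for (s in seq_along(STAGES)) {
      d <- .dist_draw(config$stage_dists[[s]])
      if (stats::runif(1) >= config$stage_survival[s]) {
        fate <- "died_immature"  # died during this stage; duration unobserved
        break
      }
      durs[s] <- d
    }
    sex <- "unknown"; longevity <- NA_integer_
    if (fate == "adult") {
      sex <- if (stats::runif(1) < config$sex_ratio_p) "female" else "male"
      if (sex == "female") {
        never <- stats::runif(1) < config$p_never_oviposit
        pre <- .dist_draw(config$preoviposition)
        ovi <- .dist_draw(config$oviposition)
        post <- .dist_draw(config$postoviposition)
        longevity <- pre + ovi + post
        eggs <- integer(longevity)
        if (!never) {
          eggs[(pre + 1):(pre + ovi)] <- if (is.infinite(config$dispersion)) {
            rep(as.integer(config$eggs_per_day), ovi)
          } else {
            stats::rnbinom(ovi, size = config$dispersion,
                           mu = config$eggs_per_day)
          }
        }
        fec[[i]] <- data.frame(id = id, age_day = seq_len(longevity),
                               eggs = eggs, stringsAsFactors = FALSE)
      }
    }
    if (lost) {
      fate <- "lost"; sex <- "unknown"; longevity <- NA_integer_
      durs[-1L] <- NA_integer_
      fec[i] <- list(NULL)
    }
    rows[[i]] <- data.frame(
      id = id, treatment = config$treatment, fate = fate, sex = sex,
      t(durs), adult_longevity = longevity, stringsAsFactors = FALSE)
  }
  ind <- do.call(rbind, rows)
  fec <- do.call(rbind, fec[!vapply(fec, is.null, logical(1))])
  if (is.null(fec)) {
    fec <- data.frame(id = character(), age_day = integer(), eggs = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(ind) <- rownames(fec) <- NULL
  cohort_study(config$treatment, ind, fec, n_initial_eggs = config$n_eggs)
}

# Convolution of two finite duration tables.
.dist_conv <- function(a, b) {
  lo <- min(a$support) + min(b$support)
  hi <- max(a$support) + max(b$support)
  prob <- numeric(hi - lo + 1L)
  for (k in seq_along(a$support)) {
    idx <- a$support[k] + b$support - lo + 1L
    prob[idx] <- prob[idx] + a$prob[k] * b$prob
  }
  list(support = lo:hi, prob = prob)
}

.dist_zero <- list(support = 0L, prob = 1)

#' Exact expected schedules and parameters of a configuration
#'
#' Computed by enumeration/convolution of the finite discrete duration
#' distributions, not by simulation: expected lx is overall egg-to-adult
#' survival times the probability a female is still alive at age x; expected
#' mx is the sex ratio times the expected egg output per living female. The
#' demographic parameters are then computed from the expected schedules, so
#' the expected rm satisfies the Euler-Lotka equation on them by
#' construction.
#'
#' @param config A [cohort_config()].
#' @param age_origin Age origin of the expected schedule.
#' @param tol Euler-Lotka tolerance.
#' @return An `analytic_expectation`: `schedule` (a `life_schedule`), `R0`,
#'   `T`, `rm`, `lam`, `SURV`, `SR`.
#' @export
analytic_expectation <- function(config, age_origin = c("egg", "adult_emergence"),
                                 tol = 1e-10) {
  stopifnot(inherits(config, "cohort_config"))
  age_origin <- match.arg(age_origin)
  SURV <- prod(config$stage_survival)
  SR <- config$sex_ratio_p
  E <- if (age_origin == "egg") {
    Reduce(.dist_conv, config$stage_dists)
  } else {
    .dist_zero
  }
  A <- .dist_conv(E, config$preoviposition)            # first possible laying age
  L <- .dist_conv(.dist_conv(config$preoviposition, config$oviposition),
                  config$postoviposition)
  death <- .dist_conv(E, L)                            # first dead age
  X <- max(death$support) - 1L
  ages <- 0:X
  # P(alive at x) = P(death > x)
  cdf_death <- cumsum(death$prob)
  p_dead <- function(x) {  # P(death <= x)
    i <- pmin(pmax(x - min(death$support) + 1L, 0L), length(cdf_death))
    ifelse(i == 0L, 0, cdf_death[pmax(i, 1L)]) * (i > 0L)
  }
  p_alive <- 1 - p_dead(ages)
  # P(laying at x) = P(A <= x < A + OVI) = sum_a P(A=a) P(OVI > x - a)
  ovi <- config$oviposition
  surv_ovi <- pmax(1 - cumsum(ovi$prob), 0)            # P(OVI > support[j])
  p_ovi_gt <- function(d) {  # P(OVI > d), d integer vector
    i <- pmin(pmax(d - min(ovi$support) + 1L, 0L), length(surv_ovi))
    out <- ifelse(d < min(ovi$support), 1, 0)
    pos <- i >= 1L & d >= min(ovi$support)
    out[pos] <- surv_ovi[i[pos]]
    out
  }
  p_window <- vapply(ages, function(x) {
    a <- A$support[A$support <= x]
    if (!length(a)) return(0)
    sum(A$prob[seq_along(a)] * p_ovi_gt(x - a))
  }, numeric(1))
  mu_eff <- (1 - config$p_never_oviposit) * config$eggs_per_day
  lx <- pmin(pmax(SURV * p_alive, 0), 1)
  mx <- pmax(ifelse(p_alive > 0, SR * mu_eff * p_window / p_alive, 0), 0)
  keep <- p_alive > 0
  last <- max(which(keep))
  sched <- schedule_from_vectors(ages[1:last], lx[1:last], mx[1:last],
                                 age_origin = age_origin,
                                 census = list(SURV = SURV, SR = SR, NF = NA))
  par <- demographic_params(sched, tol = tol)
  structure(list(schedule = sched, R0 = par$R0, T = par$T, rm = par$rm,
                 lam = par$lam, SURV = SURV, SR = SR),
            class = "analytic_expectation")
}

#' @export
print.analytic_expectation <- function(x, ...) {
  cat(sprintf(
    "<analytic_expectation> R0 %.3f  T %.3f d  rm %.4f /d  lambda %.4f /d\n",
    x$R0, x$T, x$rm, x$lam))
  invisible(x)
}

#' Diet presets calibrated to the published rearing study
#'
#' Three configurations ("aphids", "moth_eggs", "mixed") whose generative
#' means match the printed per-stage development times, reproductive-phase
#' means and fecundities of the three diet treatments, with egg-to-adult
#' survival of 0.95/0.95/1.0 and sex ratios of 0.42, 11/19 and 0.5. The
#' daily egg-count means are back-derived so that (1 - p_never) * mu *
#' E(oviposition days) reproduces the printed mean total fecundity per
#' female; p_never reflects the published counts of non-laying females.
#'
#' @param seed Root seed shared by the three configs (their treatment labels
#'   give each its own substreams).
#' @param n_eggs Cohort size per treatment (default 20).
#' @return Named list of three [cohort_config()] objects.
#' @export
paper_calibrated_configs <- function(seed = 1L, n_eggs = 20L) {
  surv95 <- stats::setNames(c(1, 1, 1, 1, 1, 0.95), STAGES)
  surv100 <- stats::setNames(rep(1, 6), STAGES)
  list(
    aphids = cohort_config(
      "aphids", n_eggs = n_eggs,
      stage_means = c(egg = 8.4, n1 = 2.6, n2 = 2.1, n3 = 2.4, n4 = 3.4,
                      n5 = 5.9),
      stage_survival = surv95, sex_ratio_p = 0.42,
      preoviposition = 13.0, oviposition = 5.7, postoviposition = 10.0,
      eggs_per_day = (5.7 * 7 / 3) / 5.7, p_never_oviposit = 4 / 7,
      seed = seed),
    moth_eggs = cohort_config(
      "moth_eggs", n_eggs = n_eggs,
      stage_means = c(egg = 8.5, n1 = 2.9, n2 = 2.2, n3 = 2.3, n4 = 3.2,
                      n5 = 5.4),
      stage_survival = surv95, sex_ratio_p = 11 / 19,
      preoviposition = 7.9, oviposition = 37.4, postoviposition = 1.4,
      eggs_per_day = (206.8 * 11 / 8) / 37.4, p_never_oviposit = 3 / 11,
      seed = seed),
    mixed = cohort_config(
      "mixed", n_eggs = n_eggs,
      stage_means = c(egg = 8.5, n1 = 2.6, n2 = 1.8, n3 = 2.0, n4 = 2.6,
                      n5 = 4.2),
      stage_survival = surv100, sex_ratio_p = 0.5,
      preoviposition = 4.4, oviposition = 41.6, postoviposition = 3.4,
      eggs_per_day = (497.7 * 10 / 9) / 41.6, p_never_oviposit = 0.1,
      seed = seed))
}
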