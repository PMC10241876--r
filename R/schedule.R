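# Age-specific survival (lx) and fecundity (mx) schedules.
#
# Female-based formulation: lx = SURV * NSF_x / NF and mx = NEGG_x * SR,
# where SURV is egg-to-adult survival, NF the initial number of adult
# females, NSF_x how many of those females are still alive at age x, NEGG_x
# the mean eggs laid per living female at age x and SR the proportion of
# emerged adults that are female. Ages are whole days; a female dying on day
# d is counted alive at ages < d (death-day exclusive). Eventual females are
# counted alive throughout their immature period, so lx = SURV before the
# first emergence under the egg origin.

.age_origins <- c("egg", "adult_emergence")

#' Census quantities of a cohort
#'
#' @param cohort A [cohort_study], after [apply_exclusions()].
#' @return List with `SURV` (egg-to-adult survival fraction), `SR` (proportion
#'   female among emerged adults), `NF` (number of adult females), `n_adults`,
#'   `n_initial_eggs` and a `degenerate` flag (no adults emerged).
#' @export
census_quantities <- function(cohort) {
  arr <- .cohort_arrays(cohort)
  n_fem <- length(arr$imm)
  list(SURV = if (arr$n_eggs > 0) arr$n_adults / arr$n_eggs else 0,
       SR = if (arr$n_adults > 0) n_fem / arr$n_adults else 0,
       NF = n_fem,
       n_adults = arr$n_adults,
       n_initial_eggs = arr$n_eggs,
       degenerate = arr$n_adults == 0L)
}

# Vectorised schedule computation from per-female arrays. `imm` immature
# durations, `lon` adult longevities, `eggs` per-female list(age_day, eggs)
# with age_day 1-based since emergence. Truncated at the last age with any
# female alive.
.schedule_core <- function(imm, lon, eggs, n_eggs, n_adults,
                           age_origin = "egg") {
  NF <- length(imm)
  if (NF == 0L) {
    stop("no adult females in cohort (NF = 0); schedules are undefined")
  }
  SURV <- n_adults / n_eggs
  SR <- NF / n_adults
  offset <- if (age_origin == "egg") imm else integer(NF)
  death <- offset + lon            # first age at which each female is dead
  X <- max(death) - 1L             # last age with any female alive
  ages <- 0:X
  # NSF_x = number of females with death age > x
  dd <- tabulate(death, nbins = X + 1L)  # deaths occurring at age <= X (none: death >= X+1 for at least one)
  NSF <- NF - cumsum(c(0L, dd[seq_len(X)]))
  EG <- numeric(X + 1L)
  for (i in seq_len(NF)) {
    e <- eggs[[i]]
    if (length(e$age_day)) {
      ax <- offset[i] + e$age_day - 1L
      if (any(ax > X) || any(ax >= death[i])) {
        stop("egg record extends past female death age")
      }
      EG[ax + 1L] <- EG[ax + 1L] + e$eggs
    }
  }
  lx <- SURV * (NSF / NF)  # grouping keeps lx = SURV exact while NSF = NF
  mx <- ifelse(NSF > 0L, EG / NSF, 0) * SR
  list(ages = ages, lx = lx, mx = mx,
       census = list(SURV = SURV, SR = SR, NF = NF, n_adults = n_adults,
                     n_initial_eggs = n_eggs),
       total_eggs = sum(EG))
}

.as_schedule <- function(core, age_origin) {
  structure(
    list(ages = core$ages, lx = core$lx, mx = core$mx,
         age_origin = age_origin, census = core$census,
         total_eggs = core$total_eggs),
    class = "life_schedule")
}

#' Build the full lx/mx schedule of a cohort
#'
#' @param cohort A [cohort_study], post-exclusion.
#' @param age_origin `"egg"` (day 0 = oviposition of the focal egg; the
#'   default, whole-life-cycle framing) or `"adult_emergence"` (day 0 = first
#'   adult day).
#' @return A `life_schedule`: contiguous integer `ages` from 0, `lx`
#'   (non-increasing, starts at SURV), `mx` (daughters per living female per
#'   day), the census used, and the age origin. Truncated at the last age
#'   with a living female.
#' @export
build_schedule <- function(cohort, age_origin = c("egg", "adult_emergence")) {
  age_origin <- match.arg(age_origin)
  arr <- .cohort_arrays(cohort)
  .as_schedule(
    .schedule_core(arr$imm, arr$lon, arr$eggs, arr$n_eggs, arr$n_adults,
                   age_origin),
    age_origin)
}

#' @rdname build_schedule
#' @return `build_lx`/`build_mx` return just the per-age numeric vector.
#' @export
build_lx <- function(cohort, age_origin = c("egg", "adult_emergence")) {
  build_schedule(cohort, age_origin)$lx
}

#' @rdname build_schedule
#' @export
build_mx <- function(cohort, age_origin = c("egg", "adult_emergence")) {
  build_schedule(cohort, age_origin)$mx
}

#' @export
print.life_schedule <- function(x, ...) {
  cat(sprintf(
    "<life_schedule> %d ages (origin: %s), SURV %.3f, SR %.3f, NF %d\n",
    length(x$ages), x$age_origin, x$census$SURV, x$census$SR, x$census$NF))
  cat(sprintf("  sum(lx*mx) = %.4f\n", sum(x$lx * x$mx)))
  invisible(x)
}

#' Export / import a schedule as a table
#'
#' One row per age with full double precision, suitable for survival and
#' fecundity curve plotting.
#'
#' @param schedule A `life_schedule`.
#' @param path Optional CSV path; when given the table is also written.
#' @return Data frame `x`, `lx`, `mx` (invisibly when writing).
#' @export
export_schedule <- function(schedule, path = NULL) {
  stopifnot(inherits(schedule, "life_schedule"))
  df <- data.frame(x = schedule$ages, lx = schedule$lx, mx = schedule$mx)
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, quote = FALSE, eol = "\n")
    close(con)
    return(invisible(df))
  }
  df
}

#' @rdname export_schedule
#' @param age_origin Age origin to attach to the re-imported schedule.
#' @export
import_schedule <- function(path, age_origin = c("egg", "adult_emergence")) {
  age_origin <- match.arg(age_origin)
  df <- utils::read.csv(path)
  structure(list(ages = as.integer(df$x), lx = as.numeric(df$lx),
                 mx = as.numeric(df$mx), age_origin = age_origin,
                 census = NULL, total_eggs = NA_real_),
            class = "life_schedule")
}

# Build a schedule directly from vectors (used by the analytic-expectation
# oracle and by tests that construct schedules by hand).
#' Construct a schedule from raw vectors
#'
#' Mainly for constructed/expected schedules; no census is attached unless
#' given.
#' @param ages,lx,mx Equal-length vectors; ages must be contiguous from 0.
#' @param age_origin Age origin label.
#' @param census Optional census list.
#' @export
schedule_from_vectors <- function(ages, lx, mx, age_origin = "egg",
                                  census = NULL) {
  ages <- as.integer(ages)
  stopifnot(length(ages) == length(lx), length(lx) == length(mx),
            identical(ages, seq.int(0L, length.out = length(ages))),
            all(mx >= 0), all(lx >= 0), all(lx <= 1))
  structure(list(ages = ages, lx = as.numeric(lx), mx = as.numeric(mx),
                 age_origin = age_origin, census = census,
                 total_eggs = NA_real_),
            class = "life_schedule")
}
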