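# Individual rearing records and treatment cohorts.
#
# An individual is one row of a data frame (one reared egg): treatment, fate,
# sex, per-stage development durations in whole days, adult longevity for
# females, plus a long-format table of daily egg counts (day 1 = first adult
# day). A cohort_study bundles all individuals of one treatment with the
# initial cohort size, so egg-to-adult survival keeps its denominator even
# after immature deaths.

#' Names of the immature stages, in developmental order
#'
#' Egg plus the five nymphal instars; duration columns in the individuals
#' table are `dur_<stage>`.
#' @export
STAGES <- c("egg", "n1", "n2", "n3", "n4", "n5")

.dur_cols <- paste0("dur_", STAGES)

.ind_cols <- c("id", "treatment", "fate", "sex", .dur_cols, "adult_longevity")

.fates <- c("adult", "died_immature", "lost")
.sexes <- c("female", "male", "unknown")

#' Construct a cohort study
#'
#' @param treatment Treatment label.
#' @param individuals Data frame with columns `id`, `treatment`, `fate`,
#'   `sex`, `dur_egg` ... `dur_n5`, `adult_longevity` (NA = absent).
#' @param fecundity Long-format data frame `id`, `age_day`, `eggs`, one row
#'   per observed adult day per female; `age_day` is the day since adult
#'   emergence (1-based).
#' @param n_initial_eggs Number of eggs that started the cohort (defaults to
#'   the number of individual records).
#' @return An object of class `cohort_study`.
#' @export
cohort_study <- function(treatment, individuals, fecundity = NULL,
                         n_initial_eggs = nrow(individuals)) {
  if (is.null(fecundity)) {
    fecundity <- data.frame(id = character(), age_day = integer(),
                            eggs = integer(), stringsAsFactors = FALSE)
  }
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.ind_cols, names(individuals))
  if (length(missing_cols)) {
    stop("individuals table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(individuals$id)) {
    stop("duplicate individual id(s): ",
         paste(unique(individuals$id[duplicated(individuals$id)]), collapse = ", "))
  }
  bad <- setdiff(unique(fecundity$id), individuals$id)
  if (length(bad)) {
    stop("fecundity records for unknown id(s): ", paste(bad, collapse = ", "))
  }
  if (any(fecundity$eggs < 0, na.rm = TRUE)) stop("negative egg counts")
  structure(
    list(treatment = as.character(treatment),
         individuals = individuals[.ind_cols],
         fecundity = fecundity[c("id", "age_day", "eggs")],
         n_initial_eggs = as.integer(n_initial_eggs),
         excluded = FALSE),
    class = "cohort_study")
}

#' @export
print.cohort_study <- function(x, ...) {
  cen <- census_quantities(x)
  cat(sprintf(
    "<cohort_study> treatment '%s': %d records / %d initial eggs\n",
    x$treatment, nrow(x$individuals), x$n_initial_eggs))
  cat(sprintf("  adults %d (SURV %.3f), females %d (SR %.3f)%s\n",
              cen$n_adults, cen$SURV, cen$NF, cen$SR,
              if (x$excluded) ", exclusions applied" else ""))
  invisible(x)
}

#' Read cohorts from the two CSV schemas
#'
#' The individuals file has one row per reared individual
#' (`id,treatment,fate,sex,dur_egg,...,dur_n5,adult_longevity`, empty field =
#' absent); the fecundity file is long-format (`id,age_day,eggs`) with one
#' row per observed adult day of each female. One [cohort_study] is returned
#' per distinct treatment label.
#'
#' @param individuals_path,fecundity_path Paths to the two CSV files.
#' @return Named list of [cohort_study] objects (names = treatment labels, in
#'   file order of first appearance).
#' @export
read_cohort_csv <- function(individuals_path, fecundity_path) {
  ind <- utils::read.csv(individuals_path, stringsAsFactors = FALSE,
                         colClasses = c(id = "character", treatment = "character",
                                        fate = "character", sex = "character"))
  missing_cols <- setdiff(.ind_cols, names(ind))
  if (length(missing_cols)) {
    stop("malformed individuals file ", individuals_path,
         ": missing columns ", paste(missing_cols, collapse = ", "))
  }
  for (cc in c(.dur_cols, "adult_longevity")) {
    v <- ind[[cc]]
    if (!is.numeric(v) && !is.logical(v)) {
      bad <- which(!grepl("^\\s*[0-9]*\\s*$", as.character(v)) & !is.na(v))
      stop("malformed individuals file: non-integer '", cc, "' at data line ",
           if (length(bad)) bad[1] else "?")
    }
    ind[[cc]] <- as.integer(v)
  }
  bad_fate <- which(!ind$fate %in% .fates)
  if (length(bad_fate)) {
    stop("malformed individuals file: unknown fate '", ind$fate[bad_fate[1]],
         "' at data line ", bad_fate[1])
  }
  bad_sex <- which(!ind$sex %in% .sexes)
  if (length(bad_sex)) {
    stop("malformed individuals file: unknown sex '", ind$sex[bad_sex[1]],
         "' at data line ", bad_sex[1])
  }
  if (anyDuplicated(ind$id)) {
    stop("duplicate individual id(s): ",
         paste(unique(ind$id[duplicated(ind$id)]), collapse = ", "))
  }
  fec <- utils::read.csv(fecundity_path, stringsAsFactors = FALSE,
                         colClasses = c(id = "character"))
  if (!all(c("id", "age_day", "eggs") %in% names(fec))) {
    stop("malformed fecundity file ", fecundity_path,
         ": needs columns id,age_day,eggs")
  }
  fec$age_day <- as.integer(fec$age_day)
  fec$eggs <- as.integer(fec$eggs)
  unknown <- setdiff(unique(fec$id), ind$id)
  if (length(unknown)) {
    stop("fecundity records for unknown id(s): ", paste(unknown, collapse = ", "))
  }
  fec_owner <- ind[match(fec$id, ind$id), ]
  bad <- fec$id[fec_owner$sex != "female" | fec_owner$fate != "adult"]
  if (length(bad)) {
    stop("fecundity records for non-(adult female) id(s): ",
         paste(unique(bad), collapse = ", "))
  }
  if (any(is.na(fec$eggs)) || any(fec$eggs < 0)) stop("negative or missing egg counts")

  out <- list()
  for (tr in unique(ind$treatment)) {
    sub <- ind[ind$treatment == tr, , drop = FALSE]
    fsub <- fec[fec$id %in% sub$id, , drop = FALSE]
    rownames(sub) <- rownames(fsub) <- NULL
    out[[tr]] <- cohort_study(tr, sub, fsub)
  }
  out
}

#' Write cohorts to the two CSV schemas
#'
#' Inverse of [read_cohort_csv()]; emits the same dialect (LF endings, no
#' quoting, empty field for absent values) so write/read round-trips exactly.
#'
#' @param cohorts A [cohort_study] or list of them.
#' @param individuals_path,fecundity_path Output paths.
#' @export
write_cohort_csv <- function(cohorts, individuals_path, fecundity_path) {
  if (inherits(cohorts, "cohort_study")) cohorts <- list(cohorts)
  ind <- do.call(rbind, lapply(cohorts, function(co) co$individuals))
  fec <- do.call(rbind, lapply(cohorts, function(co) co$fecundity))
  con <- file(individuals_path, open = "wb")
  utils::write.csv(ind, con, row.names = FALSE, quote = FALSE, na = "", eol = "\n")
  close(con)
  con <- file(fecundity_path, open = "wb")
  utils::write.csv(fec, con, row.names = FALSE, quote = FALSE, na = "", eol = "\n")
  close(con)
  invisible(c(individuals_path, fecundity_path))
}

#' Discard records lost during the experiment
#'
#' Individuals with `fate = "lost"` (escaped, damaged, etc.) are removed
#' before any analysis and the initial cohort size is reduced accordingly, so
#' they count neither for nor against egg-to-adult survival. Immature deaths
#' are kept: they stay in the survival denominator. Idempotent.
#'
#' @param cohort A [cohort_study].
#' @return A copy with no `lost` records and `n_initial_eggs` reduced by the
#'   number removed.
#' @export
apply_exclusions <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_study"))
  lost <- cohort$individuals$fate == "lost"
  keep <- cohort$individuals[!lost, , drop = FALSE]
  rownames(keep) <- NULL
  fec <- cohort$fecundity[cohort$fecundity$id %in% keep$id, , drop = FALSE]
  rownames(fec) <- NULL
  out <- cohort_study(cohort$treatment, keep, fec,
                      n_initial_eggs = cohort$n_initial_eggs - sum(lost))
  out$excluded <- TRUE
  out
}

#' Validate a cohort against the record-level invariants
#'
#' Reports (never raises) violations: adults must have all six stage
#' durations and non-adults must not; egg records imply an adult female;
#' adult longevity must cover the egg-laying record; durations are whole
#' days >= 1; egg counts are non-negative.
#'
#' @param cohort A [cohort_study].
#' @return Data frame `id`, `check`, `message`; zero rows means valid.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_study"))
  ind <- cohort$individuals
  fec <- cohort$fecundity
  v <- list()
  note <- function(id, check, message) {
    v[[length(v) + 1L]] <<- data.frame(id = id, check = check,
                                       message = message, stringsAsFactors = FALSE)
  }
  durs <- as.matrix(ind[.dur_cols])
  n_dur <- rowSums(!is.na(durs))
  for (i in seq_len(nrow(ind))) {
    if (ind$fate[i] == "adult" && n_dur[i] != length(STAGES)) {
      note(ind$id[i], "stage_durations",
           "adult without all six stage durations")
    }
    if (ind$fate[i] != "adult" && n_dur[i] == length(STAGES)) {
      note(ind$id[i], "stage_durations",
           "all stage durations present but fate is not adult")
    }
    if (!is.na(ind$adult_longevity[i]) &&
        (ind$fate[i] != "adult" || ind$sex[i] != "female")) {
      note(ind$id[i], "adult_longevity",
           "adult_longevity present for a non-(adult female)")
    }
    if (ind$fate[i] == "adult" && ind$sex[i] == "female" &&
        is.na(ind$adult_longevity[i])) {
      note(ind$id[i], "adult_longevity", "adult female without adult_longevity")
    }
  }
  bad_dur <- which(durs < 1, arr.ind = TRUE)
  if (nrow(bad_dur)) {
    for (k in seq_len(nrow(bad_dur))) {
      note(ind$id[bad_dur[k, 1]], "stage_durations", "stage duration < 1 day")
    }
  }
  if (nrow(fec)) {
    owner <- match(fec$id, ind$id)
    for (id in unique(fec$id)) {
      i <- match(id, ind$id)
      if (is.na(i)) { note(id, "fecundity", "egg record for unknown id"); next }
      if (ind$sex[i] != "female" || ind$fate[i] != "adult") {
        note(id, "fecundity", "egg record for a non-(adult female)")
      } else if (!is.na(ind$adult_longevity[i])) {
        span <- max(fec$age_day[fec$id == id])
        if (span > ind$adult_longevity[i]) {
          note(id, "adult_longevity",
               sprintf("egg record spans %d adult days but longevity is %d",
                       span, ind$adult_longevity[i]))
        }
      }
    }
    if (any(fec$eggs < 0)) note(fec$id[fec$eggs < 0][1], "fecundity",
                                "negative egg count")
    if (any(fec$age_day < 1)) note(fec$id[fec$age_day < 1][1], "fecundity",
                                   "age_day < 1 (day 1 = first adult day)")
  }
  if (nrow(ind) == 0L || cohort$n_initial_eggs == 0L) {
    note(NA_character_, "cohort", "empty cohort: no usable records")
  }
  if (length(v)) do.call(rbind, v) else
    data.frame(id = character(), check = character(), message = character(),
               stringsAsFactors = FALSE)
}

# Per-female arrays used by the schedule and jackknife machinery.
# Returns immature duration, adult longevity and the egg record of every
# adult female, plus the cohort head counts.
.cohort_arrays <- function(cohort) {
  ind <- cohort$individuals
  if (any(ind$fate == "lost")) {
    stop("cohort contains 'lost' records; run apply_exclusions() first")
  }
  adult <- ind$fate == "adult"
  fem <- adult & ind$sex == "female"
  fem_ids <- ind$id[fem]
  durs <- as.matrix(ind[fem, .dur_cols, drop = FALSE])
  imm <- as.integer(rowSums(durs))
  lon <- as.integer(ind$adult_longevity[fem])
  if (any(is.na(imm)) || any(is.na(lon))) {
    stop("adult female with missing stage durations or adult_longevity")
  }
  fec <- cohort$fecundity
  eggs <- lapply(fem_ids, function(id) {
    f <- fec[fec$id == id & fec$eggs > 0, , drop = FALSE]
    list(age_day = as.integer(f$age_day), eggs = as.integer(f$eggs))
  })
  list(n_eggs = cohort$n_initial_eggs,
       n_adults = sum(adult),
       fem_ids = fem_ids,
       imm = imm, lon = lon, eggs = eggs,
       fate = ind$fate, sex = ind$sex, ids = ind$id)
}
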