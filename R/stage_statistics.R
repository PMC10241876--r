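# Descriptive statistics and hypothesis tests for stage durations and
# reproductive periods: per-treatment mean +/- SE with n, Kruskal-Wallis
# (tie-corrected) with DSCF post hoc letters, and one-way ANOVA with
# Tukey-Kramer letters. Which variable gets which test mirrors the usual
# practice for daily rearing data: heavily tied duration counts ->
# rank tests; preoviposition, longevity and fecundity -> ANOVA.

#' Kruskal-Wallis test with DSCF multiple comparisons
#'
#' Tie-corrected Kruskal-Wallis H with a chi-squared reference (df = k - 1),
#' followed by Dwass-Steel-Critchlow-Fligner pairwise comparisons: each pair
#' of groups is re-ranked on its own, the tie-corrected standardised Wilcoxon
#' rank-sum statistic z is computed, and sqrt(2)|z| is referred to the
#' studentized range with k groups and infinite df (the asymptotic SAS
#' NPAR1WAY procedure).
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param alpha Significance level for the letter display.
#' @return List: `H`, `df`, `p`, `pairwise` data frame (z, q, p per pair),
#'   `letters` (compact letter display, highest group mean = "a").
#' @export
kruskal_wallis_dscf <- function(groups, alpha = 0.05) {
  k <- length(groups)
  stopifnot(k >= 2, all(lengths(groups) >= 2))
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("group", seq_len(k))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), lengths(groups))
  N <- length(x)
  r <- rank(x)
  Rsum <- tapply(r, g, sum)
  H <- 12 / (N * (N + 1)) * sum(Rsum^2 / lengths(groups)) - 3 * (N + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C <= 0) {
    H <- 0; p <- 1  # all observations identical
  } else {
    H <- H / C
    p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  }

  sig <- matrix(FALSE, k, k, dimnames = list(labels, labels))
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      xi <- groups[[i]]; xj <- groups[[j]]
      ni <- length(xi); nj <- length(xj); nij <- ni + nj
      rij <- rank(c(xi, xj))
      W <- sum(rij[seq_len(ni)])
      tie_ij <- table(c(xi, xj))
      V <- ni * nj / 12 *
        ((nij + 1) - sum(tie_ij^3 - tie_ij) / (nij * (nij - 1)))
      if (V <= 0) { z <- 0 } else {
        z <- (W - ni * (nij + 1) / 2) / sqrt(V)
      }
      q <- sqrt(2) * abs(z)
      pq <- stats::ptukey(q, nmeans = k, df = Inf, lower.tail = FALSE)
      sig[i, j] <- sig[j, i] <- pq < alpha
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = labels[i], group2 = labels[j], z = z, q = q, p = pq,
        significant = sig[i, j], stringsAsFactors = FALSE)
    }
  }
  means <- vapply(groups, mean, numeric(1))
  list(H = H, df = k - 1, p = p, pairwise = do.call(rbind, rows),
       letters = stats::setNames(.cld(labels, means, sig), labels),
       alpha = alpha)
}

#' One-way ANOVA with Tukey-Kramer multiple comparisons
#'
#' Fixed-effects one-way ANOVA; pairwise comparisons use the studentized
#' range with the pooled mean square error and df = N - k (Tukey-Kramer for
#' unequal n).
#'
#' @inheritParams kruskal_wallis_dscf
#' @return List: `F`, `df` (c(k - 1, N - k)), `p`, `pairwise`, `letters`.
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  k <- length(groups)
  stopifnot(k >= 2, all(lengths(groups) >= 2))
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("group", seq_len(k))
  ns <- lengths(groups)
  N <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  df1 <- k - 1; df2 <- N - k
  msw <- ssw / df2
  if (msw == 0) {
    Fv <- if (ssb == 0) 0 else Inf
    p <- if (ssb == 0) 1 else 0
  } else {
    Fv <- (ssb / df1) / msw
    p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  }
  tk <- .tukey_pairwise(labels, means, ns, msw, df2, alpha)
  list(F = Fv, df = c(df1, df2), p = p, pairwise = tk$pairwise,
       letters = stats::setNames(tk$letters, labels), alpha = alpha)
}

# Build a group_summary from per-treatment observation vectors. Treatments
# with fewer than `min_n` observations are kept in the table (mean, n) but
# excluded from the test with a warning.
.summarize_groups <- function(variable, values, test, alpha = 0.05,
                              min_n = 2L) {
  labels <- names(values)
  ns <- lengths(values)
  testable <- ns >= min_n
  if (any(!testable) && sum(testable) >= 2) {
    warning(sprintf("%s: treatment(s) %s have < %d observations; excluded from test",
                    variable, paste(labels[!testable], collapse = ", "), min_n))
  }
  res <- NULL
  letts <- stats::setNames(rep("", length(values)), labels)
  if (sum(testable) >= 2) {
    res <- if (test == "kruskal_wallis_dscf") {
      kruskal_wallis_dscf(values[testable], alpha)
    } else {
      anova_tukey(values[testable], alpha)
    }
    letts[names(res$letters)] <- res$letters
  }
  tab <- data.frame(
    treatment = labels,
    mean = vapply(values, function(v) if (length(v)) mean(v) else NA_real_,
                  numeric(1)),
    se = vapply(values, function(v) if (length(v) >= 2) .se(v) else NA_real_,
                numeric(1)),
    n = ns,
    letter = unname(letts),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(
    list(variable = variable, groups = tab, test = test,
         statistic = if (is.null(res)) NA_real_ else
           if (test == "kruskal_wallis_dscf") res$H else res$F,
         df = if (is.null(res)) NA else res$df,
         p = if (is.null(res)) NA_real_ else res$p,
         pairwise = if (is.null(res)) NULL else res$pairwise,
         alpha = alpha),
    class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  statname <- if (x$test == "kruskal_wallis_dscf") "H" else "F"
  cat(sprintf("<group_summary> %s (%s: %s = %.3f, p = %.4g)\n",
              x$variable, x$test, statname, x$statistic, x$p))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Stage-duration summaries across treatments
#'
#' Per-stage developmental durations (days) of the individuals that completed
#' each stage, plus the total immature period (egg to adult) of individuals
#' reaching adulthood; each compared across treatments by Kruskal-Wallis with
#' DSCF letters.
#'
#' @param cohorts List of [cohort_study] objects, post-exclusion.
#' @param alpha Significance level.
#' @return Named list of `group_summary` objects (one per stage and
#'   `total_immature`).
#' @export
stage_duration_summary <- function(cohorts, alpha = 0.05) {
  labels <- vapply(cohorts, function(co) co$treatment, character(1))
  out <- list()
  for (s in STAGES) {
    cc <- paste0("dur_", s)
    values <- stats::setNames(lapply(cohorts, function(co) {
      v <- co$individuals[[cc]]
      v[!is.na(v)]
    }), labels)
    out[[s]] <- .summarize_groups(s, values, "kruskal_wallis_dscf", alpha)
  }
  values <- stats::setNames(lapply(cohorts, function(co) {
    ind <- co$individuals
    ad <- ind$fate == "adult"
    rowSums(as.matrix(ind[ad, .dur_cols, drop = FALSE]))
  }), labels)
  out$total_immature <- .summarize_groups("total_immature", values,
                                          "kruskal_wallis_dscf", alpha)
  out
}

# Per-female reproductive variables of one cohort: longevity and total
# fecundity for every adult female; pre/ovi/postoviposition periods for
# ovipositing females only (first egg on adult day f, last on day l:
# preovi = f - 1, ovi = l - f + 1, postovi = longevity - l; the three sum to
# the longevity).
.female_variables <- function(cohort) {
  ind <- cohort$individuals
  fem <- ind$fate == "adult" & ind$sex == "female"
  ids <- ind$id[fem]
  lon <- ind$adult_longevity[fem]
  fec <- cohort$fecundity
  total <- vapply(ids, function(id) sum(fec$eggs[fec$id == id]), numeric(1))
  fl <- lapply(ids, function(id) {
    d <- fec$age_day[fec$id == id & fec$eggs > 0]
    if (length(d)) range(d) else c(NA_integer_, NA_integer_)
  })
  f <- vapply(fl, `[`, numeric(1), 1)
  l <- vapply(fl, `[`, numeric(1), 2)
  lay <- !is.na(f)
  list(longevity = as.numeric(lon), fecundity = as.numeric(total),
       preoviposition = f[lay] - 1, oviposition = l[lay] - f[lay] + 1,
       postoviposition = lon[lay] - l[lay], n_layers = sum(lay))
}

#' Reproductive-period and fecundity summaries across treatments
#'
#' Pre-, post- and oviposition periods are computed over ovipositing females
#' only (non-layers have no egg dates); adult longevity and total fecundity
#' cover all adult females, zeros of non-layers included. Preoviposition,
#' longevity and fecundity are compared by one-way ANOVA with Tukey letters;
#' oviposition and postoviposition by Kruskal-Wallis with DSCF letters.
#'
#' @inheritParams stage_duration_summary
#' @return Named list of `group_summary` objects (`preoviposition`,
#'   `oviposition`, `postoviposition`, `longevity`, `fecundity`).
#' @export
reproductive_summary <- function(cohorts, alpha = 0.05) {
  labels <- vapply(cohorts, function(co) co$treatment, character(1))
  fv <- lapply(cohorts, .female_variables)
  pick <- function(var) stats::setNames(lapply(fv, `[[`, var), labels)
  list(
    preoviposition = .summarize_groups("preoviposition",
                                       pick("preoviposition"), "anova_tukey",
                                       alpha),
    oviposition = .summarize_groups("oviposition", pick("oviposition"),
                                    "kruskal_wallis_dscf", alpha),
    postoviposition = .summarize_groups("postoviposition",
                                        pick("postoviposition"),
                                        "kruskal_wallis_dscf", alpha),
    longevity = .summarize_groups("longevity", pick("longevity"),
                                  "anova_tukey", alpha),
    fecundity = .summarize_groups("fecundity", pick("fecundity"),
                                  "anova_tukey", alpha))
}

#' Headline effect sizes between two diets
#'
#' Fold change in mean total fecundity (1 decimal place) and percent
#' reduction in the total immature period (nearest integer) of a focal
#' treatment relative to a reference.
#'
#' @param fecundity,total_immature Either `group_summary` objects (from
#'   [reproductive_summary()] / [stage_duration_summary()]) or named numeric
#'   vectors of treatment means.
#' @param treatment,reference Treatment labels (focal and baseline).
#' @return List `fecundity_fold`, `immature_reduction_pct`.
#' @export
headline_ratios <- function(fecundity, total_immature, treatment, reference) {
  grab <- function(x, tr) {
    if (inherits(x, "group_summary")) {
      m <- x$groups$mean[x$groups$treatment == tr]
      if (!length(m)) stop("no treatment '", tr, "' in summary ", x$variable)
      m
    } else {
      as.numeric(x[[tr]])
    }
  }
  fec_t <- grab(fecundity, treatment); fec_r <- grab(fecundity, reference)
  imm_t <- grab(total_immature, treatment); imm_r <- grab(total_immature, reference)
  if (fec_r == 0 || imm_r == 0) {
    warning("zero reference mean: ratios undefined")
    return(list(fecundity_fold = NA_real_, immature_reduction_pct = NA_real_))
  }
  list(fecundity_fold = round(fec_t / fec_r, 1),
       immature_reduction_pct = round(100 * (1 - imm_t / imm_r)))
}
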