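# Leave-one-out jackknife inference for the demographic parameters.
#
# For each omitted unit the whole pipeline is rerun (census -> schedule ->
# parameters) on the reduced cohort; pseudo-values pv_i = n*theta_all -
# (n-1)*theta_(-i) give the jackknife estimate (their mean) and standard
# error sqrt(sum((pv - mean)^2) / (n (n-1))). Treatments are then compared
# parameter by parameter with Tukey's studentized range test on the
# pseudo-values.

.jk_params <- c("R0", "T", "rm", "lam")

.new_jackknife_estimate <- function(parameter, treatment, theta_all, pv,
                                    n_units, flagged = integer()) {
  pv_ok <- pv[!is.na(pv)]
  n <- length(pv_ok)
  se <- if (n >= 2) sqrt(sum((pv_ok - mean(pv_ok))^2) / (n * (n - 1))) else NA_real_
  structure(
    list(parameter = parameter, treatment = treatment,
         theta_all = theta_all, pseudo_values = pv,
         theta_jack = mean(pv_ok), se = se, n_units = n_units,
         n_used = n, flagged = flagged),
    class = "jackknife_estimate")
}

#' @export
print.jackknife_estimate <- function(x, ...) {
  cat(sprintf("<jackknife_estimate> %s [%s]: %.4f +/- %.4f (n = %d%s)\n",
              x$parameter, x$treatment, x$theta_jack, x$se, x$n_used,
              if (x$n_used < x$n_units)
                sprintf(" of %d; %d replicate(s) degenerate", x$n_units,
                        x$n_units - x$n_used) else ""))
  invisible(x)
}

#' Generic leave-one-out jackknife of a statistic
#'
#' Utility sharing the pseudo-value machinery of [jackknife_parameters()];
#' for a linear statistic such as the mean, the jackknife SE equals the
#' classical standard error of the mean exactly.
#'
#' @param x Numeric vector of observations.
#' @param statistic Function of a numeric vector returning a scalar.
#' @param label,treatment Labels carried into the result.
#' @return A `jackknife_estimate`.
#' @export
jackknife <- function(x, statistic, label = "statistic", treatment = "") {
  n <- length(x)
  stopifnot(n >= 2)
  theta_all <- statistic(x)
  theta_loo <- vapply(seq_len(n), function(i) statistic(x[-i]), numeric(1))
  pv <- n * theta_all - (n - 1) * theta_loo
  .new_jackknife_estimate(label, treatment, theta_all, pv, n)
}

#' Jackknife estimates of the four demographic parameters
#'
#' @param cohort A [cohort_study], post-exclusion.
#' @param unit What to leave out per replicate: `"individual"` (every record,
#'   immature deaths included, so egg-to-adult survival varies across
#'   replicates; the default) or `"female"` (adult females only, the stricter
#'   female-based deletion).
#' @param age_origin Passed to the schedule builder.
#' @param tol Euler-Lotka residual tolerance.
#' @return Named list (`R0`, `T`, `rm`, `lam`) of `jackknife_estimate`
#'   objects. If removing a unit leaves a replicate with no reproduction
#'   (R0 = 0), the R0 pseudo-value uses theta = 0 while the T/rm/lam
#'   pseudo-values for that replicate are flagged missing and those estimates
#'   are reported with reduced n and a warning.
#' @export
jackknife_parameters <- function(cohort, unit = c("individual", "female"),
                                 age_origin = c("egg", "adult_emergence"),
                                 tol = 1e-10) {
  unit <- match.arg(unit)
  age_origin <- match.arg(age_origin)
  arr <- .cohort_arrays(cohort)
  NF <- length(arr$imm)
  full <- .schedule_core(arr$imm, arr$lon, arr$eggs, arr$n_eggs, arr$n_adults,
                         age_origin)
  theta_all <- .params_vec(full, tol)
  if (anyNA(theta_all)) {
    stop("full-sample parameters are degenerate (R0 = 0); jackknife undefined")
  }
  n_rec <- length(arr$ids)
  units <- if (unit == "individual") seq_len(n_rec) else which(
    arr$fate == "adult" & arr$sex == "female")
  n <- length(units)
  if (n < 2) stop("need at least 2 jackknife units")
  fem_index <- match(arr$ids, arr$fem_ids)  # record -> female slot or NA

  loo <- matrix(NA_real_, nrow = n, ncol = 4,
                dimnames = list(NULL, .jk_params))
  for (k in seq_len(n)) {
    i <- units[k]
    is_adult <- arr$fate[i] == "adult"
    fi <- fem_index[i]
    if (!is.na(fi)) {
      imm <- arr$imm[-fi]; lon <- arr$lon[-fi]; eggs <- arr$eggs[-fi]
    } else {
      imm <- arr$imm; lon <- arr$lon; eggs <- arr$eggs
    }
    if (length(imm) == 0L) {
      loo[k, ] <- c(0, NA, NA, NA)  # no females left: R0 = 0 by convention
      next
    }
    core <- .schedule_core(imm, lon, eggs,
                           n_eggs = arr$n_eggs - 1L,
                           n_adults = arr$n_adults - as.integer(is_adult),
                           age_origin)
    p <- .params_vec(core, tol)
    if (is.na(p["rm"])) p["R0"] <- sum(core$lx * core$mx)  # 0; keep explicit
    loo[k, ] <- p
  }

  out <- list()
  for (par in .jk_params) {
    th <- loo[, par]
    if (par == "R0") th[is.na(th)] <- 0
    pv <- ifelse(is.na(th), NA_real_, n * theta_all[par] - (n - 1) * th)
    flagged <- which(is.na(th))
    if (length(flagged) && par != "R0") {
      warning(sprintf(
        "%s: %d leave-one-out replicate(s) had R0 = 0; %s reported with n = %d",
        cohort$treatment, length(flagged), par, n - length(flagged)))
    }
    out[[par]] <- .new_jackknife_estimate(par, cohort$treatment,
                                          unname(theta_all[par]), pv, n,
                                          flagged)
  }
  out
}

#' Compare treatments with Tukey's test on jackknife pseudo-values
#'
#' One-way fixed-effects comparison of one parameter across treatments:
#' group means of the pseudo-values, pooled error variance with
#' df = sum(n_i - 1), Tukey-Kramer studentized-range p-values (valid for
#' unequal n) and a compact letter display ordered by descending mean.
#'
#' @param estimates List of `jackknife_estimate` objects for the same
#'   parameter, one per treatment.
#' @param alpha Significance level (default 0.05).
#' @return A `tukey_comparison`: per-treatment table (mean, se, n, letter),
#'   the pairwise decisions, pooled variance and df.
#' @export
compare_treatments <- function(estimates, alpha = 0.05) {
  params <- unique(vapply(estimates, function(e) e$parameter, character(1)))
  if (length(params) != 1) {
    stop("estimates mix parameters: ", paste(params, collapse = ", "))
  }
  pvs <- lapply(estimates, function(e) e$pseudo_values[!is.na(e$pseudo_values)])
  labels <- vapply(estimates, function(e) e$treatment, character(1))
  usable <- lengths(pvs) >= 2
  if (any(!usable)) {
    warning("treatment(s) with < 2 pseudo-values excluded: ",
            paste(labels[!usable], collapse = ", "))
    pvs <- pvs[usable]; labels <- labels[usable]; estimates <- estimates[usable]
  }
  if (length(pvs) < 2) stop("need at least 2 treatments to compare")
  ns <- lengths(pvs)
  means <- vapply(pvs, mean, numeric(1))
  df <- sum(ns - 1)
  s2 <- sum(vapply(pvs, function(v) sum((v - mean(v))^2), numeric(1))) / df
  tk <- .tukey_pairwise(labels, means, ns, s2, df, alpha)
  tab <- data.frame(
    treatment = labels,
    estimate = means,
    se = vapply(estimates, function(e) e$se, numeric(1)),
    n = ns,
    letter = tk$letters,
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(parameter = params, table = tab, pairwise = tk$pairwise,
                 pooled_var = s2, df = df, alpha = alpha),
            class = "tukey_comparison")
}

#' @export
print.tukey_comparison <- function(x, ...) {
  cat(sprintf("<tukey_comparison> %s (alpha = %g, df = %d)\n",
              x$parameter, x$alpha, x$df))
  print(x$table, row.names = FALSE)
  invisible(x)
}
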