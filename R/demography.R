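# The four population parameters of a schedule.
#
# R0 = sum lx*mx, T = sum x*lx*mx / R0, rm solves the discrete Euler-Lotka
# equation sum exp(-r x) lx mx = 1, lambda = exp(rm). Schedules are finite by
# construction (truncated at the last death), so all sums are exact.

#' Net reproductive rate
#'
#' Expected daughters per newborn female per generation, `sum(lx * mx)` over
#' the schedule's ages.
#' @param schedule A `life_schedule`.
#' @export
net_reproductive_rate <- function(schedule) {
  stopifnot(inherits(schedule, "life_schedule"))
  sum(schedule$lx * schedule$mx)
}

#' Mean generation time
#'
#' Reproduction-weighted mean age of mothers, in days:
#' `sum(x * lx * mx) / sum(lx * mx)`.
#' @param schedule A `life_schedule`.
#' @export
mean_generation_time <- function(schedule) {
  stopifnot(inherits(schedule, "life_schedule"))
  w <- schedule$lx * schedule$mx
  R0 <- sum(w)
  if (R0 <= 0) stop("mean generation time undefined: R0 = 0")
  sum(schedule$ages * w) / R0
}

#' Euler-Lotka residual
#'
#' `sum(exp(-r * x) * lx * mx) - 1`; zero at the intrinsic rate of increase.
#' At r = 0 it equals R0 - 1.
#' @param schedule A `life_schedule`.
#' @param r Growth rate(s), per day.
#' @export
euler_lotka_residual <- function(schedule, r) {
  stopifnot(inherits(schedule, "life_schedule"))
  w <- schedule$lx * schedule$mx
  x <- schedule$ages
  vapply(r, function(ri) sum(exp(-ri * x) * w) - 1, numeric(1))
}

#' Intrinsic rate of increase
#'
#' The unique real root of the discrete Euler-Lotka equation. The left side
#' is strictly decreasing in r whenever some reproduction occurs at an age
#' x > 0, so the root is found by bracketing (starting on \[-2, 2\] per day
#' and expanding geometrically if needed) followed by Brent refinement, and
#' is polished by bisection until the residual is within `tol`.
#'
#' @param schedule A `life_schedule` with R0 > 0.
#' @param tol Residual tolerance (default 1e-10).
#' @return The rate (per day), with a `solver` attribute: bracket, iteration
#'   count and final residual.
#' @export
intrinsic_rate <- function(schedule, tol = 1e-10) {
  stopifnot(inherits(schedule, "life_schedule"))
  w <- schedule$lx * schedule$mx
  x <- schedule$ages
  R0 <- sum(w)
  if (R0 <= 0) stop("intrinsic rate undefined: R0 = 0")
  if (sum(w[x > 0]) <= 0) {
    stop("intrinsic rate undefined: all reproduction at age 0")
  }
  f <- function(r) sum(exp(-r * x) * w) - 1
  lo <- -2; hi <- 2
  n_expand <- 0L
  while (f(hi) > 0) {
    hi <- hi * 2
    n_expand <- n_expand + 1L
    if (n_expand > 30L) stop("failed to bracket Euler-Lotka root above r = 2")
  }
  while (f(lo) < 0) {
    lo <- lo * 2
    n_expand <- n_expand + 1L
    if (n_expand > 30L) stop("failed to bracket Euler-Lotka root below r = -2")
  }
  sol <- stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.75)
  r <- sol$root
  res <- f(r)
  it <- sol$iter
  a <- lo; b <- hi
  while (abs(res) > tol && (b - a) > .Machine$double.eps * max(1, abs(r))) {
    if (res > 0) a <- r else b <- r
    r <- (a + b) / 2
    res <- f(r)
    it <- it + 1L
    if (it > 200L) break
  }
  if (abs(res) > tol) {
    warning(sprintf("Euler-Lotka residual %.3e exceeds tol %.1e", res, tol))
  }
  attr(r, "solver") <- list(bracket = c(lo, hi), iterations = it,
                            residual = res, tol = tol)
  r
}

#' Finite rate of increase
#'
#' Daily population multiplication factor, `exp(rm)`.
#' @param rm Intrinsic rate of increase (per day).
#' @export
finite_rate <- function(rm) {
  stopifnot(is.finite(rm))
  r <- as.numeric(rm)
  exp(r)
}

#' All four demographic parameters of a schedule
#'
#' @param schedule A `life_schedule`.
#' @param tol Euler-Lotka residual tolerance.
#' @return A `demographic_params` object: `R0`, `T`, `rm`, `lam` and the
#'   solver diagnostics. When R0 = 0 the rate parameters are NA (and flagged
#'   `degenerate`).
#' @export
demographic_params <- function(schedule, tol = 1e-10) {
  R0 <- net_reproductive_rate(schedule)
  if (R0 <= 0) {
    out <- list(R0 = R0, T = NA_real_, rm = NA_real_, lam = NA_real_,
                solver = NULL, degenerate = TRUE)
  } else {
    rm <- intrinsic_rate(schedule, tol = tol)
    out <- list(R0 = R0, T = mean_generation_time(schedule),
                rm = as.numeric(rm), lam = finite_rate(rm),
                solver = attr(rm, "solver"), degenerate = FALSE)
  }
  structure(out, class = "demographic_params")
}

#' @export
print.demographic_params <- function(x, ...) {
  if (x$degenerate) {
    cat("<demographic_params> degenerate (R0 = 0)\n")
  } else {
    cat(sprintf(
      "<demographic_params> R0 %.3f  T %.3f d  rm %.4f /d  lambda %.4f /d\n",
      x$R0, x$T, x$rm, x$lam))
    cat(sprintf("  Euler-Lotka residual %.2e in %d iterations\n",
                x$solver$residual, x$solver$iterations))
  }
  invisible(x)
}

# Fast path used by the jackknife: parameters straight from a schedule core
# list, skipping S3 wrapping. Returns c(R0, T, rm, lam); rate entries NA when
# R0 = 0.
.params_vec <- function(core, tol = 1e-10) {
  w <- core$lx * core$mx
  R0 <- sum(w)
  if (R0 <= 0) return(c(R0 = R0, T = NA_real_, rm = NA_real_, lam = NA_real_))
  x <- core$ages
  Tg <- sum(x * w) / R0
  f <- function(r) sum(exp(-r * x) * w) - 1
  lo <- -2; hi <- 2
  k <- 0L
  while (f(hi) > 0 && k < 30L) { hi <- hi * 2; k <- k + 1L }
  while (f(lo) < 0 && k < 30L) { lo <- lo * 2; k <- k + 1L }
  r <- stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.75)$root
  res <- f(r)
  a <- lo; b <- hi; it <- 0L
  while (abs(res) > tol && it < 200L) {
    if (res > 0) a <- r else b <- r
    r <- (a + b) / 2
    res <- f(r)
    it <- it + 1L
  }
  c(R0 = R0, T = Tg, rm = r, lam = exp(r))
}
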