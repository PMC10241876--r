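test_that("simulation is reproducible and respects cohort size", {
  cfg <- small_config(seed = 21)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_equal(co1, co2)
  expect_equal(nrow(co1$individuals), 20)
  expect_equal(co1$n_initial_eggs, 20L)

  # identical CSV bytes
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  q1 <- withr::local_tempfile(fileext = ".csv")
  q2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co1, p1, q1)
  write_cohort_csv(co2, p2, q2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  expect_identical(readBin(q1, "raw", file.size(q1)),
                   readBin(q2, "raw", file.size(q2)))

  # different seed, different draws
  co3 <- simulate_cohort(small_config(seed = 22))
  expect_false(identical(co1$fecundity, co3$fecundity))

  # simulate does not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulate_cohort(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("deleting an individual does not perturb the others' draws", {
  cfg <- small_config(seed = 33, n_eggs = 12)
  cfg_small <- small_config(seed = 33, n_eggs = 11)
  co_big <- simulate_cohort(cfg)
  co_small <- simulate_cohort(cfg_small)
  expect_equal(co_small$individuals, co_big$individuals[1:11, ])
})

test_that("degenerate deterministic chain yields identical individuals", {
  co <- simulate_cohort(identical_female_config(n_eggs = 4))
  ind <- co$individuals
  expect_true(all(ind$fate == "adult"))
  expect_true(all(ind$sex == "female"))
  expect_equal(unique(ind$adult_longevity), 10L)  # 3 + 5 + 2
  per_fem <- tapply(co$fecundity$eggs, co$fecundity$id, sum)
  expect_true(all(per_fem == 20))                 # 4 eggs/day * 5 days
  sc <- build_schedule(co)
  # emergence at 23 days; laying on ages 26..30; mx = 4 there
  expect_equal(sc$mx[27:31], rep(4, 5))
  expect_equal(sum(sc$lx * sc$mx), 20)
})

test_that("lost records are generated and excluded downstream", {
  cfg <- small_config(seed = 44)
  cfg$p_lost <- 0.3
  co <- simulate_cohort(cfg)
  n_lost <- sum(co$individuals$fate == "lost")
  expect_gt(n_lost, 0)
  ex <- apply_exclusions(co)
  expect_equal(ex$n_initial_eggs, 20L - n_lost)
})

test_that("analytic expectation equals the realization for deterministic configs", {
  cfg <- identical_female_config(n_eggs = 3)
  ae <- analytic_expectation(cfg)
  co <- simulate_cohort(cfg)
  sc <- build_schedule(co)
  expect_equal(ae$schedule$ages, sc$ages)
  expect_equal(ae$schedule$lx, sc$lx)
  expect_equal(ae$schedule$mx, sc$mx)
  expect_equal(ae$R0, 20)
  expect_equal(ae$rm, demographic_params(sc)$rm, tolerance = 1e-9)
})

test_that("two-point egg duration produces the convolved survival atoms", {
  cfg <- identical_female_config()
  cfg$stage_dists$egg <- as_duration_dist(list(support = c(8, 9),
                                               prob = c(0.5, 0.5)))
  ae <- analytic_expectation(cfg)
  # emergence at 23 or 24 days, death at 33 or 34; alive ages 0..33
  expect_equal(max(ae$schedule$ages), 33)
  expect_equal(ae$schedule$lx[33], 1.0)   # age 32: everyone alive
  expect_equal(ae$schedule$lx[34], 0.5)   # age 33: only the late emergers
})

test_that("expected rm satisfies Euler-Lotka on the expected schedule", {
  for (cfg in paper_calibrated_configs(seed = 1)) {
    ae <- analytic_expectation(cfg)
    expect_lt(abs(euler_lotka_residual(ae$schedule, ae$rm)), 1e-8)
  }
})

test_that("raising the daily egg mean raises R0", {
  # analytic: strict monotonicity
  r0s <- vapply(c(2, 4, 8), function(mu) {
    analytic_expectation(small_config(eggs_per_day = mu))$R0
  }, numeric(1))
  expect_true(all(diff(r0s) > 0))
  # realized, large n: one ordered pair
  lo <- apply_exclusions(simulate_cohort(small_config(seed = 55, n_eggs = 300,
                                                      eggs_per_day = 2)))
  hi <- apply_exclusions(simulate_cohort(small_config(seed = 55, n_eggs = 300,
                                                      eggs_per_day = 8)))
  expect_lt(net_reproductive_rate(build_schedule(lo)),
            net_reproductive_rate(build_schedule(hi)))
})

test_that("calibrated presets hit the published means at large n", {
  cfg <- paper_calibrated_configs(seed = 13, n_eggs = 2000)$mixed
  co <- simulate_cohort(cfg)
  ad <- co$individuals[co$individuals$fate == "adult", ]
  total_imm <- rowSums(ad[paste0("dur_", STAGES)])
  expect_lt(abs(mean(total_imm) - 21.6), 0.5)

  # analytic R0 within 10% of the published mixed-diet value
  ae <- analytic_expectation(paper_calibrated_configs(seed = 1)$mixed)
  expect_lt(abs(ae$R0 - 248.85) / 248.85, 0.10)

  # presets round-trip through CSV and validate cleanly
  cohorts <- lapply(paper_calibrated_configs(seed = 2), simulate_cohort)
  ip <- withr::local_tempfile(fileext = ".csv")
  fp <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(cohorts, ip, fp)
  back <- read_cohort_csv(ip, fp)
  for (tr in names(back)) {
    expect_equal(nrow(validate_cohort(back[[tr]])), 0)
  }
})

test_that("impossible configurations are rejected", {
  expect_error(as_duration_dist(list(support = integer(), prob = numeric())))
  expect_error(dist_shifted_pois(0.5))
  expect_error(cohort_config("x", stage_means = c(egg = 8), sex_ratio_p = 0.5,
                             preoviposition = 2, oviposition = 3,
                             postoviposition = 1, eggs_per_day = 4))
  expect_error(cohort_config(
    "x", stage_means = stats::setNames(rep(5, 6), STAGES), sex_ratio_p = 1.4,
    preoviposition = 2, oviposition = 3, postoviposition = 1,
    eggs_per_day = 4))
})
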