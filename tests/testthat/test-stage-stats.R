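test_that("Kruskal-Wallis H matches hand ranking and the stats oracle", {
  g <- list(a = c(1, 2), b = c(3, 4), c = c(5, 6))
  res <- kruskal_wallis_dscf(g)
  expect_equal(res$H, 32 / 7, tolerance = 1e-12)  # ranks 1..6 by hand
  expect_equal(res$df, 2)
  oracle <- kruskal.test(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(res$H, unname(oracle$statistic))
  expect_equal(res$p, oracle$p.value)

  # tie correction agrees with stats::kruskal.test
  gt <- list(a = c(1, 2, 2, 3), b = c(2, 3, 3, 4), c = c(5, 5, 6, 7))
  rest <- kruskal_wallis_dscf(gt)
  oraclet <- kruskal.test(gt)
  expect_equal(rest$H, unname(oraclet$statistic))

  # identical groups
  res0 <- kruskal_wallis_dscf(list(a = c(2, 2), b = c(2, 2)))
  expect_equal(res0$H, 0)
  expect_equal(res0$p, 1)
  expect_true(all(res0$letters == "a"))
})

test_that("KW H is invariant to monotone transformations", {
  set.seed(5)
  g <- list(a = rpois(8, 4), b = rpois(8, 6), c = rpois(8, 9))
  h1 <- kruskal_wallis_dscf(g)$H
  h2 <- kruskal_wallis_dscf(lapply(g, function(v) exp(v / 2)))$H
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("KW and DSCF decisions match exhaustive permutation oracles", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(7, 8, 9))
  res <- kruskal_wallis_dscf(g)

  # exact permutation distribution of H over all 9!/(3!3!3!) partitions
  pool <- unlist(g)
  kw_h <- function(x, grp) {
    r <- rank(x); N <- length(x)
    Rsum <- tapply(r, grp, sum)
    H <- 12 / (N * (N + 1)) * sum(Rsum^2 / 3) - 3 * (N + 1)
    ties <- table(x)
    H / (1 - sum(ties^3 - ties) / (N^3 - N))
  }
  grp0 <- rep(1:3, each = 3)
  hs <- apply(combn(9, 3), 2, function(i) {
    rest <- setdiff(1:9, i)
    sapply(combn(rest, 3, simplify = FALSE), function(j) {
      grp <- integer(9); grp[i] <- 1; grp[j] <- 2; grp[setdiff(rest, j)] <- 3
      kw_h(pool, grp)
    })
  })
  p_exact <- mean(hs >= kw_h(pool, grp0) - 1e-9)
  expect_equal(res$p < 0.05, p_exact < 0.05)

  # DSCF pairwise versus the exact two-sample rank-sum permutation
  # distribution (tie-safe); n = 3 vs 3 can never reach two-sided exact
  # p < 0.05 (the minimum attainable without ties is 2/20 = 0.1), and the
  # asymptotic DSCF agrees in decision
  exact_p <- function(x, y) {
    nx <- length(x); N <- nx + length(y)
    r <- rank(c(x, y)); W0 <- sum(r[seq_len(nx)]); E <- nx * (N + 1) / 2
    ws <- apply(combn(N, nx), 2, function(k) sum(r[k]))
    mean(abs(ws - E) >= abs(W0 - E) - 1e-9)
  }
  for (r in seq_len(nrow(res$pairwise))) {
    pr <- res$pairwise[r, ]
    pe <- exact_p(g[[pr$group1]], g[[pr$group2]])
    expect_equal(pr$significant, pe < 0.05)
    expect_false(pr$significant)
  }
})

test_that("KW/DSCF with two groups tracks the rank-sum test", {
  for (s in 1:20) {
    set.seed(600 + s)
    g <- list(a = rpois(7, 5), b = rpois(9, 5 + (s %% 5)))
    res <- kruskal_wallis_dscf(g)
    w <- suppressWarnings(wilcox.test(g$a, g$b, exact = FALSE,
                                      correct = FALSE))
    # KW with k = 2 is the squared tie-corrected normal rank-sum statistic
    expect_equal(res$p, w$p.value, tolerance = 1e-9)
  }
})

test_that("one-way ANOVA and Tukey-Kramer match their classical forms", {
  set.seed(9)
  g <- list(a = rnorm(8, 10), b = rnorm(6, 11), c = rnorm(7, 14))
  res <- anova_tukey(g)
  df <- data.frame(y = unlist(g), grp = rep(names(g), lengths(g)))
  fit <- aov(y ~ grp, data = df)
  expect_equal(res$F, unname(summary(fit)[[1]]$`F value`[1]), tolerance = 1e-10)
  expect_equal(res$p, unname(summary(fit)[[1]]$`Pr(>F)`[1]), tolerance = 1e-10)
  thsd <- TukeyHSD(fit)$grp
  ours <- res$pairwise
  for (r in seq_len(nrow(thsd))) {
    pair <- strsplit(rownames(thsd)[r], "-")[[1]]
    i <- which((ours$group1 == pair[1] & ours$group2 == pair[2]) |
                 (ours$group1 == pair[2] & ours$group2 == pair[1]))
    expect_equal(ours$p[i], unname(thsd[r, "p adj"]), tolerance = 1e-8)
  }

  # F equals the squared pooled t statistic for two groups
  g2 <- g[1:2]
  res2 <- anova_tukey(g2)
  tt <- t.test(g2$a, g2$b, var.equal = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res2$p, tt$p.value, tolerance = 1e-10)

  # degenerate: identical groups
  res0 <- anova_tukey(list(a = c(3, 3), b = c(3, 3)))
  expect_equal(res0$F, 0)
  expect_true(all(res0$letters == "a"))
})

test_that("stage_duration_summary counts completers per stage", {
  cohorts <- lapply(c(A = 1, B = 2), function(s) {
    apply_exclusions(simulate_cohort(small_config(seed = s,
                                                  treatment = paste0("tr", s))))
  })
  sm <- stage_duration_summary(cohorts)
  expect_named(sm, c(STAGES, "total_immature"))
  for (i in seq_along(cohorts)) {
    co <- cohorts[[i]]
    expect_equal(sm$egg$groups$n[i], sum(!is.na(co$individuals$dur_egg)))
    expect_equal(sm$total_immature$groups$n[i],
                 sum(co$individuals$fate == "adult"))
    expect_equal(sm$total_immature$groups$mean[i],
                 mean(rowSums(co$individuals[co$individuals$fate == "adult",
                                             paste0("dur_", STAGES)])))
  }
  expect_equal(sm$egg$test, "kruskal_wallis_dscf")
})

test_that("reproductive_summary handles non-laying females", {
  # 7 adult females, 3 layers (aphid-like n accounting)
  layers <- list(list(eggs = c(0, 2, 3, 0, 1), lon = 8),
                 list(eggs = c(1, 1), lon = 6),
                 list(eggs = c(0, 0, 4), lon = 5))
  nonlayers <- rep(list(list(eggs = numeric(), lon = 7)), 4)
  co <- toy_cohort("aphidlike", females = c(layers, nonlayers))
  co2 <- apply_exclusions(simulate_cohort(small_config(seed = 3,
                                                       treatment = "other")))
  sm <- suppressWarnings(reproductive_summary(list(co, co2)))
  g <- function(v) sm[[v]]$groups[sm[[v]]$groups$treatment == "aphidlike", ]
  expect_equal(g("fecundity")$n, 7)
  expect_equal(g("oviposition")$n, 3)
  expect_equal(g("longevity")$n, 7)
  # non-layers contribute zeros to mean fecundity
  expect_equal(g("fecundity")$mean, (6 + 2 + 4) / 7)
  # period decomposition: pre + ovi + post = longevity for each layer
  expect_equal(g("preoviposition")$mean + g("oviposition")$mean +
                 g("postoviposition")$mean, mean(c(8, 6, 5)))
  # first layer: first egg day 2, last day 5 -> pre 1, ovi 4, post 3
  expect_equal(sm$preoviposition$test, "anova_tukey")
  expect_equal(sm$oviposition$test, "kruskal_wallis_dscf")

  # all females lay -> oviposition n equals fecundity n
  co3 <- toy_cohort("all-lay", females = list(list(eggs = c(2, 2), lon = 3),
                                              list(eggs = 4, lon = 2)))
  sm3 <- suppressWarnings(reproductive_summary(list(co3, co2)))
  g3 <- sm3$oviposition$groups[sm3$oviposition$groups$treatment == "all-lay", ]
  expect_equal(g3$n, 2)
})

test_that("headline ratios reproduce the published effect sizes", {
  fec <- c(mixed = 497.7, aphids = 5.7)
  imm <- c(mixed = 21.6, aphids = 24.8)
  hr <- headline_ratios(fec, imm, "mixed", "aphids")
  expect_equal(hr$fecundity_fold, 87.3)
  expect_equal(hr$immature_reduction_pct, 13)

  # identity case
  hr0 <- headline_ratios(c(x = 3, y = 3), c(x = 10, y = 10), "x", "y")
  expect_equal(hr0$fecundity_fold, 1.0)
  expect_equal(hr0$immature_reduction_pct, 0)

  # zero denominator
  expect_warning(hrz <- headline_ratios(c(x = 3, y = 0), c(x = 1, y = 2),
                                        "x", "y"), "zero")
  expect_true(is.na(hrz$fecundity_fold))

  # group_summary input route
  co <- toy_cohort("A", females = list(list(eggs = c(5, 5), lon = 3)))
  co2 <- toy_cohort("B", females = list(list(eggs = c(1, 1), lon = 3)))
  sm <- suppressWarnings(reproductive_summary(list(co, co2)))
  smd <- suppressWarnings(stage_duration_summary(list(co, co2)))
  hr2 <- headline_ratios(sm$fecundity, smd$total_immature, "A", "B")
  expect_equal(hr2$fecundity_fold, 5)
})
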