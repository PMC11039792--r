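test_that("signed-rank worked examples match enumeration", {
  r1 <- wilcoxon_signed_rank(c(1, 2, 3))
  expect_equal(r1$statistic, 6)
  expect_equal(r1$p_value, 0.25)
  expect_true(r1$exact)

  r2 <- wilcoxon_signed_rank(c(-1, 1))          # tied magnitudes -> midranks
  expect_equal(r2$statistic, 1.5)
  expect_equal(r2$p_value, 1)

  r3 <- wilcoxon_signed_rank(5)
  expect_equal(r3$statistic, 1)
  expect_equal(r3$p_value, 1)

  expect_warning(r4 <- wilcoxon_signed_rank(c(0, 0, 0)), "zero")
  expect_equal(r4$p_value, 1)
})

test_that("rank-sum worked examples match enumeration", {
  r <- exact_wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 3)            # midrank sum of x
  expect_equal(r$p_value, 2 / 6)
  expect_true(r$exact)

  expect_equal(exact_wilcoxon_rank_sum(c(7, 7), c(7, 7))$p_value, 1)
})

test_that("exact p-values equal brute force for all small tied inputs", {
  set.seed(101)
  # signed-rank: random tie-rich differences, n <= 8
  for (i in 1:60) {
    n <- sample(1:8, 1)
    d <- sample(-3:3, n, replace = TRUE)
    if (all(d == 0)) d[1] <- 1
    got <- suppressWarnings(wilcoxon_signed_rank(d))
    expect_equal(got$p_value, oracle_signed_rank_p(d), tolerance = 1e-12)
  }
  # rank-sum: random tie-rich groups, n + m <= 10
  for (i in 1:60) {
    n <- sample(1:5, 1); m <- sample(1:5, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:4, m, replace = TRUE)
    got <- exact_wilcoxon_rank_sum(x, y)
    expect_equal(got$p_value, oracle_rank_sum_p(x, y), tolerance = 1e-12)
  }
})

test_that("tie-free exact p-values agree with the classical distribution", {
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1))
    expect_equal(exact_wilcoxon_rank_sum(x, y)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
    d <- rnorm(sample(4:10, 1))
    expect_equal(wilcoxon_signed_rank(d)$p_value,
                 wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis H and rank eta-squared match the worked example", {
  g <- factor(c("a", "a", "b", "b"))
  kt <- kruskal_wallis_eta2(c(1, 2, 3, 4), g)
  expect_equal(kt$statistic, 2.4, tolerance = 1e-12)
  expect_equal(kt$effect_size, 0.7, tolerance = 1e-12)

  # invariance under strictly monotone transforms
  kt2 <- kruskal_wallis_eta2(exp(c(1, 2, 3, 4)), g)
  expect_equal(kt2$statistic, kt$statistic)

  deg <- kruskal_wallis_eta2(rep(2, 5), factor(c(1, 1, 2, 2, 2)))
  expect_equal(deg$statistic, 0)
  expect_equal(deg$p_value, 1)
  expect_equal(deg$effect_size, 0)
})

test_that("eta-squared grows with separation and stays in [0, 1]", {
  set.seed(33)
  shifts <- c(0, 0.5, 1.5, 4)
  e2 <- vapply(shifts, function(s) {
    x <- c(rnorm(15), rnorm(15, s), rnorm(15, 2 * s))
    g <- factor(rep(1:3, each = 15))
    kruskal_wallis_eta2(x, g)$effect_size
  }, 0)
  expect_true(all(e2 >= 0 & e2 <= 1))
  expect_true(e2[4] > e2[1])
  expect_true(e2[4] > e2[2])
})

test_that("Steel-Dwass behaves on degenerate and separated groups", {
  g <- factor(rep(1:3, each = 3))
  same <- steel_dwass(rep(c(5, 6, 7), 3), g)
  expect_true(all(same$p_adjusted > 0.9))

  sep <- steel_dwass(c(1, 2, 3, 4, 5, 6, 7, 8, 9), g)
  i13 <- with(sep, which((group_a == "1" & group_b == "3")))
  expect_true(all(sep$p_adjusted[i13] <= sep$p_adjusted + 1e-12))
  expect_true(all(abs(sep$z) > 0))

  # family-wise adjustment is never anti-conservative against its own
  # pairwise asymptotic test: adjusted p >= two-sided normal p of the same z
  set.seed(9)
  x <- rnorm(20); g4 <- factor(rep(1:4, each = 5))
  sd4 <- steel_dwass(x, g4)
  expect_true(all(sd4$p_adjusted + 1e-9 >= 2 * pnorm(-abs(sd4$z))))

  # k = 2 delegates to the exact rank-sum test
  g2 <- factor(rep(1:2, each = 3))
  d2 <- steel_dwass(c(1, 2, 3, 10, 11, 12), g2)
  expect_equal(d2$p_adjusted,
               exact_wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))$p_value)

  expect_error(steel_dwass(1:4, factor(c(1, 1, 2, 3))), "at least 2")
})

test_that("Steel-Dwass isolates a single shifted group", {
  set.seed(18)
  x <- c(rnorm(8), rnorm(8), rnorm(8), rnorm(8, 3))
  g <- factor(rep(1:4, each = 8))
  res <- steel_dwass(x, g)
  with_shifted <- res$group_a == "4" | res$group_b == "4"
  expect_true(all(res$p_adjusted[with_shifted] < 0.05))
  expect_true(all(res$p_adjusted[!with_shifted] >= 0.05))
})

test_that("asymptotic Steel-Dwass agrees with the permutation reference", {
  set.seed(71)
  x <- c(rnorm(8), rnorm(8, 1.2), rnorm(8, 2.5))
  g <- factor(rep(1:3, each = 8))
  asym <- steel_dwass(x, g)
  perm <- steel_dwass(x, g, method = "permutation", n_perm = 4000, seed = 1)
  expect_equal(asym$p_adjusted, perm$p_adjusted, tolerance = 0.06)
})

test_that("covariate screen flags a planted PPI effect and skips constants", {
  co <- generate_cohort(sim_config(n_participants = 49, seed = 14,
                                   beta = c(age_trend = 0, hypertension = 0,
                                            ppi = log(4))))
  prof <- translocation_scores(co$table, co$pairings)
  expect_warning(
    scr <- covariate_screen(prof, cbind(co$pairings,
                                        constant = factor(rep("x", 49)))),
    "constant")
  row <- scr$screen[scr$screen$factor == "ppi", ]
  expect_lt(row$p_value, 0.05)
  expect_true("ppi" %in% names(scr$posthoc))
  expect_true("constant" %in% scr$skipped)
  # eta2 of the planted factor beats a null binary factor
  expect_gt(row$eta2, scr$screen$eta2[scr$screen$factor == "smoking"])
})
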