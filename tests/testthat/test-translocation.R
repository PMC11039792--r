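test_that("relative abundances normalise rows to one", {
  m <- matrix(c(5, 5, 1000, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("A1", "A2")))
  ra <- relative_abundance(count_table(m))
  expect_equal(ra["S1", ], c(A1 = 0.5, A2 = 0.5))
  expect_equal(ra["S2", ], c(A1 = 1, A2 = 0))
  tab <- random_table(10, 50, seed = 21)
  expect_true(all(abs(rowSums(relative_abundance(tab)) - 1) < 1e-12))
})

test_that("source ASV identification is boundary-inclusive at 0.1%", {
  m <- matrix(c(500, 300, 199, 1), 1, 4,
              dimnames = list("T1", c("a", "b", "c", "d")))
  m <- count_table(rbind(m, R1 = c(1, 1, 1, 997)))
  expect_setequal(identify_source_asvs(m, "T1"), c("a", "b", "c", "d"))
  m2 <- count_table(matrix(c(9995, 5, 1, 1), 2, 2, byrow = TRUE,
                           dimnames = list(c("T1", "R1"), c("a", "b"))))
  expect_equal(identify_source_asvs(m2, "T1"), "a")
})

test_that("pair scores match the hand-computed toy and limits", {
  # tongue ASVs {a,b}; rectal a=0.02, b=0, c=0.98 over rectal ASVs {a,c}
  m <- matrix(c(600, 400, 0,
                2, 0, 98), 2, 3, byrow = TRUE,
              dimnames = list(c("T1", "R1"), c("a", "b", "c")))
  sc <- pair_scores(count_table(m), "T1", "R1")
  expect_setequal(sc$source_asvs, c("a", "b"))
  expect_equal(sc$abundance_score, 0.02)
  expect_equal(sc$richness_fraction, 1 / 2)
  expect_true(sc$detected)

  # disjoint tongue/rectal sets
  m2 <- matrix(c(10, 10, 0, 0,
                 0, 0, 10, 10), 2, 4, byrow = TRUE,
               dimnames = list(c("T1", "R1"), letters[1:4]))
  sc2 <- pair_scores(count_table(m2), "T1", "R1")
  expect_equal(sc2$abundance_score, 0)
  expect_equal(sc2$richness_fraction, 0)
  expect_false(sc2$detected)

  # self-pairing: score = 1 minus the sub-threshold tail
  m3 <- matrix(c(899, 100, 1, 1000), 2, 2, byrow = TRUE,
               dimnames = list(c("T1", "R1"), c("a", "b")))
  sc3 <- pair_scores(count_table(m3), "T1", "T1")
  expect_equal(sc3$abundance_score, 1)
})

test_that("abundance score equals brute-force summation on random tables", {
  set.seed(77)
  for (i in 1:25) {
    n_asv <- sample(3:20, 1)
    tab <- random_table(2, n_asv, lambda = sample(c(2, 30, 200), 1))
    rownames(tab) <- c("T1", "R1")
    tab <- count_table(unclass(tab))
    sc <- pair_scores(tab, "T1", "R1")
    expect_equal(sc$abundance_score,
                 oracle_abundance_score(unclass(tab), "T1", "R1"),
                 tolerance = 1e-12)
  }
})

test_that("abundance score is monotone in the right directions", {
  tab <- random_table(2, 12, seed = 8)
  rownames(tab) <- c("T1", "R1")
  tab <- count_table(unclass(tab))
  src <- identify_source_asvs(tab, "T1")
  non_src <- setdiff(colnames(tab), src)
  base <- pair_scores(tab, "T1", "R1")$abundance_score
  m_up <- unclass(tab); m_up["R1", src[1]] <- m_up["R1", src[1]] + 50
  expect_gte(pair_scores(count_table(m_up), "T1", "R1")$abundance_score, base)
  if (length(non_src)) {
    m_dn <- unclass(tab); m_dn["R1", non_src[1]] <- m_dn["R1", non_src[1]] + 50
    expect_lte(pair_scores(count_table(m_dn), "T1", "R1")$abundance_score, base)
  }
})

test_that("log-scale Bray-Curtis matches closed forms", {
  m <- matrix(c(9, 0, 9, 9,
                0, 9, 9, 0), 2, 4, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("a", "b", "c", "d")))
  tab <- count_table(m)
  # identical sample with itself
  expect_equal(bray_curtis_log(tab, "S1", "S1"), 0)
  # u=(9,0), v=(0,9) -> log10 transform (1,0) vs (0,1) -> BC = 1
  sub <- subset_count_table(tab, asvs = c("a", "b"))
  expect_equal(bray_curtis_log(sub, "S1", "S2"), 1)
  # u=(9,9), v=(9,0) -> (1,1) vs (1,0) -> BC = 1/3
  sub2 <- count_table(matrix(c(9, 9, 9, 0), 2, 2, byrow = TRUE,
                             dimnames = list(c("S1", "S2"), c("c", "d"))))
  expect_equal(bray_curtis_log(sub2, "S1", "S2"), 1 / 3)
  # fully disjoint ASV sets -> 1
  dis <- count_table(matrix(c(5, 7, 0, 0, 0, 0, 3, 4), 2, 4, byrow = TRUE,
                            dimnames = list(c("S1", "S2"), letters[1:4])))
  expect_equal(bray_curtis_log(dis, "S1", "S2"), 1)
})

test_that("intra/inter comparison handles degeneracy and matches the oracle", {
  # identical tongues for everyone -> all differences zero -> p = 1 + warning
  set.seed(12)
  base_t <- rpois(8, 40) + 1
  base_r <- rpois(8, 40) + 1
  rows <- list()
  for (i in 1:3) {
    rows[[paste0("T", i)]] <- base_t
    rows[[paste0("R", i)]] <- base_r
  }
  m <- do.call(rbind, rows)
  colnames(m) <- paste0("A", 1:8)
  tab <- count_table(m)
  pairs <- as_cohort_pairing(data.frame(participant_id = paste0("P", 1:3),
                                        tongue_sample_id = paste0("T", 1:3),
                                        rectal_sample_id = paste0("R", 1:3)),
                             table = tab)
  expect_warning(res <- intra_inter_comparison(tab, pairs,
                                               metric = "abundance_score"),
                 "zero")
  expect_equal(res$p_value, 1)

  # n = 3 statistic equals the enumeration oracle on the same metric matrix
  tab2 <- random_table(6, 15, lambda = 2, seed = 31)
  rownames(tab2) <- c(paste0("T", 1:3), paste0("R", 1:3))
  tab2 <- count_table(unclass(tab2))
  res2 <- intra_inter_comparison(tab2, pairs, metric = "abundance_score")
  d <- res2$per_participant$intra - res2$per_participant$inter
  expect_equal(res2$p_value, oracle_signed_rank_p(d), tolerance = 1e-12)
  # metric matrix cross-check by direct pair scoring
  M <- res2$metric_matrix
  expect_equal(M["P2", "P1"],
               pair_scores(tab2, "T1", "R2")$abundance_score)

  expect_error(intra_inter_comparison(tab2, pairs[1:2, ]), "3 participants")
})

test_that("PCoA reproduces known geometry and reports all eigenvalues", {
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  p3 <- pcoa(d3)
  ev <- p3$eigenvalues
  expect_equal(ev[1], ev[2], tolerance = 1e-9)
  expect_lt(abs(ev[3]), 1e-9)

  # distances from known 2-D coordinates: recovered up to rotation/reflection
  set.seed(2)
  X <- matrix(rnorm(20), 10, 2)
  D <- as.matrix(dist(X))
  pc <- pcoa(D, k = 2)
  Y <- pc$coordinates
  # rotation/reflection-invariant check: inter-point distances reproduced
  expect_lt(max(abs(as.matrix(dist(Y)) - D)), 1e-8)

  # two points: one positive eigenvalue, separation = distance
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  p2 <- pcoa(d2)
  expect_equal(sum(p2$eigenvalues > 1e-8), 1)
  expect_equal(unname(abs(diff(p2$coordinates[, 1]))), 3)

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})
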