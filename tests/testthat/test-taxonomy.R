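make_reference <- function() {
  set.seed(9)
  base <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  other <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  ref <- c(base, other)
  names(ref) <- c("Streptococcus_salivarius|HMT-755",
                  "Prevotella_melaninogenica|HMT-469")
  attr(ref, "taxa") <- data.frame(id = names(ref),
                                  taxon = c("Streptococcus salivarius",
                                            "Prevotella melaninogenica"),
                                  hmt = c("HMT-755", "HMT-469"),
                                  stringsAsFactors = FALSE)
  ref
}

mutate_at <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) ch[p] <- chartr("ACGT", "CAGT", ch[p])
  # ensure a real substitution at every position
  ch2 <- strsplit(seq, "")[[1]]
  for (p in positions) if (ch[p] == ch2[p]) ch[p] <- if (ch2[p] == "A") "G" else "A"
  paste(ch, collapse = "")
}

test_that("species assignment applies the 98.5% identity threshold", {
  ref <- make_reference()
  q <- c(exact = as.character(ref[1]),
         two_mm = mutate_at(ref[[1]], c(50, 150)),
         six_mm = mutate_at(ref[[1]], c(10, 60, 110, 160, 210, 260)))
  tx <- assign_species(q, ref)
  expect_true(tx$assigned[tx$asv_id == "exact"])
  expect_equal(tx$identity[tx$asv_id == "exact"], 100)
  expect_equal(tx$taxon[tx$asv_id == "exact"], "Streptococcus salivarius")
  expect_equal(tx$hmt[tx$asv_id == "exact"], "HMT-755")

  expect_true(tx$assigned[tx$asv_id == "two_mm"])
  expect_equal(tx$identity[tx$asv_id == "two_mm"], 100 * 298 / 300,
               tolerance = 1e-8)

  expect_false(tx$assigned[tx$asv_id == "six_mm"])
  expect_equal(tx$identity[tx$asv_id == "six_mm"], 98, tolerance = 1e-6)
})

test_that("duplicated references change candidate multiplicity, not identity", {
  ref <- make_reference()
  dup <- c(ref, ref[1])
  names(dup)[3] <- "Streptococcus_salivarius_copy|HMT-755"
  attr(dup, "taxa") <- rbind(attr(ref, "taxa"),
                             data.frame(id = names(dup)[3],
                                        taxon = "Streptococcus salivarius copy",
                                        hmt = "HMT-755"))
  q <- c(q1 = as.character(ref[1]))
  t1 <- assign_species(q, ref)
  t2 <- assign_species(q, dup)
  expect_equal(t1$identity, t2$identity)
  expect_equal(nrow(t1$candidates[[1]]), 1)
  expect_equal(nrow(t2$candidates[[1]]), 2)
  # tied candidates merge under a sorted compound label
  expect_equal(t2$taxon, "Streptococcus salivarius/Streptococcus salivarius copy")
})

test_that("contaminant filtering follows the control-dominance rule", {
  m <- matrix(c(
    # A1 contaminant: 40% of NC, trace in biology; A2 genuine; A3 NC-absent
    1,  500, 499,
    2,  600, 398,
    400, 550,  50), nrow = 3, byrow = TRUE,
    dimnames = list(c("B1", "B2", "NC"), c("A1", "A2", "A3")))
  tab <- count_table(m)
  rule <- contaminant_rule("NC", min_nc_relative_abundance = 0.005)
  res <- filter_contaminants(tab, rule)
  expect_equal(res$removed, "A1")
  expect_false("NC" %in% rownames(res$table))
  expect_true(all(c("A2", "A3") %in% colnames(res$table)))

  # never removes an ASV absent from controls unless blocklisted
  expect_false("A3" %in% res$removed)

  tx <- data.frame(asv_id = c("A1", "A2", "A3"), assigned = TRUE,
                   identity = 100,
                   taxon = c("Pseudomonas fluorescens", "X y", "Z w"),
                   hmt = NA, stringsAsFactors = FALSE)
  res2 <- filter_contaminants(tab, contaminant_rule(
    "NC", blocklist = "Pseudomonas fluorescens"), taxonomy = tx)
  expect_true("A1" %in% res2$removed)

  expect_error(filter_contaminants(tab, contaminant_rule("missing")), "absent")
})

test_that("taxon collapsing conserves per-sample totals", {
  tab <- random_table(4, 6, seed = 3)
  tx <- data.frame(asv_id = colnames(tab), assigned = c(rep(TRUE, 4), FALSE, FALSE),
                   identity = 99,
                   taxon = c("S parasanguinis", "S parasanguinis", "F magna",
                             "F magna", NA, NA),
                   stringsAsFactors = FALSE)
  col <- collapse_to_taxon(tab, tx)
  expect_equal(unname(rowSums(col)), unname(rowSums(tab)))
  expect_setequal(colnames(col), c("S parasanguinis", "F magna", "unassigned"))
  expect_equal(unname(unclass(col)[, "S parasanguinis"]),
               unname(rowSums(unclass(tab)[, 1:2])))

  tx$taxon <- NA
  all_un <- collapse_to_taxon(tab, tx)
  expect_equal(colnames(all_un), "unassigned")
  expect_equal(unname(unclass(all_un)[, 1]), unname(rowSums(tab)))
})

test_that("predominant taxa use an inclusive mean-abundance threshold", {
  m <- matrix(c(2, 0,
                98, 80,
                0, 20), nrow = 2, byrow = FALSE,
              dimnames = list(c("S1", "S2"), c("edge", "big", "mid")))
  tab <- count_table(m)
  # edge: 2% and 0% -> mean exactly 1% -> included
  expect_true("edge" %in% predominant_taxa(tab, 0.01))
  expect_false("zero" %in% predominant_taxa(tab, 0.01))
  expect_equal(predominant_taxa(tab, 0.01)[1], "big")

  # planted recovery: taxa above 0.1% by construction
  set.seed(4)
  planted <- random_table(10, 40, lambda = 50)
  truth <- predominant_taxa(planted, 0)
  mu <- colMeans(relative_abundance(planted))
  expect_setequal(predominant_taxa(planted, 0.001), names(mu)[mu >= 0.001])
})
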