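# Independent brute-force oracles, kept deliberately naive.

# Two-sided exact signed-rank p by full enumeration of all 2^n sign patterns
# (midranks for tied magnitudes, zeros dropped, doubling convention).
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  v_all <- apply(signs, 1, function(s) sum(r[unlist(s)]))
  p_le <- mean(v_all <= v_obs + 1e-9)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Two-sided exact rank-sum p by enumerating all C(n+m, n) group assignments.
oracle_rank_sum_p <- function(x, y) {
  n <- length(x); N <- n + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)])
  combos <- utils::combn(N, n)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Translocation abundance score by explicit loops over ASVs.
oracle_abundance_score <- function(counts, tongue, rectal, threshold = 0.001) {
  tongue_total <- sum(counts[tongue, ])
  rectal_total <- sum(counts[rectal, ])
  score <- 0
  for (a in colnames(counts)) {
    if (counts[tongue, a] / tongue_total >= threshold)
      score <- score + counts[rectal, a] / rectal_total
  }
  score
}

# Small deterministic count table fixture.
toy_table <- function() {
  m <- matrix(c(10, 0,
                5, 5,
                0, 20), nrow = 3, byrow = TRUE,
              dimnames = list(c("S1", "S2", "S3"), c("A1", "A2")))
  count_table(m)
}

random_table <- function(n_samples, n_asvs, lambda = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    m <- matrix(rpois(n_samples * n_asvs, lambda), n_samples, n_asvs,
                dimnames = list(paste0("S", seq_len(n_samples)),
                                paste0("A", seq_len(n_asvs))))
    if (all(rowSums(m) > 0)) return(count_table(m))
  }
}

demo_scheme <- function(n_samples = 3) {
  bases <- c("A", "C", "G", "T")
  set.seed(42)
  tags <- data.frame(
    sample_id = paste0("S", seq_len(n_samples)),
    tag5 = replicate(n_samples, paste(sample(bases, 8, TRUE), collapse = "")),
    tag3 = replicate(n_samples, paste(sample(bases, 8, TRUE), collapse = "")),
    stringsAsFactors = FALSE)
  tag_scheme(tags, forward_primer = "AGAGTTTGATYMTGGCTCAG",
             reverse_primer = "TGCTGCCTCCCGTAGGAGT")
}

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, ""), function(s)
    paste(rev(s), collapse = ""), ""))
}

# Assemble a valid read for a sample under the fixed layout.
make_read <- function(scheme, sample_id, insert,
                      fwd = "AGAGTTTGATCATGGCTCAG", rev = "TGCTGCCTCCCGTAGGAGT") {
  tg <- scheme$tags[scheme$tags$sample_id == sample_id, ]
  paste0(tg$tag5, fwd, insert, revcomp_chr(rev), revcomp_chr(tg$tag3))
}
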