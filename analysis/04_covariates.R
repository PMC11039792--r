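#!/usr/bin/env Rscript
# Covariate screen of the translocation abundance score: one Kruskal-Wallis
# test with rank eta-squared per clinical factor, followed by Steel-Dwass or
# exact rank-sum post-hoc comparisons for significant factors.

library(oralflux)

profiles <- utils::read.delim("results/translocation_profiles.tsv")
pairs <- read_pairing("results/cohort/pairings.tsv")

scr <- covariate_screen(profiles, pairs, alpha = 0.05)
utils::write.table(scr$screen, "results/covariate_screen.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("factors ranked by rank eta-squared:\n")
print(scr$screen, row.names = FALSE, digits = 3)

if (length(scr$posthoc)) {
  ph <- do.call(rbind, lapply(names(scr$posthoc), function(f)
    data.frame(factor = f, scr$posthoc[[f]])))
  utils::write.table(ph, "results/covariate_posthoc.tsv",
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat("\npost-hoc pairwise comparisons for significant factors:\n")
  print(ph, row.names = FALSE, digits = 3)
} else {
  cat("\nno factor significant at alpha = 0.05; no post-hoc stage\n")
}
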