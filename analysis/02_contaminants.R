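#!/usr/bin/env Rscript
# Exclude PCR contaminants identified from the negative control and drop the
# control sample, mirroring the pre-analysis cleanup applied to amplicon
# runs. Writes the filtered table under results/cohort/.

library(oralflux)

counts <- read_count_table("results/cohort/asv_counts.tsv")
rule <- contaminant_rule("NC01", min_nc_relative_abundance = 0.005)
res <- filter_contaminants(counts, rule)

write_count_table(res$table, "results/cohort/asv_counts_filtered.tsv")
writeLines(res$removed, "results/cohort/removed_contaminants.txt")

cat(sprintf("removed %d contaminant ASV(s): %s\n", length(res$removed),
            paste(res$removed, collapse = ", ")))
cat(sprintf("filtered table: %d samples x %d ASVs\n",
            nrow(res$table), ncol(res$table)))
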