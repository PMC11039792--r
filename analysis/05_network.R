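#!/usr/bin/env Rscript
# Co-occurrence structure of the rectal community: collapse ASVs to their
# generating taxa, keep taxa with >= 0.1% mean relative abundance across the
# rectal samples, estimate SparCC correlations, and extract cohabiting
# groups as connected components at the r >= 0.4 edge threshold.

library(oralflux)

counts <- read_count_table("results/cohort/asv_counts_filtered.tsv")
pairs <- read_pairing("results/cohort/pairings.tsv", table = counts)
asv_map <- utils::read.delim("results/cohort/asv_map.tsv")

species <- collapse_to_taxon(counts, asv_map[, c("asv_id", "taxon")])
sel <- select_network_taxa(species, pairs$rectal_sample_id,
                           min_mean_rel_abundance = 0.001)
cat(sprintf("%d taxa with >= 0.1%% mean relative abundance in the rectal microbiota\n",
            ncol(sel)))

corr <- sparcc(sel)
net <- build_network(corr, edge_threshold = 0.4)
write_edge_list(net, "results/network_edges.tsv")

cat(sprintf("%d edges at SparCC r >= 0.4; %d cohabiting group(s)\n",
            nrow(net$edges), length(net$components)))
oral_side <- unique(asv_map$taxon[asv_map$pool %in% c("oral", "shared")])
for (i in seq_along(net$components)) {
  comp <- net$components[[i]]
  cat(sprintf("  group %d (%d taxa, %d tongue-side): %s\n", i, length(comp),
              sum(comp %in% oral_side),
              paste(utils::head(comp, 6), collapse = ", ")))
}
comp_df <- do.call(rbind, lapply(seq_along(net$components), function(i)
  data.frame(group = i, taxon = net$components[[i]])))
if (!is.null(comp_df))
  utils::write.table(comp_df, "results/network_components.tsv",
                     sep = "\t", quote = FALSE, row.names = FALSE)
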