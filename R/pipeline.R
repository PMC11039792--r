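#' End-to-end analysis run
#'
#' Orchestrates the analysis stages over a count table and pairing: optional
#' contaminant filtering, per-participant translocation profiles, the three
#' intra- versus inter-pair comparisons, the covariate screen, and the
#' co-occurrence network on predominant rectal taxa. All result tables are
#' written under `outdir` together with a manifest recording parameters,
#' seed, package version and the MD5 of every output, so a re-run with the
#' same inputs is byte-identical in deterministic mode.
#'
#' @param table a [count_table()] (ASV level), or a TSV path
#' @param pairings a `cohort_pairing`, or a TSV path
#' @param outdir output directory
#' @param taxonomy optional `taxonomy_map`; when given, the network stage
#'   runs on species-collapsed counts
#' @param contaminants optional [contaminant_rule()]
#' @param trans_params a [translocation_params()]
#' @param sparcc_parameters a [sparcc_params()]
#' @param network_min_abundance mean relative-abundance floor for network
#'   taxa (default 0.001)
#' @param edge_threshold network edge threshold on r (default 0.4)
#' @param screen_alpha significance level of the covariate screen
#' @param seed seed applied before any stochastic stage
#' @return invisible manifest list (also written as `manifest.json`)
#' @export
run_pipeline <- function(table, pairings, outdir,
                         taxonomy = NULL,
                         contaminants = NULL,
                         trans_params = translocation_params(),
                         sparcc_parameters = sparcc_params(),
                         network_min_abundance = 0.001,
                         edge_threshold = 0.4,
                         screen_alpha = 0.05,
                         seed = 1L) {
  stage <- "load"
  manifest <- list(package = "oralflux",
                   version = as.character(utils::packageVersion("oralflux")),
                   seed = seed,
                   parameters = list(
                     source_asv_threshold = trans_params$source_asv_threshold,
                     pseudocount = trans_params$pseudocount,
                     network_min_abundance = network_min_abundance,
                     edge_threshold = edge_threshold,
                     screen_alpha = screen_alpha),
                   stages = character(0))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  persist <- function() jsonlite::write_json(manifest,
                                             file.path(outdir, "manifest.json"),
                                             auto_unbox = TRUE, digits = NA,
                                             pretty = TRUE)
  on.exit(persist())
  run_stage <- function(name, expr) {
    stage <<- name
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline aborted at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE))
    manifest$stages <<- c(manifest$stages, name)
    res
  }

  set.seed(seed)
  tab <- run_stage("load", {
    if (is.character(table)) table <- read_count_table(table)
    if (is.character(pairings)) pairings <- read_pairing(pairings, table = table)
    table
  })
  if (!is.null(contaminants)) {
    fc <- run_stage("contaminants", filter_contaminants(tab, contaminants, taxonomy))
    tab <- fc$table
    manifest$removed_contaminants <- fc$removed
  }
  profiles <- run_stage("translocation", translocation_scores(tab, pairings, trans_params))
  comparisons <- run_stage("intra_inter", {
    lapply(stats::setNames(nm = c("bray_curtis_similarity", "abundance_score",
                                  "richness_fraction")),
           function(mt) intra_inter_comparison(tab, pairings, metric = mt,
                                               params = trans_params))
  })
  screen <- run_stage("screen",
                      covariate_screen(profiles, pairings, alpha = screen_alpha))
  network <- run_stage("network", {
    net_tab <- if (!is.null(taxonomy)) collapse_to_taxon(tab, taxonomy) else tab
    sel <- select_network_taxa(net_tab, pairings$rectal_sample_id,
                               network_min_abundance)
    corr <- sparcc(sel, sparcc_parameters)
    build_network(corr, edge_threshold)
  })

  stage <- "write"
  intra_long <- do.call(rbind, lapply(names(comparisons), function(mt) {
    pp <- comparisons[[mt]]$per_participant
    data.frame(metric = mt, pp, p_value = comparisons[[mt]]$p_value,
               stringsAsFactors = FALSE)
  }))
  outputs <- list(profiles = as.data.frame(profiles),
                  intra_inter = intra_long,
                  screen = screen$screen,
                  network_edges = network$edges,
                  network_components = lapply(network$components, identity))
  paths <- write_results(outdir, outputs)
  write_count_table(tab, file.path(outdir, "filtered_counts.tsv"))
  paths <- c(paths, file.path(outdir, "filtered_counts.tsv"))
  manifest$stages <- c(manifest$stages, "write")
  manifest$outputs <- as.list(tools::md5sum(paths))
  persist()
  invisible(list(manifest = manifest, profiles = profiles,
                 comparisons = comparisons, screen = screen,
                 network = network))
}
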