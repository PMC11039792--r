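#' Parameters for translocation scoring
#'
#' @param source_asv_threshold minimum relative abundance in the participant's
#'   own tongue sample for an ASV to count as a tongue (source) ASV; boundary
#'   inclusive (default 0.001, i.e. 0.1%)
#' @param pseudocount added to counts before the log10 transform used by the
#'   Bray-Curtis distance (default 1, so zero counts map to zero)
#' @param min_detection_count minimum rectal read count on a source ASV for
#'   the participant to count as detected (default 1)
#' @return a `translocation_params` list
#' @export
translocation_params <- function(source_asv_threshold = 0.001,
                                 pseudocount = 1,
                                 min_detection_count = 1L) {
  stopifnot(source_asv_threshold >= 0, source_asv_threshold < 1, pseudocount > 0)
  structure(list(source_asv_threshold = source_asv_threshold,
                 pseudocount = pseudocount,
                 min_detection_count = as.integer(min_detection_count)),
            class = "translocation_params")
}

#' Tongue (source) ASVs of one participant
#'
#' ASVs at or above the relative-abundance threshold in the participant's own
#' tongue sample. Defined per participant, never on cohort means.
#'
#' @param table contaminant-filtered [count_table()]
#' @param tongue_sample_id the participant's tongue sample
#' @param params a [translocation_params()]
#' @return character vector of ASV ids
#' @export
identify_source_asvs <- function(table, tongue_sample_id,
                                 params = translocation_params()) {
  if (!tongue_sample_id %in% rownames(table))
    stop("sample not in table: ", tongue_sample_id)
  ra <- relative_abundance(subset_count_table(table, samples = tongue_sample_id))
  colnames(table)[ra[1, ] >= params$source_asv_threshold]
}

#' Translocation scores for one tongue-rectum pair
#'
#' The abundance score is the summed relative abundance, in the rectal
#' sample, of the tongue ASVs; the richness fraction is the share of rectal
#' ASVs (count > 0) that are tongue ASVs. `source_sample`/`target_sample`
#' default to the participant's own pair but may be crossed for inter-pair
#' comparisons.
#'
#' @param table contaminant-filtered [count_table()]
#' @param source_sample tongue sample defining the source ASV set
#' @param target_sample rectal sample being scored
#' @param params a [translocation_params()]
#' @return list: `source_asvs`, `abundance_score`, `richness_fraction`,
#'   `detected`
#' @export
pair_scores <- function(table, source_sample, target_sample,
                        params = translocation_params()) {
  for (s in c(source_sample, target_sample))
    if (!s %in% rownames(table)) stop("sample not in table: ", s)
  src <- identify_source_asvs(table, source_sample, params)
  tgt_counts <- unclass(table)[target_sample, ]
  tgt_total <- sum(tgt_counts)
  if (tgt_total == 0) stop("zero-total sample: ", target_sample)
  present <- names(tgt_counts)[tgt_counts > 0]
  shared <- intersect(src, present)
  list(source_asvs = src,
       abundance_score = sum(tgt_counts[shared]) / tgt_total,
       richness_fraction = if (length(present)) length(shared) / length(present) else 0,
       detected = any(tgt_counts[src] >= params$min_detection_count))
}

#' Per-participant translocation profiles
#'
#' One row per participant: number of tongue ASVs, translocation abundance
#' score and richness fraction in the paired rectal sample, the detection
#' flag, and the intra-pair log-scale Bray-Curtis distance.
#'
#' @param table contaminant-filtered [count_table()]
#' @param pairings a `cohort_pairing` data.frame (see [read_pairing()])
#' @param params a [translocation_params()]
#' @return data.frame of class `translocation_profile`
#' @export
translocation_scores <- function(table, pairings,
                                 params = translocation_params()) {
  stopifnot(is.data.frame(pairings))
  rows <- lapply(seq_len(nrow(pairings)), function(i) {
    p <- pairings[i, ]
    sc <- pair_scores(table, p$tongue_sample_id, p$rectal_sample_id, params)
    data.frame(participant_id = p$participant_id,
               n_source_asvs = length(sc$source_asvs),
               abundance_score = sc$abundance_score,
               richness_fraction = sc$richness_fraction,
               detected = sc$detected,
               intra_distance = bray_curtis_log(table, p$tongue_sample_id,
                                                p$rectal_sample_id, params),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("translocation_profile", "data.frame")
  out
}

#' Bray-Curtis distance on log10-transformed counts
#'
#' Computes sum|u-v| / sum(u+v) on u = log10(count + pseudocount), so with the
#' default pseudocount of 1 absent ASVs contribute zero and fully disjoint
#' samples are at distance 1.
#'
#' @param table a [count_table()]
#' @param sample_i,sample_j sample ids
#' @param params a [translocation_params()] (supplies the pseudocount)
#' @return distance in `[0, 1]`
#' @export
bray_curtis_log <- function(table, sample_i, sample_j,
                            params = translocation_params()) {
  d <- bray_curtis_matrix(subset_count_table(table,
                                             samples = unique(c(sample_i, sample_j))),
                          params)
  d[sample_i, sample_j]
}

#' @rdname bray_curtis_log
#' @return `bray_curtis_matrix`: symmetric distance matrix over all samples
#' @export
bray_curtis_matrix <- function(table, params = translocation_params()) {
  lg <- log10(unclass(table) + params$pseudocount) - log10(params$pseudocount)
  as.matrix(vegan::vegdist(lg, method = "bray"))
}

#' Intra-pair versus inter-pair sharing comparison
#'
#' For each participant i the intra value is metric(tongue_i, rectum_i); the
#' inter values are metric(tongue_j, rectum_i) over all other participants j,
#' summarised per participant (mean by default). Intra and summarised inter
#' values are then compared by the exact Wilcoxon signed-rank test.
#'
#' @param table contaminant-filtered [count_table()]
#' @param pairings a `cohort_pairing` data.frame (>= 3 participants)
#' @param metric `"bray_curtis_similarity"` (1 - log-scale Bray-Curtis),
#'   `"abundance_score"` or `"richness_fraction"`
#' @param params a [translocation_params()]
#' @param inter_summary `"mean"` (default) or `"median"`
#' @return list of class `intra_inter`: `per_participant` (participant_id,
#'   intra, inter), `metric_matrix` (rows = rectal/participant i, cols =
#'   tongue/participant j), `statistic`, `p_value`, `method`
#' @export
intra_inter_comparison <- function(table, pairings,
                                   metric = c("bray_curtis_similarity",
                                              "abundance_score",
                                              "richness_fraction"),
                                   params = translocation_params(),
                                   inter_summary = c("mean", "median")) {
  metric <- match.arg(metric)
  inter_summary <- match.arg(inter_summary)
  n <- nrow(pairings)
  if (n < 3) stop("need at least 3 participants")
  ids <- pairings$participant_id
  M <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  if (metric == "bray_curtis_similarity") {
    D <- bray_curtis_matrix(table, params)
    M <- 1 - D[pairings$rectal_sample_id, pairings$tongue_sample_id]
    dimnames(M) <- list(ids, ids)
  } else {
    src_sets <- lapply(pairings$tongue_sample_id, identify_source_asvs,
                       table = table, params = params)
    ra <- relative_abundance(subset_count_table(table,
                                                samples = pairings$rectal_sample_id))
    cnt <- unclass(table)[pairings$rectal_sample_id, , drop = FALSE]
    for (j in seq_len(n)) {
      src <- src_sets[[j]]
      if (metric == "abundance_score") {
        M[, j] <- rowSums(ra[, src, drop = FALSE])
      } else {
        n_present <- rowSums(cnt > 0)
        M[, j] <- rowSums(cnt[, src, drop = FALSE] > 0) / pmax(n_present, 1)
      }
    }
  }
  intra <- diag(M)
  inter <- vapply(seq_len(n), function(i)
    match.fun(inter_summary)(M[i, -i]), 0)
  test <- wilcoxon_signed_rank(intra - inter)
  list(per_participant = data.frame(participant_id = ids, intra = intra,
                                    inter = inter, stringsAsFactors = FALSE),
       metric_matrix = M,
       metric = metric,
       statistic = test$statistic,
       p_value = test$p_value,
       method = test$method) |>
    structure(class = "intra_inter")
}

#' Principal coordinate analysis (classical MDS)
#'
#' Double-centers the squared distance matrix and eigendecomposes it;
#' coordinates are returned for axes with positive eigenvalues and the full
#' eigenvalue spectrum (including negative eigenvalues) is reported.
#'
#' @param d square symmetric distance matrix with zero diagonal
#' @param k number of axes to return (default: all positive)
#' @return list: `coordinates` (samples x axes), `eigenvalues` (all, may be
#'   negative), `relative_eig` (share of the positive total)
#' @export
pcoa <- function(d, k = NULL) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be square and symmetric")
  n <- nrow(d)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE))
  eig <- fit$eig
  npos <- sum(eig > 1e-8)
  if (is.null(k)) k <- npos else k <- min(k, npos)
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(k))
  list(coordinates = coords,
       eigenvalues = eig,
       relative_eig = pmax(eig, 0) / sum(pmax(eig, 0)))
}
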