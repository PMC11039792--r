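#' Parameters for nearest-neighbor species assignment
#'
#' @param species_identity_threshold minimum percent identity for a reference
#'   to be a species candidate (default 98.5)
#' @param min_query_coverage minimum fraction of the query aligned (default
#'   0.90)
#' @param kmer_prescreen_k k-mer size for the candidate prescreen (default 8)
#' @param max_candidates_aligned number of prescreen hits carried into the
#'   alignment stage
#' @return an `assignment_params` list
#' @export
assignment_params <- function(species_identity_threshold = 98.5,
                              min_query_coverage = 0.90,
                              kmer_prescreen_k = 8L,
                              max_candidates_aligned = 25L) {
  stopifnot(species_identity_threshold > 0, species_identity_threshold <= 100,
            min_query_coverage > 0, min_query_coverage <= 1)
  structure(list(species_identity_threshold = species_identity_threshold,
                 min_query_coverage = min_query_coverage,
                 kmer_prescreen_k = as.integer(kmer_prescreen_k),
                 max_candidates_aligned = as.integer(max_candidates_aligned)),
            class = "assignment_params")
}

kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1), k:n))
}

#' Assign species to ASV sequences by nearest-neighbor identity
#'
#' Each query is compared against an oral 16S reference (eHOMD layout, see
#' [read_fasta()]): a shared k-mer prescreen ranks references, the top hits
#' are aligned end-gap-free (semi-global), and every reference tied at the
#' maximum percent identity is reported as a candidate provided that identity
#' reaches the species threshold and the aligned fraction of the query reaches
#' the coverage floor. Percent identity is matches over alignment length.
#'
#' @param asv_sequences named character vector of uppercase DNA queries
#' @param reference named character vector from [read_fasta()] (the `"taxa"`
#'   attribute supplies taxon names and HMT numbers)
#' @param params an [assignment_params()]
#' @return a `taxonomy_map` data.frame with one row per ASV: `asv_id`,
#'   `assigned`, `identity` (best identity, NA if no alignment passed
#'   coverage), `taxon` (tied candidates merged under a sorted `/`-joined
#'   label), `hmt`, and list-column `candidates` (data.frame taxon, hmt,
#'   identity per candidate)
#' @export
assign_species <- function(asv_sequences, reference, params = assignment_params()) {
  if (length(asv_sequences) == 0) stop("no query sequences")
  if (any(!nzchar(asv_sequences))) stop("empty query sequence")
  if (length(reference) == 0) stop("empty reference")
  taxa <- attr(reference, "taxa")
  if (is.null(taxa))
    taxa <- data.frame(id = names(reference),
                       taxon = names(reference), hmt = NA_character_,
                       stringsAsFactors = FALSE)
  k <- params$kmer_prescreen_k
  ref_kmers <- lapply(as.character(reference), kmer_set, k = k)
  ref_seq <- Biostrings::DNAStringSet(as.character(reference))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)

  rows <- lapply(seq_along(asv_sequences), function(qi) {
    q <- asv_sequences[[qi]]
    qk <- kmer_set(q, k)
    shared <- vapply(ref_kmers, function(s) sum(qk %in% s), 0L)
    ord <- order(shared, decreasing = TRUE)
    top <- ord[shared[ord] > 0][seq_len(min(params$max_candidates_aligned,
                                            sum(shared > 0)))]
    best <- data.frame(taxon = character(0), hmt = character(0),
                       identity = numeric(0), stringsAsFactors = FALSE)
    best_id <- NA_real_
    if (length(top)) {
      aln <- Biostrings::pairwiseAlignment(
        pattern = rep(Biostrings::DNAStringSet(q), length(top)),
        subject = ref_seq[top],
        type = "overlap", substitutionMatrix = mat,
        gapOpening = 5, gapExtension = 2)
      alen <- Biostrings::nchar(aln)           # alignment length incl. internal gaps
      ident <- 100 * Biostrings::nmatch(aln) / alen
      qcov <- (Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)) / nchar(q)
      ok <- qcov >= params$min_query_coverage
      if (any(ok)) {
        best_id <- max(ident[ok])
        sel <- ok & abs(ident - best_id) < 1e-9
        if (best_id >= params$species_identity_threshold) {
          best <- data.frame(taxon = taxa$taxon[top[sel]],
                             hmt = taxa$hmt[top[sel]],
                             identity = ident[sel], stringsAsFactors = FALSE)
          best <- unique(best[order(best$taxon), , drop = FALSE])
        }
      }
    }
    data.frame(asv_id = names(asv_sequences)[qi],
               assigned = nrow(best) > 0,
               identity = if (nrow(best)) best_id else best_id,
               taxon = if (nrow(best)) paste(unique(best$taxon), collapse = "/")
                       else NA_character_,
               hmt = if (nrow(best)) paste(unique(stats::na.omit(best$hmt)),
                                           collapse = "/") else NA_character_,
               candidates = I(list(best)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$hmt[out$hmt == ""] <- NA_character_
  class(out) <- c("taxonomy_map", "data.frame")
  out
}

#' Attach externally computed genus labels to a taxonomy map
#'
#' Genus-level classification (e.g. an RDP run) is not recomputed here; this
#' merges a two-column TSV or data.frame (`asv_id`, `genus`) into the map.
#'
#' @param taxonomy a `taxonomy_map`
#' @param genus_table data.frame or TSV path with columns asv_id, genus
#' @return the taxonomy map with a `genus` column
#' @export
import_genus <- function(taxonomy, genus_table) {
  if (is.character(genus_table))
    genus_table <- utils::read.delim(genus_table, stringsAsFactors = FALSE)
  stopifnot(all(c("asv_id", "genus") %in% names(genus_table)))
  taxonomy$genus <- genus_table$genus[match(taxonomy$asv_id, genus_table$asv_id)]
  taxonomy
}

#' Contaminant exclusion rule based on negative controls
#'
#' @param negative_control_sample_ids sample ids of the negative controls
#' @param min_nc_relative_abundance minimum relative abundance in some
#'   negative control for an ASV to be considered control-dominant (default
#'   0.005)
#' @param blocklist taxon names removed outright regardless of abundance
#' @return a `contaminant_rule` list
#' @export
contaminant_rule <- function(negative_control_sample_ids = character(0),
                             min_nc_relative_abundance = 0.005,
                             blocklist = character(0)) {
  stopifnot(min_nc_relative_abundance >= 0, min_nc_relative_abundance <= 1)
  structure(list(negative_control_sample_ids = as.character(negative_control_sample_ids),
                 min_nc_relative_abundance = min_nc_relative_abundance,
                 blocklist = as.character(blocklist)),
            class = "contaminant_rule")
}

#' Remove PCR-contaminant ASVs identified from negative controls
#'
#' An ASV is removed when (a) its assigned taxon is blocklisted, or (b) its
#' relative abundance in any negative control reaches
#' `min_nc_relative_abundance` AND exceeds its mean relative abundance across
#' the biological samples — i.e. it is predominantly a control feature.
#' Negative-control samples are dropped from the returned table.
#'
#' @param table a [count_table()] containing the negative controls
#' @param rule a [contaminant_rule()]
#' @param taxonomy optional `taxonomy_map` (required when the blocklist is
#'   non-empty)
#' @return list with `table` (filtered, controls dropped) and `removed`
#'   (character vector of excluded ASV ids)
#' @export
filter_contaminants <- function(table, rule, taxonomy = NULL) {
  stopifnot(inherits(rule, "contaminant_rule"))
  nc <- rule$negative_control_sample_ids
  absent <- setdiff(nc, rownames(table))
  if (length(absent))
    stop("negative-control sample(s) absent from table: ",
         paste(absent, collapse = ", "))
  if (length(nc) == 0 && length(rule$blocklist) == 0)
    stop("rule has neither negative controls nor a blocklist")
  removed <- character(0)
  if (length(rule$blocklist)) {
    if (is.null(taxonomy)) stop("blocklist requires a taxonomy map")
    hit_one <- function(lbl) any(strsplit(lbl, "/")[[1]] %in% rule$blocklist)
    hit <- !is.na(taxonomy$taxon) & vapply(taxonomy$taxon, hit_one, TRUE)
    removed <- c(removed, taxonomy$asv_id[hit])
  }
  bio <- setdiff(rownames(table), nc)
  if (length(nc)) {
    ra <- relative_abundance(subset_count_table(table, samples = rownames(table)))
    nc_max <- apply(ra[nc, , drop = FALSE], 2, max)
    bio_mean <- colMeans(ra[bio, , drop = FALSE])
    control_dominant <- nc_max >= rule$min_nc_relative_abundance & nc_max > bio_mean
    removed <- union(removed, colnames(table)[control_dominant])
  }
  keep <- setdiff(colnames(table), removed)
  list(table = subset_count_table(table, samples = bio, asvs = keep),
       removed = intersect(colnames(table), removed))
}

#' Collapse an ASV table to taxon level
#'
#' Counts are summed per assigned taxon; ASVs without an assignment at the
#' requested level are pooled under `"unassigned"`. Per-sample totals are
#' conserved exactly.
#'
#' @param table a [count_table()]
#' @param taxonomy a `taxonomy_map` covering the table's ASVs
#' @param level `"species"` (the map's `taxon` column) or `"genus"` (requires
#'   [import_genus()])
#' @return a [count_table()] over taxa
#' @export
collapse_to_taxon <- function(table, taxonomy, level = c("species", "genus")) {
  level <- match.arg(level)
  col <- if (level == "species") "taxon" else "genus"
  if (is.null(taxonomy[[col]]))
    stop("taxonomy map has no '", col, "' labels")
  lab <- taxonomy[[col]][match(colnames(table), taxonomy$asv_id)]
  lab[is.na(lab)] <- "unassigned"
  m <- unclass(table)
  agg <- t(rowsum(t(m), group = lab))
  count_table(agg[, order(colnames(agg)), drop = FALSE])
}

#' Predominant taxa by mean relative abundance
#'
#' @param table a [count_table()] (ASV- or taxon-level)
#' @param min_mean_relative_abundance inclusive threshold on the unweighted
#'   mean relative abundance across the chosen samples
#' @param samples sample ids over which to average (default: all)
#' @return character vector of taxa sorted by decreasing mean abundance
#' @export
predominant_taxa <- function(table, min_mean_relative_abundance,
                             samples = rownames(table)) {
  ra <- relative_abundance(subset_count_table(table, samples = samples))
  mu <- colMeans(ra)
  sel <- mu >= min_mean_relative_abundance
  names(sort(mu[sel], decreasing = TRUE))
}
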