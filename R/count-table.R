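#' ASV count table
#'
#' The universal currency of the pipeline: a samples x ASVs matrix of
#' non-negative integer read counts, optionally carrying the DNA sequence of
#' each ASV. Samples are always rows internally; readers normalise
#' orientation at the boundary.
#'
#' @param counts integer matrix, samples as rows, with unique row and column
#'   names. Non-integer or negative entries are rejected.
#' @param sequences optional named character vector mapping every ASV id to an
#'   uppercase DNA sequence over {A,C,G,T}.
#' @return an object of class `count_table`: the validated matrix with the
#'   sequence registry attached as attribute `"sequences"` and any all-zero
#'   samples recorded in attribute `"empty_samples"`.
#' @export
count_table <- function(counts, sequences = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count_table requires sample (row) and ASV (column) names")
  validate_count_table(structure(counts, class = c("count_table", "matrix")))
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate ASV ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  storage.mode(counts) <- "double"   # counts can exceed .Machine$integer.max in aggregate
  if (!is.null(sequences)) {
    sequences <- toupper(sequences)
    missing <- setdiff(colnames(counts), names(sequences))
    if (length(missing))
      stop("sequences missing for ASVs: ", paste(utils::head(missing, 5), collapse = ", "))
    sequences <- sequences[colnames(counts)]
    bad <- grepl("[^ACGT]", sequences)
    if (any(bad))
      stop("non-ACGT characters in sequences for: ",
           paste(utils::head(names(sequences)[bad], 5), collapse = ", "))
  }
  structure(counts,
            sequences = sequences,
            empty_samples = rownames(counts)[rowSums(counts) == 0],
            class = c("count_table", "matrix"))
}

validate_count_table <- function(x) {
  if (any(x < 0)) {
    idx <- which(x < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at sample '%s', ASV '%s'",
                 rownames(x)[idx[1]], colnames(x)[idx[2]]))
  }
  if (any(x != floor(x))) {
    idx <- which(x != floor(x), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at sample '%s', ASV '%s'",
                 rownames(x)[idx[1]], colnames(x)[idx[2]]))
  }
  invisible(x)
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d ASVs, %s reads\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  if (!is.null(attr(x, "sequences"))) cat("  sequences: attached\n")
  es <- attr(x, "empty_samples")
  if (length(es)) cat("  empty samples:", paste(es, collapse = ", "), "\n")
  invisible(x)
}

#' Subset a count table by samples and/or ASVs
#'
#' Keeps the sequence registry consistent with the retained ASVs.
#'
#' @param x a `count_table`
#' @param samples,asvs character vectors of ids to keep (default: all)
#' @return a `count_table`
#' @export
subset_count_table <- function(x, samples = rownames(x), asvs = colnames(x)) {
  missing_s <- setdiff(samples, rownames(x))
  if (length(missing_s)) stop("unknown sample ids: ", paste(missing_s, collapse = ", "))
  missing_a <- setdiff(asvs, colnames(x))
  if (length(missing_a)) stop("unknown ASV ids: ", paste(missing_a, collapse = ", "))
  seqs <- attr(x, "sequences")
  count_table(unclass(x)[samples, asvs, drop = FALSE],
              sequences = if (!is.null(seqs)) seqs[asvs])
}

#' Per-sample relative abundances
#'
#' Divides each sample's counts by its total so rows sum to one; the
#' denominator for every downstream abundance statistic.
#'
#' @param table a `count_table` (or plain samples x ASVs matrix)
#' @return numeric matrix of the same shape with rows summing to 1
#' @export
relative_abundance <- function(table) {
  m <- unclass(table)
  totals <- rowSums(m)
  zero <- totals == 0
  if (any(zero))
    stop("zero-total sample(s): ", paste(rownames(m)[zero], collapse = ", "))
  sweep(m, 1, totals, "/")
}
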