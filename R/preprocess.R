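#' Tag-and-primer scheme for a multiplexed amplicon run
#'
#' Each sample is identified by an 8-base tag at both ends of the read; the
#' amplicon is framed by the forward and reverse PCR primers (IUPAC codes
#' allowed). The assumed read layout is
#' `5'-[tag5][forward primer][insert][revcomp(reverse primer)][revcomp(tag3)]-3'`.
#'
#' @param tags data.frame with columns `sample_id`, `tag5`, `tag3` (8-base DNA,
#'   tag pairs unique across samples). `tag3` may equal `tag5`.
#' @param forward_primer,reverse_primer IUPAC DNA strings, written 5'->3' as on
#'   the primer tube label.
#' @param min_raw_length minimum raw read length in bases (reads shorter than
#'   this are discarded before any trimming)
#' @return a `tag_scheme` list
#' @export
tag_scheme <- function(tags, forward_primer, reverse_primer, min_raw_length = 100) {
  stopifnot(is.data.frame(tags),
            all(c("sample_id", "tag5", "tag3") %in% names(tags)))
  tags$sample_id <- as.character(tags$sample_id)
  tags$tag5 <- toupper(as.character(tags$tag5))
  tags$tag3 <- toupper(as.character(tags$tag3))
  if (any(nchar(tags$tag5) != 8L) || any(nchar(tags$tag3) != 8L))
    stop("all tags must be exactly 8 bases")
  if (any(grepl("[^ACGT]", c(tags$tag5, tags$tag3))))
    stop("tags must be plain ACGT")
  if (anyDuplicated(paste(tags$tag5, tags$tag3)))
    stop("tag pairs must be unique across samples")
  if (anyDuplicated(tags$sample_id)) stop("duplicate sample_id in tag table")
  forward_primer <- toupper(forward_primer)
  reverse_primer <- toupper(reverse_primer)
  if (!nzchar(forward_primer) || !nzchar(reverse_primer))
    stop("primers must be non-empty")
  structure(list(tags = tags,
                 forward_primer = forward_primer,
                 reverse_primer = reverse_primer,
                 min_raw_length = as.integer(min_raw_length)),
            class = "tag_scheme")
}

#' Read / write single-end FASTQ
#'
#' Thin wrappers over Biostrings keeping (id, sequence, quality) triplets as
#' parallel character vectors for fast string slicing.
#'
#' @param path FASTQ path
#' @return list of class `amplicon_reads` with fields `id`, `seq`, `qual`
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping its own metadata columns here; harmless
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  amplicon_reads(id = names(x), seq = unname(as.character(x)),
                 qual = unname(as.character(Biostrings::quality(x))))
}

#' @rdname read_fastq
#' @param reads an `amplicon_reads` object
#' @export
write_fastq <- function(reads, path) {
  if (length(reads$seq) == 0) { file.create(path); return(invisible(path)) }
  set <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(stats::setNames(reads$seq, reads$id)),
    Biostrings::PhredQuality(reads$qual))
  Biostrings::writeQualityScaledXStringSet(set, path)
  invisible(path)
}

#' Construct an in-memory read set
#' @param id,seq,qual parallel character vectors (quality defaults to uniform)
#' @return list of class `amplicon_reads`
#' @export
amplicon_reads <- function(id, seq, qual = NULL) {
  seq <- toupper(seq)
  if (is.null(qual))
    qual <- vapply(nchar(seq), function(n) strrep("I", n), "")
  if (length(id) != length(seq) || length(qual) != length(seq))
    stop("id, seq, qual must have equal length")
  if (any(nchar(qual) != nchar(seq)))
    stop(sprintf("malformed record %d: quality length differs from sequence length",
                 which(nchar(qual) != nchar(seq))[1]))
  structure(list(id = as.character(id), seq = seq, qual = qual),
            class = "amplicon_reads")
}

subset_reads <- function(reads, keep) {
  amplicon_reads(reads$id[keep], reads$seq[keep], reads$qual[keep])
}

revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

# Count per-read mismatches of an IUPAC pattern against fixed-position windows.
# Vectorized over reads; loops only over the pattern length.
iupac_mismatches <- function(windows, pattern) {
  iupac <- Biostrings::IUPAC_CODE_MAP
  n <- nchar(pattern)
  mm <- integer(length(windows))
  pat <- strsplit(pattern, "")[[1]]
  for (i in seq_len(n)) {
    allowed <- strsplit(iupac[[pat[i]]], "")[[1]]
    mm <- mm + !(substring(windows, i, i) %in% allowed)
  }
  mm <- mm + pmax(0L, n - nchar(windows))  # truncated windows count as mismatches
  mm
}

#' Filter raw reads on length and primer presence
#'
#' A read is kept when its raw length reaches `min_raw_length` and it carries
#' the forward primer immediately after the 5' tag position and the
#' reverse-complemented reverse primer immediately before the 3' tag position.
#' Primer comparison honours IUPAC degeneracy; `max_primer_mismatch` extra
#' mismatches are tolerated (default none).
#'
#' @param reads an `amplicon_reads` object (or FASTQ path)
#' @param scheme a [tag_scheme()]
#' @param max_primer_mismatch non-IUPAC mismatches allowed per primer
#' @return list with `kept` (an `amplicon_reads`), `rejected` (same, for
#'   inspection) and `log`, a named integer vector counting reads kept and
#'   rejected per failure class (`length`, then `primer`)
#' @export
filter_reads <- function(reads, scheme, max_primer_mismatch = 0L) {
  if (is.character(reads) && length(reads) == 1) reads <- read_fastq(reads)
  stopifnot(inherits(scheme, "tag_scheme"))
  len <- nchar(reads$seq)
  tag_n <- 8L
  fp <- scheme$forward_primer
  rp_rc <- revcomp(scheme$reverse_primer)
  nf <- nchar(fp); nr <- nchar(rp_rc)

  too_short <- len < scheme$min_raw_length
  fwd_win <- substring(reads$seq, tag_n + 1L, tag_n + nf)
  rev_win <- substring(reads$seq, len - tag_n - nr + 1L, len - tag_n)
  primer_ok <- iupac_mismatches(fwd_win, fp) <= max_primer_mismatch &
               iupac_mismatches(rev_win, rp_rc) <= max_primer_mismatch &
               len >= 2L * tag_n + nf + nr     # room for both tags and primers
  keep <- !too_short & primer_ok
  reason <- rep("kept", length(len))
  reason[!keep] <- "primer"
  reason[too_short] <- "length"           # length filter is checked first
  list(kept = subset_reads(reads, keep),
       rejected = subset_reads(reads, !keep),
       log = c(kept = sum(keep),
               length = sum(reason == "length"),
               primer = sum(reason == "primer")),
       reason = reason)
}

#' Demultiplex filtered reads by their dual 8-base tags
#'
#' A read is assigned to a sample iff its 5' tag and its 3' tag (read off the
#' reverse-complemented 3' end) both match that sample's tag pair exactly;
#' tag conflicts (valid tags from two different samples) are unassigned.
#' Assigned reads are trimmed of tags and primers, leaving the insert.
#'
#' @param reads an `amplicon_reads` object (or FASTQ path)
#' @param scheme a [tag_scheme()]
#' @param filter apply [filter_reads()] first (default TRUE)
#' @param orientation `"forward"`, or `"reverse"` if the stream was recorded
#'   reverse-complemented (reads are flipped before matching)
#' @param max_primer_mismatch passed to [filter_reads()]
#' @return list with `samples` (named list sample_id -> trimmed
#'   `amplicon_reads`), `unassigned` count, `log` (kept/length/primer counts
#'   from filtering plus `assigned`/`unassigned`), and `assignment`, the
#'   per-kept-read sample id (NA when unassigned)
#' @export
demultiplex <- function(reads, scheme, filter = TRUE,
                        orientation = c("forward", "reverse"),
                        max_primer_mismatch = 0L) {
  if (is.character(reads) && length(reads) == 1) reads <- read_fastq(reads)
  orientation <- match.arg(orientation)
  if (orientation == "reverse") {
    reads <- amplicon_reads(reads$id, revcomp(reads$seq),
                            vapply(strsplit(reads$qual, ""), function(q)
                              paste(rev(q), collapse = ""), ""))
  }
  if (filter) {
    fl <- filter_reads(reads, scheme, max_primer_mismatch)
    flog <- fl$log
    reads <- fl$kept
  } else flog <- c(kept = length(reads$seq), length = 0L, primer = 0L)

  tag_n <- 8L
  len <- nchar(reads$seq)
  tag5 <- substring(reads$seq, 1L, tag_n)
  tag3 <- revcomp(substring(reads$seq, len - tag_n + 1L, len))
  tags <- scheme$tags
  s5 <- tags$sample_id[match(tag5, tags$tag5)]
  s3 <- tags$sample_id[match(tag3, tags$tag3)]
  assigned <- !is.na(s5) & !is.na(s3) & s5 == s3
  assignment <- ifelse(assigned, s5, NA_character_)

  nf <- nchar(scheme$forward_primer)
  nr <- nchar(scheme$reverse_primer)
  from <- rep(tag_n + nf + 1L, length(len))
  to <- len - tag_n - nr
  samples <- stats::setNames(vector("list", nrow(tags)), tags$sample_id)
  for (sid in tags$sample_id) {
    idx <- which(assigned & assignment == sid)
    samples[[sid]] <- amplicon_reads(
      reads$id[idx],
      substring(reads$seq[idx], from[idx], to[idx]),
      substring(reads$qual[idx], from[idx], to[idx]))
  }
  list(samples = samples,
       unassigned = sum(!assigned),
       log = c(flog, assigned = sum(assigned), unassigned = sum(!assigned)),
       assignment = assignment)
}

#' Tabulate ASVs from trimmed per-sample reads
#'
#' Collapses identical insert sequences into ASV ids (`ASV0001`, ... ordered
#' by decreasing total count) and counts them per sample. This is a
#' bookkeeping step for error-free simulated reads; real data should go
#' through a dedicated denoiser, whose ASV table enters via
#' [read_count_table()].
#'
#' @param samples named list sample_id -> `amplicon_reads` (from
#'   [demultiplex()])
#' @return a [count_table()] with the sequence registry attached
#' @export
tabulate_asvs <- function(samples) {
  long <- do.call(rbind, lapply(names(samples), function(sid) {
    if (length(samples[[sid]]$seq) == 0) return(NULL)
    data.frame(sample = sid, seq = samples[[sid]]$seq, stringsAsFactors = FALSE)
  }))
  if (is.null(long)) stop("no reads in any sample")
  tab <- table(long$sample, long$seq)
  seqs <- colnames(tab)
  ord <- order(colSums(tab), decreasing = TRUE)
  tab <- tab[, ord, drop = FALSE]
  seqs <- seqs[ord]
  ids <- sprintf("ASV%04d", seq_along(seqs))
  m <- matrix(as.numeric(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), ids))
  count_table(m, sequences = stats::setNames(seqs, ids))
}
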