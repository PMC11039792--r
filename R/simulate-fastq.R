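#' Generate a multiplexed single-end FASTQ from a sequence-bearing count table
#'
#' Assembles one read per counted molecule in the layout the preprocessing
#' stage expects: `tag5 + forward primer + ASV sequence + revcomp(reverse
#' primer) + revcomp(tag3)`, with IUPAC codes in the primers resolved to a
#' random matching base per read. Optional uniform substitution errors and a
#' fraction of reads with corrupted 5' tags exercise the rejection paths.
#'
#' @param table a [count_table()] carrying sequences (e.g. from
#'   [generate_cohort()] with `sequences = TRUE`); every sample id must
#'   appear in the scheme's tag table
#' @param scheme a [tag_scheme()]
#' @param error_rate per-base substitution probability in the insert
#'   (default 0)
#' @param tag_error_fraction fraction of reads whose 5' tag is corrupted (one
#'   substitution), which must leave them unassigned (default 0)
#' @param reads_per_sample optional cap: subsample each sample to at most
#'   this many reads (keeps fixtures small)
#' @param seed RNG seed
#' @return list: `reads` (an `amplicon_reads`), `truth` (data.frame read_id,
#'   sample_id, asv_id, tag_corrupted)
#' @export
generate_multiplexed_fastq <- function(table, scheme, error_rate = 0,
                                       tag_error_fraction = 0,
                                       reads_per_sample = NULL,
                                       seed = 1L) {
  stopifnot(inherits(scheme, "tag_scheme"))
  seqs <- attr(table, "sequences")
  if (is.null(seqs)) stop("count table must carry ASV sequences")
  missing <- setdiff(rownames(table), scheme$tags$sample_id)
  if (length(missing))
    stop("samples without tags: ", paste(missing, collapse = ", "))
  set.seed(seed)
  m <- unclass(table)

  resolve_iupac <- function(primer) {
    map <- Biostrings::IUPAC_CODE_MAP
    ch <- strsplit(primer, "")[[1]]
    paste(vapply(ch, function(b) {
      opts <- strsplit(map[[b]], "")[[1]]
      if (length(opts) == 1) opts else sample(opts, 1)
    }, ""), collapse = "")
  }

  out_sample <- character(0); out_asv <- character(0); out_seq <- character(0)
  for (sid in rownames(m)) {
    counts <- m[sid, ]
    counts <- counts[counts > 0]
    asv_ids <- rep(names(counts), counts)
    if (!is.null(reads_per_sample) && length(asv_ids) > reads_per_sample)
      asv_ids <- sample(asv_ids, reads_per_sample)
    tg <- scheme$tags[scheme$tags$sample_id == sid, ]
    inserts <- unname(seqs[asv_ids])
    if (error_rate > 0) {
      inserts <- vapply(inserts, function(s) {
        ch <- strsplit(s, "")[[1]]
        hit <- stats::runif(length(ch)) < error_rate
        if (any(hit))
          ch[hit] <- vapply(ch[hit], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
        paste(ch, collapse = "")
      }, "")
    }
    fwd <- vapply(seq_along(inserts), function(i) resolve_iupac(scheme$forward_primer), "")
    rev_rc <- vapply(seq_along(inserts), function(i)
      revcomp(resolve_iupac(scheme$reverse_primer)), "")
    reads <- paste0(tg$tag5, fwd, inserts, rev_rc, revcomp(tg$tag3))
    out_sample <- c(out_sample, rep(sid, length(reads)))
    out_asv <- c(out_asv, asv_ids)
    out_seq <- c(out_seq, reads)
  }
  n <- length(out_seq)
  corrupted <- logical(n)
  if (tag_error_fraction > 0) {
    hit <- sample(n, round(tag_error_fraction * n))
    corrupted[hit] <- TRUE
    out_seq[hit] <- vapply(out_seq[hit], function(s) {
      p <- sample(8, 1)
      b <- substring(s, p, p)
      paste0(substring(s, 1, p - 1),
             sample(setdiff(c("A", "C", "G", "T"), b), 1),
             substring(s, p + 1, nchar(s)))
    }, "", USE.NAMES = FALSE)
  }
  ord <- sample(n)   # interleave samples as a sequencer would
  ids <- sprintf("read%06d", seq_len(n))
  list(reads = amplicon_reads(ids, out_seq[ord]),
       truth = data.frame(read_id = ids, sample_id = out_sample[ord],
                          asv_id = out_asv[ord],
                          tag_corrupted = corrupted[ord],
                          stringsAsFactors = FALSE))
}
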