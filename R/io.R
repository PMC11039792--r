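#' Read an ASV count table from TSV
#'
#' The TSV carries one header row and one identifier column; `orientation`
#' says whether rows are samples or ASVs. The internal contract is always
#' samples-as-rows, so reading a transposed file with the flipped flag yields
#' an identical object.
#'
#' @param path TSV file path
#' @param orientation `"samples_as_rows"` (default) or `"asvs_as_rows"`
#' @return a [count_table()]
#' @export
read_count_table <- function(path,
                             orientation = c("samples_as_rows", "asvs_as_rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, header = TRUE, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count table needs an id column plus at least one data column")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  colnames(m) <- names(df)[-1]   # undo make.unique applied by `[.data.frame`
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) & !is.na(m),
                 arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-numeric cell at row '%s', column '%s'",
                   ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
    storage.mode(m) <- "double"
  }
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing/unparseable cell at row '%s', column '%s'",
                 ids[idx[1]], colnames(m)[idx[2]]))
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at row '%s', column '%s'",
                 ids[idx[1]], colnames(m)[idx[2]]))
  }
  if (any(m != floor(m))) {
    idx <- which(m != floor(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at row '%s', column '%s'",
                 ids[idx[1]], colnames(m)[idx[2]]))
  }
  rownames(m) <- ids
  if (orientation == "asvs_as_rows") m <- t(m)
  count_table(m)
}

#' Write a count table to TSV
#'
#' Samples as rows, first column `sample_id`. `read_count_table()` on the
#' result reproduces the table exactly.
#'
#' @param table a `count_table`
#' @param path output TSV path
#' @export
write_count_table <- function(table, path) {
  m <- unclass(table)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Covariate schema mirroring the study's participant characteristics table
#'
#' Categorical levels for the clinical covariates the screen iterates over:
#' sex, age group, BMI class, and binary flags for lifestyle factors,
#' comorbidities and medication classes.
#'
#' @return named list of allowed levels per covariate
#' @export
covariate_schema <- function() {
  yn <- c("no", "yes")
  list(
    sex       = c("male", "female"),
    age_group = c("20-39", "40-59", "60-79", ">=80"),
    bmi_class = c("<18.5", "18.5-25", ">=25"),
    alcohol = yn, smoking = yn, hypertension = yn, diabetes = yn,
    steroid = yn, nsaid = yn, opioid = yn, ppi = yn, immunosuppressant = yn
  )
}

#' Bin an age in years into the study's age strata
#' @param age numeric vector of ages (>= 20)
#' @return factor with levels `20-39`, `40-59`, `60-79`, `>=80`
#' @export
bin_age_group <- function(age) {
  age <- as.numeric(age)
  cut(age, breaks = c(20, 40, 60, 80, Inf), right = FALSE,
      labels = covariate_schema()$age_group)
}

#' Read the participant pairing / metadata table
#'
#' Requires columns `participant_id`, `tongue_sample_id`, `rectal_sample_id`.
#' Recognised covariate columns are validated against [covariate_schema()]
#' (a numeric `age` column is binned into `age_group`); unrecognised columns
#' are preserved as opaque factors with a warning so the covariate screen can
#' iterate over them generically.
#'
#' @param path TSV file path
#' @param table optional `count_table` to validate sample ids against
#' @return data.frame of class `cohort_pairing`, one row per participant
#' @export
read_pairing <- function(path, table = NULL) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  as_cohort_pairing(df, table = table)
}

#' Validate a pairing data.frame
#' @param df data.frame with participant_id, tongue_sample_id, rectal_sample_id
#'   and optional covariate columns
#' @param table optional `count_table` whose samples must contain every paired id
#' @return data.frame of class `cohort_pairing`
#' @export
as_cohort_pairing <- function(df, table = NULL) {
  req <- c("participant_id", "tongue_sample_id", "rectal_sample_id")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("pairing table missing column(s): ", paste(miss, collapse = ", "))
  for (cl in req) df[[cl]] <- as.character(df[[cl]])
  if (anyDuplicated(df$participant_id))
    stop("duplicate participant_id")
  if (any(df$tongue_sample_id == df$rectal_sample_id))
    stop("tongue and rectal sample ids must differ within a participant")
  all_ids <- c(df$tongue_sample_id, df$rectal_sample_id)
  if (anyDuplicated(all_ids))
    stop("sample id used in more than one pairing: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  if (!is.null(table)) {
    absent <- setdiff(all_ids, rownames(table))
    if (length(absent))
      stop("paired sample ids absent from count table: ",
           paste(utils::head(absent, 5), collapse = ", "))
  }
  schema <- covariate_schema()
  if ("age" %in% names(df) && !("age_group" %in% names(df))) {
    df$age_group <- bin_age_group(df$age)
    df$age <- NULL
  }
  extra <- setdiff(names(df), c(req, names(schema)))
  for (cl in names(df)) {
    if (cl %in% req) next
    if (cl %in% names(schema)) {
      vals <- normalize_covariate(df[[cl]], schema[[cl]])
      bad <- !is.na(vals) & !(as.character(vals) %in% schema[[cl]])
      if (any(bad))
        stop(sprintf("covariate '%s' has value(s) outside schema: %s", cl,
                     paste(unique(df[[cl]][bad]), collapse = ", ")))
      df[[cl]] <- factor(as.character(vals), levels = schema[[cl]])
    } else {
      df[[cl]] <- factor(df[[cl]])
    }
  }
  if (length(extra))
    warning("unknown covariate column(s) kept as opaque factors: ",
            paste(extra, collapse = ", "))
  structure(df, class = c("cohort_pairing", "data.frame"))
}

# Accept 0/1 and TRUE/FALSE spellings for binary yes/no covariates.
normalize_covariate <- function(x, levels) {
  x <- as.character(x)
  if (identical(levels, c("no", "yes"))) {
    x[x %in% c("0", "FALSE", "false", "No", "NO")] <- "no"
    x[x %in% c("1", "TRUE", "true", "Yes", "YES")] <- "yes"
  }
  x
}

#' Read a FASTA file, parsing eHOMD-style headers
#'
#' Sequences are uppercased and validated against the IUPAC alphabet. Headers
#' of the form `Genus_species|HMT-755` (eHOMD 16S RefSeq layout) contribute a
#' taxon name (underscores to spaces) and Human Microbial Taxon number,
#' attached as the `"taxa"` attribute (data.frame: id, taxon, hmt).
#'
#' @param path FASTA file path
#' @return named character vector of sequences, in file order
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path, format = "fasta")
  seqs <- toupper(as.character(set))
  iupac <- "ACGTRYSWKMBDHVN"
  bad <- grepl(paste0("[^", iupac, "]"), seqs)
  if (any(bad)) {
    first <- which(bad)[1]
    pos <- which(!strsplit(seqs[first], "")[[1]] %in% strsplit(iupac, "")[[1]])
    stop(sprintf("non-IUPAC characters in record '%s' at position(s) %s",
                 names(seqs)[first], paste(utils::head(pos, 10), collapse = ",")))
  }
  ids <- names(seqs)
  word <- vapply(strsplit(ids, "[ |]"), `[`, "", 1)
  hmt <- ifelse(grepl("HMT-\\d+", ids),
                regmatches(ids, regexpr("HMT-\\d+", ids)), NA_character_)
  taxa <- data.frame(id = ids,
                     taxon = gsub("_", " ", word),
                     hmt = hmt,
                     stringsAsFactors = FALSE)
  structure(seqs, taxa = taxa)
}

#' Write sequences to FASTA
#' @param seqs named character vector of DNA sequences
#' @param path output path
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, format = "fasta", width = 80)
  invisible(path)
}

#' Write a set of result tables to a directory
#'
#' Each element of `objects` is written as `<name>.tsv` (data.frames/matrices)
#' or `<name>.json` (lists).
#'
#' @param dir output directory (created if needed)
#' @param objects named list of data.frames, matrices or lists
#' @return invisible character vector of the paths written
#' @export
write_results <- function(dir, objects) {
  stopifnot(is.list(objects), !is.null(names(objects)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(objects)) {
    obj <- objects[[nm]]
    if (is.matrix(obj)) obj <- data.frame(id = rownames(obj), obj, check.names = FALSE)
    if (is.data.frame(obj)) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(obj, p, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      p <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    paths <- c(paths, p)
  }
  invisible(paths)
}
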