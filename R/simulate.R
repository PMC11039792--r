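#' Configuration for the paired-cohort simulator
#'
#' Emulates the study design: paired tongue/rectal communities per
#' participant, a per-subject translocation fraction tau driven by clinical
#' covariates on the logit scale, subject-private oral ASV variants, and
#' sequencing depths matching the study's per-site read-count moments.
#' Covariate frequencies default to the participant-characteristics table of
#' the cohort being emulated (e.g. hypertension 51.0%, PPI 24.5%, diabetes
#' 14.3%).
#'
#' @param n_participants cohort size (default 49)
#' @param oral_pool_size,gut_pool_size,shared_pool_size numbers of
#'   oral-specialist, gut-specialist and site-shared taxa
#' @param subject_specificity probability rho that an oral taxon's reads in a
#'   given subject carry a subject-private ASV variant rather than the
#'   cohort-shared one (default 1)
#' @param alpha_oral,alpha_gut symmetric Dirichlet concentrations of the
#'   per-subject oral and gut compositions
#' @param shared_gut_weight multiplier on `alpha_gut` for the shared taxa
#'   inside the gut community (oral-capable taxa are minor gut members)
#' @param beta0 intercept of the translocation model on the logit scale
#'   (default `qlogis(0.005)`, placing cohort abundance scores in the
#'   sub-10% range reported for real paired cohorts)
#' @param beta named covariate effects on logit(tau); defaults plant an age
#'   gradient (per stratum step) plus hypertension and PPI effects, the
#'   factors the screen is expected to recover
#' @param sigma SD of the subject-level noise on logit(tau)
#' @param tau_fixed set every subject's tau to this value (overrides the
#'   covariate model; 0 gives a no-translocation null)
#' @param depth_tongue_mean,depth_tongue_sd,depth_rectal_mean,depth_rectal_sd
#'   truncated-normal (>= `min_depth`) read-depth moments per site
#' @param min_depth truncation floor for depths
#' @param covariate_freq named list of category frequencies used to draw the
#'   covariate table
#' @param sequences also generate ASV DNA sequences (default FALSE)
#' @param seq_length amplicon insert length when `sequences = TRUE`
#' @param seed RNG seed
#' @return a `sim_config` list
#' @export
sim_config <- function(n_participants = 49L,
                       oral_pool_size = 120L,
                       gut_pool_size = 150L,
                       shared_pool_size = 20L,
                       subject_specificity = 1,
                       alpha_oral = 0.5,
                       alpha_gut = 0.5,
                       shared_gut_weight = 0.2,
                       beta0 = stats::qlogis(0.005),
                       beta = c(age_trend = 0.5, hypertension = 0.6,
                                ppi = log(3)),
                       sigma = 0.5,
                       tau_fixed = NULL,
                       depth_tongue_mean = 30323, depth_tongue_sd = 6547,
                       depth_rectal_mean = 36248, depth_rectal_sd = 11175,
                       min_depth = 1000L,
                       covariate_freq = default_covariate_freq(),
                       sequences = FALSE,
                       seq_length = 250L,
                       seed = 1L) {
  stopifnot(oral_pool_size >= 4, gut_pool_size >= 4, shared_pool_size >= 0,
            subject_specificity >= 0, subject_specificity <= 1,
            is.null(tau_fixed) || (tau_fixed >= 0 && tau_fixed < 1),
            min_depth >= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_covariate_freq <- function() {
  list(sex = c(male = 0.510, female = 0.490),
       age_group = c("20-39" = 0.184, "40-59" = 0.224,
                     "60-79" = 0.469, ">=80" = 0.122),
       bmi_class = c("<18.5" = 0.061, "18.5-25" = 0.592, ">=25" = 0.347),
       alcohol = 0.265, smoking = 0.306, hypertension = 0.510,
       diabetes = 0.143, steroid = 0.122, nsaid = 0.327, opioid = 0.061,
       ppi = 0.245, immunosuppressant = 0.122)
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

rtrunc_norm_depth <- function(n, mean, sd, floor) {
  out <- numeric(0)
  while (length(out) < n) {
    d <- stats::rnorm(n, mean, sd)
    out <- c(out, d[d >= floor])
  }
  as.integer(round(out[seq_len(n)]))
}

draw_covariates <- function(n, freq) {
  df <- data.frame(participant_id = sprintf("P%03d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (nm in names(freq)) {
    f <- freq[[nm]]
    if (length(f) == 1) {
      df[[nm]] <- factor(ifelse(stats::runif(n) < f, "yes", "no"),
                         levels = c("no", "yes"))
    } else {
      df[[nm]] <- factor(sample(names(f), n, replace = TRUE, prob = f),
                         levels = names(f))
    }
  }
  df
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""), "")
}

mutate_dna <- function(seq, n_sub) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), n_sub)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

#' Generate a paired tongue/rectal cohort with known translocation structure
#'
#' Per subject i: an oral composition over the oral + shared taxon pool and a
#' gut composition over the gut + shared pool are drawn from Dirichlet
#' distributions; the rectal composition is the mixture
#' `(1 - tau_i) * gut + tau_i * oral`; tongue and rectal reads are
#' multinomial at truncated-normal depths. Each tongue-side taxon's reads
#' carry a subject-private ASV variant with probability
#' `subject_specificity`, otherwise the cohort-shared variant; gut-derived
#' reads of shared taxa always carry the cohort-resident variant. This is the
#' lever that makes intra-pair sharing exceed inter-pair sharing. The full
#' generating truth is returned for parameter-recovery tests.
#'
#' @param config a [sim_config()]
#' @return list of class `synthetic_cohort`: `table` (a [count_table()]),
#'   `pairings` (a `cohort_pairing`), and `truth` (list: `tau`, `logit_tau`,
#'   `beta`, `p_oral`, `p_gut`, `q_rectal`, `asv_map` (asv_id, taxon, pool,
#'   subject), `covariates`, `depths`, `config`)
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_participants
  oral_taxa <- sprintf("oral_t%03d", seq_len(config$oral_pool_size))
  shared_taxa <- sprintf("shared_t%03d", seq_len(config$shared_pool_size))
  gut_taxa <- sprintf("gut_t%03d", seq_len(config$gut_pool_size))
  if (anyDuplicated(c(oral_taxa, shared_taxa, gut_taxa)))
    stop("taxon pool label collision")

  cov <- draw_covariates(n, config$covariate_freq)
  if (is.null(config$tau_fixed)) {
    age_step <- as.integer(cov$age_group) - 1L
    lt <- config$beta0 +
      config$beta[["age_trend"]] * age_step +
      config$beta[["hypertension"]] * (cov$hypertension == "yes") +
      config$beta[["ppi"]] * (cov$ppi == "yes") +
      stats::rnorm(n, 0, config$sigma)
    tau <- stats::plogis(lt)
  } else {
    lt <- rep(stats::qlogis(max(config$tau_fixed, 1e-12)), n)
    tau <- rep(config$tau_fixed, n)
  }

  n_os <- config$oral_pool_size + config$shared_pool_size
  p_oral <- rdirichlet(n, rep(config$alpha_oral, n_os))
  colnames(p_oral) <- c(oral_taxa, shared_taxa)
  alpha_g <- c(rep(config$alpha_gut, config$gut_pool_size),
               rep(config$alpha_gut * config$shared_gut_weight,
                   config$shared_pool_size))
  p_gut <- rdirichlet(n, alpha_g)
  colnames(p_gut) <- c(gut_taxa, shared_taxa)

  all_taxa <- c(oral_taxa, shared_taxa, gut_taxa)
  q <- matrix(0, n, length(all_taxa), dimnames = list(NULL, all_taxa))
  q[, oral_taxa] <- tau * p_oral[, oral_taxa, drop = FALSE]
  q[, shared_taxa] <- tau * p_oral[, shared_taxa, drop = FALSE] +
    (1 - tau) * p_gut[, shared_taxa, drop = FALSE]
  q[, gut_taxa] <- (1 - tau) * p_gut[, gut_taxa, drop = FALSE]

  # Subject-private vs cohort-shared ASV id per (subject, tongue-side taxon).
  # Privacy applies to every taxon of the tongue community (oral specialists
  # and shared taxa alike): at strain resolution a subject's tongue variant of
  # a shared species differs from the cohort's gut-resident variant with
  # probability rho. Gut-derived reads always carry the cohort variant, so at
  # rho = 1 rectal reads land on a subject's tongue ASVs only by
  # translocation, while at rho = 0 tongue and gut copies of shared taxa
  # collapse onto one ASV.
  os_taxa <- c(oral_taxa, shared_taxa)
  private <- matrix(stats::runif(n * length(os_taxa)) <
                      config$subject_specificity,
                    n, length(os_taxa), dimnames = list(NULL, os_taxa))
  tongue_asv_of <- function(i, taxon) {
    priv <- private[i, ][match(taxon, os_taxa)]
    priv[is.na(priv)] <- FALSE
    ifelse(priv, paste0(taxon, "_p", sprintf("%03d", i)),
           paste0(taxon, "_c"))
  }

  depth_t <- rtrunc_norm_depth(n, config$depth_tongue_mean,
                               config$depth_tongue_sd, config$min_depth)
  depth_r <- rtrunc_norm_depth(n, config$depth_rectal_mean,
                               config$depth_rectal_sd, config$min_depth)

  tongue_ids <- sprintf("T%03d", seq_len(n))
  rectal_ids <- sprintf("R%03d", seq_len(n))
  sample_counts <- vector("list", 2 * n)
  names(sample_counts) <- c(tongue_ids, rectal_ids)
  gs_taxa <- c(gut_taxa, shared_taxa)
  for (i in seq_len(n)) {
    ct <- stats::rmultinom(1, depth_t[i], p_oral[i, ])[, 1]
    names(ct) <- tongue_asv_of(i, os_taxa)
    sample_counts[[tongue_ids[i]]] <- ct[ct > 0]
    # rectal reads: oral-derived components carry the subject's tongue ASV,
    # gut-derived components the cohort-resident ASV; identical ids merge
    comp_p <- c(tau[i] * p_oral[i, os_taxa],
                (1 - tau[i]) * p_gut[i, gs_taxa])
    comp_id <- c(tongue_asv_of(i, os_taxa), paste0(gs_taxa, "_c"))
    cr <- stats::rmultinom(1, depth_r[i], comp_p)[, 1]
    names(cr) <- comp_id
    cr <- tapply(cr, names(cr), sum)
    sample_counts[[rectal_ids[i]]] <- cr[cr > 0]
  }
  all_ids <- sort(unique(unlist(lapply(sample_counts, names))))
  m <- matrix(0, 2 * n, length(all_ids),
              dimnames = list(names(sample_counts), all_ids))
  for (s in names(sample_counts)) {
    v <- sample_counts[[s]]
    v <- tapply(v, names(v), sum)   # private+shared ids never collide, but be safe
    m[s, names(v)] <- v
  }

  asv_map <- data.frame(
    asv_id = all_ids,
    taxon = sub("_(c|p[0-9]+)$", "", all_ids),
    stringsAsFactors = FALSE)
  asv_map$pool <- ifelse(asv_map$taxon %in% oral_taxa, "oral",
                         ifelse(asv_map$taxon %in% shared_taxa, "shared", "gut"))
  is_priv <- grepl("_p[0-9]+$", asv_map$asv_id)
  asv_map$subject <- NA_integer_
  asv_map$subject[is_priv] <- as.integer(sub(".*_p", "", all_ids[is_priv]))

  seqs <- NULL
  if (isTRUE(config$sequences)) {
    base_seq <- stats::setNames(random_dna(length(all_taxa), config$seq_length),
                                all_taxa)
    seqs <- vapply(seq_along(all_ids), function(k) {
      b <- base_seq[[asv_map$taxon[k]]]
      if (is.na(asv_map$subject[k])) b else mutate_dna(b, 2L)
    }, "")
    names(seqs) <- all_ids
  }

  table <- count_table(m, sequences = seqs)
  pair_df <- cbind(data.frame(participant_id = cov$participant_id,
                              tongue_sample_id = tongue_ids,
                              rectal_sample_id = rectal_ids,
                              stringsAsFactors = FALSE),
                   cov[, -1, drop = FALSE])
  pairings <- as_cohort_pairing(pair_df, table = table)

  structure(list(table = table,
                 pairings = pairings,
                 truth = list(tau = stats::setNames(tau, cov$participant_id),
                              logit_tau = lt,
                              beta = c(beta0 = config$beta0, config$beta),
                              p_oral = p_oral, p_gut = p_gut, q_rectal = q,
                              asv_map = asv_map, covariates = cov,
                              depths = data.frame(participant_id = cov$participant_id,
                                                  tongue = depth_t,
                                                  rectal = depth_r),
                              config = config)),
            class = "synthetic_cohort")
}

#' Spike a negative-control sample carrying a PCR contaminant
#'
#' Adds (a) a contaminant ASV present at `contaminant_fraction` of a new
#' negative-control sample whose remaining reads follow the cohort mean
#' composition, and (b) trace contaminant counts in the biological samples,
#' emulating a reagent contaminant that dominates the control.
#'
#' @param table a [count_table()]
#' @param contaminant_id ASV id for the contaminant
#' @param nc_sample_id id of the added control sample
#' @param nc_depth control read depth
#' @param contaminant_fraction contaminant share of the control (default 0.4)
#' @param bio_trace_fraction expected contaminant share of each biological
#'   sample (Poisson counts; default 1e-4)
#' @param contaminant_seq optional contaminant sequence (required when the
#'   table carries sequences)
#' @return the augmented [count_table()]
#' @export
spike_negative_control <- function(table, contaminant_id = "contam_001",
                                   nc_sample_id = "NC01", nc_depth = 5000L,
                                   contaminant_fraction = 0.4,
                                   bio_trace_fraction = 1e-4,
                                   contaminant_seq = NULL) {
  m <- unclass(table)
  if (contaminant_id %in% colnames(m)) stop("contaminant id collides with an ASV")
  if (nc_sample_id %in% rownames(m)) stop("control sample id collides")
  mean_comp <- colMeans(relative_abundance(table))
  n_contam <- round(nc_depth * contaminant_fraction)
  nc_bg <- stats::rmultinom(1, nc_depth - n_contam, mean_comp)[, 1]
  trace <- stats::rpois(nrow(m), bio_trace_fraction * rowSums(m))
  m2 <- cbind(m, trace)
  colnames(m2)[ncol(m2)] <- contaminant_id
  m2 <- rbind(m2, c(nc_bg[colnames(m)], n_contam))
  rownames(m2)[nrow(m2)] <- nc_sample_id
  seqs <- attr(table, "sequences")
  if (!is.null(seqs)) {
    if (is.null(contaminant_seq))
      contaminant_seq <- random_dna(1, nchar(seqs[[1]]))
    seqs <- c(seqs, stats::setNames(contaminant_seq, contaminant_id))
  }
  count_table(m2, sequences = seqs)
}

#' Simulate compositional counts from a log-normal basis community
#'
#' The validation design for compositional correlation estimators: absolute
#' (basis) abundances are log-normal with unit log-variance and, optionally,
#' a planted equicorrelated block; samples are multinomial reads of the
#' closed compositions. The true basis correlation matrix is returned so an
#' estimator's error can be measured pair by pair.
#'
#' @param n_samples number of samples
#' @param n_taxa number of taxa (log-mean spread `mu_sd` apart)
#' @param block taxon indices forming an equicorrelated block (NULL = fully
#'   independent basis)
#' @param block_rho basis correlation inside the block (default 0.7)
#' @param depth reads per sample
#' @param mu_sd SD of the per-taxon log-mean offsets
#' @param seed RNG seed
#' @return list: `table` (a [count_table()]), `true_correlation`
#' @export
simulate_basis_counts <- function(n_samples, n_taxa, block = NULL,
                                  block_rho = 0.7, depth = 50000L,
                                  mu_sd = 1, seed = 1L) {
  set.seed(seed)
  R <- diag(n_taxa)
  if (!is.null(block)) R[block, block] <- block_rho
  diag(R) <- 1
  L <- chol(R)
  Z <- matrix(stats::rnorm(n_samples * n_taxa), n_samples) %*% L
  mu <- stats::rnorm(n_taxa, 0, mu_sd)
  W <- exp(sweep(Z, 2, mu, "+"))
  frac <- W / rowSums(W)
  m <- t(apply(frac, 1, function(p) stats::rmultinom(1, depth, p)[, 1]))
  dimnames(m) <- list(sprintf("S%03d", seq_len(n_samples)),
                      sprintf("taxon%03d", seq_len(n_taxa)))
  list(table = count_table(m), true_correlation = R)
}
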