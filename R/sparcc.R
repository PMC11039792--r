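#' SparCC parameters
#'
#' @param exclusion_threshold correlation magnitude above which the single
#'   most strongly correlated pair is removed from the basis-variance
#'   equations at each refinement pass (default 0.1)
#' @param exclusion_iterations maximum refinement passes (default 10)
#' @param resampling_rounds 0 (default) uses deterministic posterior-mean
#'   fractions under a unit Dirichlet prior; > 0 draws that many Dirichlet
#'   resamples of the fractions and aggregates correlations by the
#'   element-wise median
#' @param seed RNG seed used when `resampling_rounds > 0`
#' @return a `sparcc_params` list
#' @export
sparcc_params <- function(exclusion_threshold = 0.1,
                          exclusion_iterations = 10L,
                          resampling_rounds = 0L,
                          seed = NULL) {
  stopifnot(exclusion_threshold > 0, exclusion_threshold < 1,
            resampling_rounds >= 0)
  structure(list(exclusion_threshold = exclusion_threshold,
                 exclusion_iterations = as.integer(exclusion_iterations),
                 resampling_rounds = as.integer(resampling_rounds),
                 seed = seed),
            class = "sparcc_params")
}

# One SparCC basis solve from a log-ratio variance matrix T (D x D), with an
# optional set of excluded pairs (logical D x D matrix). Equations: for taxon
# i over its active partners A_i,  sum_{j in A_i} T_ij = |A_i| w_i +
# sum_{j in A_i} w_j  (pairwise covariances dropped under sparsity).
solve_basis <- function(Tmat, excluded) {
  D <- nrow(Tmat)
  active <- !excluded
  diag(active) <- FALSE
  M <- active * 1
  diag(M) <- rowSums(active)
  t_vec <- rowSums(Tmat * active)
  omega <- solve(M, t_vec)
  omega
}

sparcc_from_fractions <- function(frac, params) {
  lf <- log(frac)
  D <- ncol(lf)
  C <- stats::cov(lf)
  v <- diag(C)
  Tmat <- outer(v, rep(1, D)) + outer(rep(1, D), v) - 2 * C
  excluded <- matrix(FALSE, D, D)
  corr <- NULL
  for (it in seq_len(params$exclusion_iterations + 1L)) {
    omega <- solve_basis(Tmat, excluded)
    if (any(omega <= 0)) {
      if (it > params$exclusion_iterations)
        stop("negative basis variance persisted through the exclusion passes")
      # fall through: exclusion of the strongest pair below may repair it
      omega <- pmax(omega, min(omega[omega > 0], na.rm = TRUE))
    }
    denom <- 2 * sqrt(outer(omega, omega))
    corr <- (outer(omega, rep(1, D)) + outer(rep(1, D), omega) - Tmat) / denom
    corr <- pmin(pmax(corr, -1), 1)
    diag(corr) <- 1
    if (it > params$exclusion_iterations) break
    cand <- abs(corr)
    cand[excluded] <- -Inf
    diag(cand) <- -Inf
    mx <- max(cand)
    if (mx <= params$exclusion_threshold) break
    idx <- which(cand == mx, arr.ind = TRUE)[1, ]
    excluded[idx[1], idx[2]] <- TRUE
    excluded[idx[2], idx[1]] <- TRUE
  }
  dimnames(corr) <- dimnames(Tmat)
  corr
}

#' SparCC compositional correlation estimation
#'
#' Estimates correlations between the (unobserved) basis abundances of taxa
#' from compositional counts: component fractions are estimated per sample as
#' (count + 1) / (total + D) (posterior mean under a unit Dirichlet prior),
#' the variance of every pairwise log-ratio is computed across samples, the
#' taxon basis variances are solved from the log-ratio variance totals under
#' a sparsity assumption, and correlations follow as
#' r_ij = (w_i + w_j - T_ij) / (2 sqrt(w_i w_j)), clipped to `[-1, 1]`. The
#' most strongly correlated pair (above the exclusion threshold) is
#' iteratively removed from the basis equations and the system re-solved, so
#' a few strong correlations do not bias the remaining estimates. With
#' `resampling_rounds > 0` the fractions are Dirichlet resampled and the
#' median correlation matrix returned.
#'
#' @param table a [count_table()] over taxa (>= 4 taxa)
#' @param params a [sparcc_params()]
#' @return symmetric correlation matrix with unit diagonal over the table's
#'   taxa
#' @export
sparcc <- function(table, params = sparcc_params()) {
  m <- unclass(table)
  D <- ncol(m)
  if (D < 4) stop("SparCC needs at least 4 taxa")
  totals <- rowSums(m)
  if (any(totals == 0)) stop("zero-total sample(s) not allowed")
  if (params$resampling_rounds == 0) {
    frac <- (m + 1) / (totals + D)
    corr <- sparcc_from_fractions(frac, params)
  } else {
    if (!is.null(params$seed)) set.seed(params$seed)
    draws <- lapply(seq_len(params$resampling_rounds), function(r) {
      g <- matrix(stats::rgamma(length(m), shape = m + 1), nrow(m), D)
      frac <- g / rowSums(g)
      sparcc_from_fractions(frac, params)
    })
    corr <- apply(simplify2array(draws), c(1, 2), stats::median)
    corr <- (corr + t(corr)) / 2
    diag(corr) <- 1
  }
  dimnames(corr) <- list(colnames(m), colnames(m))
  corr
}

#' Threshold a correlation matrix into a co-occurrence network
#'
#' Edges connect taxa whose correlation reaches `edge_threshold` (inclusive;
#' positive correlations by default, `mode = "absolute"` uses |r|).
#' "Cohabiting groups" are the connected components over edge-incident
#' nodes, reported in a deterministic order (largest first, ties broken
#' lexicographically).
#'
#' @param corr symmetric correlation matrix with taxon dimnames
#' @param edge_threshold inclusive threshold on r (default 0.4)
#' @param mode `"positive"` (r >= threshold) or `"absolute"`
#'   (|r| >= threshold)
#' @return list of class `correlation_network`: `taxa`, `correlation`,
#'   `edges` (taxon_a, taxon_b, r; sorted by decreasing r), `components`
#'   (list of taxon vectors)
#' @export
build_network <- function(corr, edge_threshold = 0.4,
                          mode = c("positive", "absolute")) {
  mode <- match.arg(mode)
  corr <- as.matrix(corr)
  if (max(abs(corr - t(corr))) > 1e-8) stop("correlation matrix must be symmetric")
  taxa <- colnames(corr)
  val <- if (mode == "absolute") abs(corr) else corr
  sel <- which(upper.tri(val) & val >= edge_threshold, arr.ind = TRUE)
  edges <- data.frame(taxon_a = taxa[sel[, 1]], taxon_b = taxa[sel[, 2]],
                      r = corr[sel], stringsAsFactors = FALSE)
  edges <- edges[order(-edges$r, edges$taxon_a, edges$taxon_b), , drop = FALSE]
  rownames(edges) <- NULL
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
    comp <- igraph::components(g)
    members <- split(names(comp$membership), comp$membership)
    members <- lapply(members, function(x) sort(x))
    ord <- order(-vapply(members, length, 0L),
                 vapply(members, `[`, "", 1))
    components <- unname(members[ord])
  } else components <- list()
  structure(list(taxa = taxa, correlation = corr, edges = edges,
                 edge_threshold = edge_threshold, mode = mode,
                 components = components),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("correlation_network: %d taxa, %d edges (r >= %g), %d cohabiting group(s)\n",
              length(x$taxa), nrow(x$edges), x$edge_threshold,
              length(x$components)))
  invisible(x)
}

#' Select taxa for network analysis by site-specific predominance
#'
#' Restricts the taxon table to the given site's samples and keeps taxa with
#' mean relative abundance at or above the threshold (the rectal-network
#' selection rule).
#'
#' @param table a taxon-level [count_table()]
#' @param site_samples sample ids defining the site
#' @param min_mean_rel_abundance inclusive threshold (default 0.001)
#' @return a [count_table()] over the selected taxa and site samples
#' @export
select_network_taxa <- function(table, site_samples,
                                min_mean_rel_abundance = 0.001) {
  if (!length(site_samples)) stop("site_samples must be non-empty")
  keep <- predominant_taxa(table, min_mean_rel_abundance, samples = site_samples)
  if (length(keep) < 4)
    stop("fewer than 4 taxa pass the abundance threshold")
  subset_count_table(table, samples = site_samples, asvs = keep)
}

#' Write a network's edge list to TSV
#' @param network a `correlation_network`
#' @param path output TSV
#' @export
write_edge_list <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
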