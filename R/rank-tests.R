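# Exact nonparametric rank tests with ties handled by midranks and exact null
# distributions computed by the shift (polynomial convolution) algorithm on
# doubled midrank scores, which are always integers.

midranks <- function(x) rank(x, ties.method = "average")

# Distribution of the sum of a random subset of signs: returns counts over
# totals 0..sum(scores) of +score assignments (2^n patterns).
signed_rank_distribution <- function(scores) {
  total <- sum(scores)
  f <- numeric(total + 1)
  f[1] <- 1
  for (s in scores) {
    g <- f
    idx <- (s + 1):(total + 1)
    g[idx] <- g[idx] + f[idx - s]
    f <- g
  }
  f
}

# Counts of n-subsets of `scores` by score total (shift algorithm / dynamic
# programme over items).
rank_sum_distribution <- function(scores, n) {
  total <- sum(scores)
  f <- vector("list", n + 1)
  f[[1]] <- c(1, numeric(total))
  for (j in seq_len(n)) f[[j + 1]] <- numeric(total + 1)
  for (s in scores) {
    for (j in rev(seq_len(n))) {
      idx <- (s + 1):(total + 1)
      f[[j + 1]][idx] <- f[[j + 1]][idx] + f[[j]][idx - s]
    }
  }
  f[[n + 1]]
}

two_sided_p <- function(weights, observed) {
  # `weights` over integer totals 0..len-1; doubling convention, capped at 1
  tot <- sum(weights)
  obs <- round(observed)
  p_le <- sum(weights[seq_len(obs + 1)]) / tot
  p_ge <- sum(weights[(obs + 1):length(weights)]) / tot
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon signed-rank test (exact under ties)
#'
#' Zero differences are dropped (standard convention); |differences| are
#' midranked and V is the sum of ranks of the positive differences. For up to
#' `exact_limit` non-zero differences the two-sided p-value is exact over all
#' sign patterns via the shift algorithm on doubled midranks; beyond that a
#' normal approximation with tie-corrected variance is used.
#'
#' @param x paired differences, or first member of each pair if `y` given
#' @param y optional second member; differences are `x - y`
#' @param exact_limit largest n for the exact distribution (default 25)
#' @return list of class `rank_test`: `statistic` (V), `p_value`, `n`
#'   (non-zero differences), `exact`, `method`
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_limit = 25L) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero; degenerate signed-rank test")
    return(structure(list(statistic = 0, p_value = 1, n = 0L, exact = TRUE,
                          n_zero_dropped = n_zero,
                          method = "Wilcoxon signed-rank (degenerate)"),
                     class = "rank_test"))
  }
  r <- midranks(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_limit) {
    scores <- as.integer(round(2 * r))
    f <- signed_rank_distribution(scores)
    p <- two_sided_p(f, 2 * v)
    exact <- TRUE
  } else {
    mu <- sum(r) / 2
    sigma2 <- sum(r^2) / 4
    z <- (v - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  structure(list(statistic = v, p_value = p, n = n, exact = exact,
                 n_zero_dropped = n_zero,
                 method = paste0("Wilcoxon signed-rank (",
                                 if (exact) "exact" else "normal approximation", ")")),
            class = "rank_test")
}

#' Exact Wilcoxon rank-sum test
#'
#' W is the midrank sum of `x` in the pooled sample. For `n + m <=
#' exact_limit` the two-sided p-value is exact over all subset assignments
#' via the shift algorithm on doubled midranks (valid under arbitrary ties);
#' larger samples use a normal approximation with tie-corrected variance.
#'
#' @param x,y the two groups
#' @param exact_limit largest pooled size for the exact distribution
#'   (default 50)
#' @return list of class `rank_test`: `statistic` (W, midrank sum of x),
#'   `p_value`, `exact`, `method`
#' @export
exact_wilcoxon_rank_sum <- function(x, y, exact_limit = 50L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n <- length(x); m <- length(y); N <- n + m
  if (n == 0 || m == 0) stop("both groups must be non-empty")
  r <- midranks(c(x, y))
  w <- sum(r[seq_len(n)])
  if (stats::var(r) == 0) {
    return(structure(list(statistic = w, p_value = 1, exact = TRUE,
                          method = "exact Wilcoxon rank-sum (degenerate)"),
                     class = "rank_test"))
  }
  if (N <= exact_limit) {
    scores <- as.integer(round(2 * r))
    f <- rank_sum_distribution(scores, n)
    p <- two_sided_p(f, 2 * w)
    exact <- TRUE
  } else {
    mu <- n * (N + 1) / 2
    sigma2 <- n * m / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
    z <- (w - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  structure(list(statistic = w, p_value = p, exact = exact,
                 method = paste0("Wilcoxon rank-sum (",
                                 if (exact) "exact" else "normal approximation", ")")),
            class = "rank_test")
}

#' Kruskal-Wallis test with rank eta-squared effect size
#'
#' H is tie-corrected (via [stats::kruskal.test()]) and referred to
#' chi-squared with k-1 df; the effect size is the rank-based
#' eta^2 = (H - k + 1) / (n - k), floored at zero.
#'
#' @param values numeric response
#' @param groups factor of group labels (k >= 2, every group non-empty)
#' @return list of class `rank_test`: `statistic` (H), `p_value`,
#'   `effect_size` (eta^2), `df`, `method`
#' @export
kruskal_wallis_eta2 <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  k <- nlevels(groups)
  n <- length(values)
  stopifnot(length(groups) == n)
  if (k < 2) stop("need at least 2 groups")
  if (any(tabulate(groups) == 0)) stop("every group must be non-empty")
  if (length(unique(values)) == 1) {
    h <- 0; p <- 1
  } else {
    kt <- stats::kruskal.test(values, groups)
    h <- unname(kt$statistic)
    p <- kt$p.value
  }
  eta2 <- max(0, (h - k + 1) / (n - k))
  structure(list(statistic = h, p_value = p, effect_size = eta2,
                 df = k - 1, k = k, n = n,
                 method = "Kruskal-Wallis with rank eta-squared"),
            class = "rank_test")
}

# Pairwise standardized Wilcoxon statistic on the pair's own midranks, with
# tie-corrected variance; the building block of the Steel-Dwass procedure.
pairwise_z <- function(xi, xj) {
  ni <- length(xi); nj <- length(xj); N <- ni + nj
  r <- midranks(c(xi, xj))
  w <- sum(r[seq_len(ni)])
  mu <- ni * (N + 1) / 2
  sigma2 <- ni * nj / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
  if (sigma2 <= 0) return(list(w = w, z = 0))
  list(w = w, z = (w - mu) / sqrt(sigma2))
}

#' Steel-Dwass all-pairs comparisons
#'
#' For every pair of groups, only that pair's pooled values are midranked and
#' the standardized rank-sum statistic z computed with tie-corrected
#' variance; the family-wise adjusted p refers sqrt(2)|z| to the studentized
#' range distribution with k groups and infinite df. A seeded Monte-Carlo
#' permutation reference (max statistic over pairs under full label
#' permutation) is available as a cross-check.
#'
#' @param values numeric response
#' @param groups factor of group labels; k >= 3 (k = 2 delegates to
#'   [exact_wilcoxon_rank_sum()])
#' @param method `"asymptotic"` (studentized range) or `"permutation"`
#' @param n_perm permutations for the Monte-Carlo reference
#' @param seed RNG seed for the permutation reference
#' @return data.frame with one row per pair: `group_a`, `group_b`,
#'   `statistic` (rank-sum W of group_a in the pair), `z`, `p_adjusted`
#' @export
steel_dwass <- function(values, groups, method = c("asymptotic", "permutation"),
                        n_perm = 10000L, seed = NULL) {
  method <- match.arg(method)
  groups <- droplevels(factor(groups))
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 groups")
  sizes <- tabulate(groups)
  if (any(sizes < 2)) stop("every group needs at least 2 observations")
  lev <- levels(groups)
  if (k == 2) {
    rt <- exact_wilcoxon_rank_sum(values[groups == lev[1]],
                                  values[groups == lev[2]])
    return(data.frame(group_a = lev[1], group_b = lev[2],
                      statistic = rt$statistic, z = NA_real_,
                      p_adjusted = rt$p_value, stringsAsFactors = FALSE))
  }
  pairs <- utils::combn(lev, 2)
  stat <- apply(pairs, 2, function(pr)
    unlist(pairwise_z(values[groups == pr[1]], values[groups == pr[2]])))
  q_obs <- sqrt(2) * abs(stat["z", ])
  if (method == "asymptotic") {
    p_adj <- 1 - stats::ptukey(q_obs, nmeans = k, df = Inf)
  } else {
    if (!is.null(seed)) set.seed(seed)
    idx_by_group <- split(seq_along(values), groups)
    q_max <- replicate(n_perm, {
      perm <- sample(values)
      grp <- groups
      max(apply(pairs, 2, function(pr)
        sqrt(2) * abs(pairwise_z(perm[grp == pr[1]], perm[grp == pr[2]])$z)))
    })
    p_adj <- vapply(q_obs, function(q) mean(q_max >= q - 1e-12), 0)
  }
  data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
             statistic = stat["w", ], z = stat["z", ],
             p_adjusted = pmin(1, p_adj), stringsAsFactors = FALSE)
}

#' Covariate screen of translocation scores
#'
#' One Kruskal-Wallis test with rank eta-squared per metadata factor on the
#' per-participant translocation abundance score; factors significant at
#' `alpha` receive all-pairs post-hoc comparisons (Steel-Dwass for k >= 3,
#' exact Wilcoxon rank-sum for k = 2). No across-factor multiplicity
#' adjustment is applied by default, mirroring per-factor reporting; set
#' `adjust = "holm"` to add one.
#'
#' @param profiles a `translocation_profile` data.frame
#'   ([translocation_scores()])
#' @param covariates data.frame keyed by `participant_id` whose remaining
#'   factor columns are screened
#' @param value profile column to screen (default `"abundance_score"`)
#' @param alpha significance level gating the post-hoc stage
#' @param adjust `"none"` (default) or `"holm"` across screened factors
#' @return list of class `covariate_screen`: `screen` (factor, k, n, H, eta2,
#'   p_value, significant), `posthoc` (named list of pairwise tables),
#'   `skipped` (constant factors)
#' @export
covariate_screen <- function(profiles, covariates, value = "abundance_score",
                             alpha = 0.05, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot("participant_id" %in% names(covariates),
            value %in% names(profiles))
  idx <- match(profiles$participant_id, covariates$participant_id)
  if (anyNA(idx)) stop("covariates missing for some participants")
  cov <- covariates[idx, setdiff(names(covariates),
                                 c("participant_id", "tongue_sample_id",
                                   "rectal_sample_id")), drop = FALSE]
  y <- profiles[[value]]
  skipped <- character(0)
  rows <- list(); posthoc <- list()
  for (f in names(cov)) {
    g <- droplevels(factor(cov[[f]]))
    if (nlevels(g) < 2) {
      warning("factor '", f, "' is constant; skipped")
      skipped <- c(skipped, f)
      next
    }
    kt <- kruskal_wallis_eta2(y, g)
    rows[[f]] <- data.frame(factor = f, k = kt$k, n = kt$n,
                            H = kt$statistic, eta2 = kt$effect_size,
                            p_value = kt$p_value, stringsAsFactors = FALSE)
  }
  screen <- do.call(rbind, rows)
  rownames(screen) <- NULL
  if (adjust == "holm") screen$p_value <- stats::p.adjust(screen$p_value, "holm")
  screen$significant <- screen$p_value < alpha
  for (f in screen$factor[screen$significant]) {
    g <- droplevels(factor(cov[[f]]))
    posthoc[[f]] <- tryCatch(steel_dwass(y, g),
                             error = function(e) NULL)
  }
  structure(list(screen = screen[order(-screen$eta2), ],
                 posthoc = posthoc, skipped = skipped, alpha = alpha),
            class = "covariate_screen")
}
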