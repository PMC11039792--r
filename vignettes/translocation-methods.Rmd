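---
title: "Scoring oral-to-gut bacterial translocation from paired ASV tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring oral-to-gut bacterial translocation from paired ASV tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oralflux)
```

## The question and the measurement model

The mouth continuously seeds the gastrointestinal tract with bacteria, but
whether those organisms survive transit and appear in the distal gut of
people without intestinal disease is contested. Species-level surveys cannot
settle it, because many species (streptococci, prevotellae) natively inhabit
both sites. Amplicon sequence variants resolve single nucleotides of the 16S
region, so a subject's tongue community carries strain-like variants that
are largely private to that subject; finding those exact variants in the
subject's own rectal sample — and not in other subjects' — is the
translocation signal this package measures.

The core quantities, per participant:

* **tongue ASVs** — ASVs at $\ge 0.1\%$ relative abundance in the
  participant's own tongue sample (inclusive boundary; the threshold is the
  `source_asv_threshold` parameter, a fraction, default $0.001$). Defining
  the set per participant rather than on cohort means is essential: the
  signal is *self*-sharing.
* **translocation abundance score** — the summed relative abundance of those
  tongue ASVs in the paired rectal sample, a number in $[0, 1]$
  interpretable as "what fraction of the rectal community is my own tongue
  flora".
* **richness fraction** — the share of rectal ASVs (count $> 0$) that are
  tongue ASVs.
* **detection** — at least one rectal read on a tongue ASV
  (`min_detection_count`, default 1; no floor beyond a single read).

Compositional dissimilarity uses Bray–Curtis on $\log_{10}(\text{count} +
1)$ vectors. The pseudocount of one maps zero counts to zero, so disjoint
samples sit at distance exactly 1; the log tames the 2–3 orders of magnitude
spanned by amplicon counts so the distance is not dominated by the top taxon.
Both the base and pseudocount are parameters of
`translocation_params()`; results are insensitive to the base (it cancels in
the Bray–Curtis ratio up to the pseudocount's position).

## Intra- versus inter-pair comparison

For metric $m$ (Bray–Curtis similarity $1 - d$, abundance score, or richness
fraction), the intra value of participant $i$ is $m(t_i, r_i)$ and the inter
values are $m(t_j, r_i)$ for all $j \ne i$: other people's tongues scored
against the same rectum. The signed-rank pairing needs one inter value per
participant, so inter values are summarised per participant by their mean
(median available via `inter_summary`); intra versus summarised-inter is
then tested with the exact Wilcoxon signed-rank test. Zero differences are
dropped; an all-zero cohort returns $p = 1$ with a warning rather than an
error, because "every tongue looks the same" is a legitimate degenerate
answer.

A caution discovered while calibrating this comparison on null cohorts
(simulated with zero translocation and no subject-private variants): the
one-versus-mean reduction is only guaranteed symmetric when the metric's
cohort-level fluctuations are small relative to its between-subject spread.
For the compositional similarity metric the test holds its nominal level.
For the score metrics, when a cohort's sharing is carried by a handful of
high-variance shared taxa, all participants' differences inherit a common
cohort-level offset, and the signed-rank test can reject well above nominal
level — in the direction that mimics translocation. The acceptance script
reports the measured type-I rates for both metrics; conclusions about
score-based intra/inter contrasts should lean on the similarity comparison
or on an explicit permutation of the pairing.

Ordination is classical PCoA (double-centered Gower matrix
eigendecomposition, via `cmdscale`); negative eigenvalues are reported, not
dropped, since Bray–Curtis matrices are generally non-Euclidean.

## Exact nonparametric machinery

The covariate screen needs tests that remain exact at cohort scale
($n = 49$) with heavily tied scores:

* **Wilcoxon signed-rank and rank-sum** use midranks for ties and compute
  exact two-sided p-values by the shift algorithm — a dynamic programme over
  doubled midrank scores (always integers) that builds the full null
  distribution of the statistic: over sign patterns for the signed-rank
  test, over group assignments for the rank-sum test. Exactness cutoffs are
  $n \le 25$ and $n + m \le 50$ (covering the cohort), beyond which a
  tie-corrected normal approximation is used and flagged. Two-sided
  p-values use the doubling convention, capped at 1.
* **Kruskal–Wallis** delegates $H$ (tie-corrected) to `kruskal.test` and
  adds the rank effect size $\eta^2_H = (H - k + 1)/(n - k)$, floored at 0.
  A fully constant response returns $H = 0$, $p = 1$ rather than the 0/0 the
  tie correction would produce.
* **Steel–Dwass** ranks each pair of groups separately (midranks,
  tie-corrected variance) and refers $\sqrt{2}\,|z|$ to the studentized
  range distribution with $k$ groups and infinite df — the classical
  all-pairs procedure controlling family-wise error. A seeded max-statistic
  permutation reference is available as a cross-check; the asymptotic form
  is the default since the two agree to a few percent on cohort-sized
  groups. With $k = 2$ the procedure reduces to the exact rank-sum test.

The screen runs one Kruskal–Wallis test per metadata factor on the abundance
score, ranks factors by $\eta^2$, and applies post-hoc comparisons only to
factors significant at $\alpha = 0.05$. No across-factor multiplicity
correction is applied by default, matching per-factor reporting conventions;
a Holm option exists.

## SparCC and cohabiting groups

Correlations between taxa cannot be read off relative abundances — closure
induces spurious negative dependence. SparCC instead works with log-ratio
variances $T_{ij} = \mathrm{Var}\log(f_i/f_j)$, which are invariant to the
closure, and solves for basis variances $\omega_i$ under the sparsity
assumption that most taxa are uncorrelated:
$\sum_{j \ne i} T_{ij} = (D-2)\,\omega_i + \sum_j \omega_j$, then
$r_{ij} = (\omega_i + \omega_j - T_{ij}) / (2\sqrt{\omega_i\omega_j})$,
clipped to $[-1, 1]$. The most strongly correlated pair above the exclusion
threshold (default $0.1$) is removed from the basis equations and the system
re-solved, up to 10 passes, so a few true correlations do not contaminate
the rest. Fractions default to posterior means $(n_{ij}+1)/(N_j+D)$ under a
unit Dirichlet prior — fully deterministic and bit-reproducible; the
original Monte-Carlo Dirichlet resampling (median over rounds) is available
via `resampling_rounds`.

Networks keep edges with $r \ge 0.4$ (inclusive; positive correlations by
default, since co-occurrence is the phenomenon of interest — an
absolute-value mode exists). A *cohabiting group* is a connected component
of that graph over edge-incident nodes, reported deterministically
(largest first). Network taxa are those with $\ge 0.1\%$ mean relative
abundance across the rectal samples.

## The synthetic cohort generator

`generate_cohort()` stands in for the study's sequencing data. Per subject:
an oral composition over oral-specialist plus shared taxa and a gut
composition over gut-specialist plus shared taxa are drawn from Dirichlet
distributions; the rectal composition is the mixture
$q_i = (1-\tau_i)\,p^G_i + \tau_i\,p^O_i$; tongue and rectal counts are
multinomial at truncated-normal depths matching the study's reported
moments ($30{,}323 \pm 6{,}547$ tongue, $36{,}248 \pm 11{,}175$ rectal,
floored at 1000). The translocation fraction follows
$\mathrm{logit}(\tau_i) = \beta_0 + \sum_c \beta_c x_{ic} + \varepsilon_i$
with covariates drawn at the study cohort's frequencies (hypertension 51%,
PPI 24.5%, diabetes 14.3%, the published age and BMI strata).

Key design choices:

* **Subject specificity $\rho$** is the probability that a tongue-side
  taxon's reads in a given subject carry a subject-private ASV variant
  rather than the cohort-shared one. Privacy applies to *all* tongue taxa,
  including shared species, whose gut-resident populations always carry the
  cohort variant: at strain resolution, a subject's tongue streptococcus is
  not the same variant as the cohort's gut streptococcus. $\rho = 1$
  (default) makes rectal reads land on a subject's tongue ASVs only via
  translocation; $\rho = 0$ collapses tongue and gut copies of shared taxa
  onto one ASV and is the null configuration for calibration tests.
* **Defaults** (120 oral, 150 gut, 20 shared taxa; Dirichlet concentration
  0.5; shared taxa down-weighted 5$\times$ in the gut;
  $\beta_0 = \mathrm{logit}(0.005)$, an age-gradient of 0.5 per stratum,
  hypertension 0.6 and PPI $\log 3$ on the logit scale; noise SD 0.5) give
  $\sim$7000 ASVs per cohort and abundance scores spanning roughly 0.3–12%
  with mean $\approx 3\%$ — the scale reported for real paired cohorts. The
  planted effects mirror the clinical factors a real screen should flag.
* **What it does not emulate**: zero inflation (a third of real participants
  show *no* tongue ASVs in the rectum; the logistic-normal $\tau$ model has
  no atom at zero, so simulated detection saturates near 100% at study
  depths), sequencing error and chimeras, phylogenetic structure among
  taxa, and ecological co-occurrence inside the gut community (gut taxa are
  exchangeable Dirichlet components, so network analyses on simulated
  cohorts measure estimator noise, not planted ecology — planted correlation
  structure is exercised separately via `simulate_basis_counts()`). Passing
  tests on these cohorts therefore validate the estimators, not the
  biological realism of any particular dataset.

`generate_multiplexed_fastq()` additionally assembles raw reads in the
layout `tag5 + forward primer + insert + revcomp(reverse primer) +
revcomp(tag3)` (the 8F/338R V1–V2 primer pair with IUPAC degeneracy
resolved per read), with optional substitution errors and corrupted tags,
plus `spike_negative_control()` for a reagent contaminant dominating a
control sample — exercising the length filter (100 bases, applied to the
raw read before trimming), primer verification, dual-tag demultiplexing and
the control-dominance contaminant rule
(relative abundance $\ge 0.5\%$ in a control *and* above the biological
mean) end to end.

## Species assignment and numerical conventions

Nearest-neighbor species assignment aligns each ASV to reference sequences
end-gap-free (semi-global), after a shared 8-mer prescreen for speed;
percent identity is matches over alignment length, the species threshold is
$\ge 98.5\%$ with query coverage $\ge 0.90$ (the coverage floor is a
declared default, not a literature value), and all references tied at the
maximum identity are reported — collapsing merges ties under a sorted
compound label so the operation is deterministic. Genus-level classification
is imported from external classifiers rather than recomputed.

Other conventions: thresholds on relative abundance are inclusive
($\ge$) throughout; per-sample totals are conserved exactly by taxon
collapsing; all-zero samples are flagged at load and rejected by any
operation that normalises; SparCC errors out if basis variances stay
negative after the exclusion passes rather than silently clamping.

## Problem sizes used in validation

The test-suite and acceptance script validate on: exhaustive-enumeration
oracles up to $n \le 8$ (signed-rank) and $n + m \le 10$ (rank-sum)
including ties; 500–1000 random small tables for the score oracle; one
$n = 50$ cohort at study depths for recovery of $\tau$ (Spearman
$\ge 0.8$ required, $\approx 0.997$ achieved); 200 null cohorts for type-I
calibration; SparCC on $D = 50$ taxa $\times$ 500 samples with a planted
0.7-correlation block (per-pair error $\le 0.15$, RMSE $\le 0.15$); and 100
seeded replicates for covariate-screen power. These sizes make the whole
validation suite run in a few minutes on one core while keeping every
Monte-Carlo margin comfortable.
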