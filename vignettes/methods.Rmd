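---
title: "Methods: clade-targeted ASV population structure and transcription ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clade-targeted ASV population structure and transcription ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladepop)
```

`cladepop` analyses the population structure of a single bacterial clade
from a clade-specific marker-gene amplicon (the defaults are configured for
a pmoA fragment), and ranks gene transcription levels from companion
RNA-seq count tables.  This vignette states the underlying models, the
meaning of every default, what the synthetic-data generator does and does
not cover, and the numerical conventions the implementation commits to.

## The amplicon model

The pipeline assumes a **clade-specific amplicon**: all reads derive from
one marker region of fixed length, amplified by anchored primers.  After
primer removal, all sequences have equal length and are compared
**position by position without alignment**.  This is the key simplification
that a clade-targeted primer set buys: within one clade and one amplicon
the marker region is length-conserved, so indel handling and multiple
alignment are unnecessary.  Reads of deviating length are removed by the
filters, not aligned.

* `filter_reads()` keeps a read iff the fraction of bases with Phred
  quality strictly below `q_threshold = 30` is at most
  `max_low_frac = 0.03`, and the read is at least `min_len = 150` nt.
  Both boundaries are closed on the keep side (exactly 3% low-quality
  bases, or exactly 150 nt, is kept): the rule is "discard if *more than*
  3% of bases are below Q30, or *shorter than* 150 bp".
* `trim_primers()` matches one of the forward primers at the 5′ end and
  the reverse complement of the reverse primer at the 3′ end, both
  anchored, honoring IUPAC ambiguity codes in the primer (not in the
  read), with `max_mismatch = 0` by default.  The bundled
  `pmoa_primers()` set has two 20-nt forward primers and one 20-nt
  reverse primer whose 461-bp product leaves a 421-nt insert.  Primer
  absence is a reported outcome (`NA` insert), not an error.
* `dereplicate()` performs exact dereplication of the trimmed reads into
  ASVs (amplicon sequence variants) with per-sample counts.  No error
  model, denoising, or chimera removal is applied; on real reads the
  caller is expected to provide denoised input.  ASV ids are assigned by
  descending total count with lexicographic tie-breaks, so they are
  reproducible functions of the data.
* `subsample_counts()` rarefies every sample to a fixed depth (default
  50,000) by sampling reads without replacement, making richness and
  diversity comparable across samples.

## Distances

`pairwise_distances()` computes the proportion of differing sites *p*
(the p-distance) with **pairwise deletion** of sites where either sequence
has `N`, and the **Jukes–Cantor** correction

$$d = -\tfrac{3}{4}\,\ln\!\left(1 - \tfrac{4}{3}p\right),$$

the evolutionary distance under the one-parameter substitution model with
equal base frequencies and equal substitution rates.  The correction is
undefined at $p \ge 0.75$ (saturation); the package raises an error there
rather than returning `Inf` or `NA`, because a saturated pair inside a
single clade's amplicon indicates corrupt input.  The one deliberate
exception is `place_reference()`, where a saturated *external* reference is
simply beyond any grouping threshold and is reported as `ungrouped` at
infinite distance.

## Tree building

`nj_tree()` wraps the neighbor-joining family from `ape`: `"bionj"`
(default) uses the variance-weighted BIONJ variant, `"classic"` the
original NJ.  Both reconstruct additive distance matrices exactly up to
floating-point error; note that the BIONJ backend carries branch lengths
with about 7 significant digits, so exactness tests for it use a 1e-5
bound while classic NJ meets 1e-9.  Negative branch-length estimates (a
well-known NJ artifact on noisy, non-additive input) are clamped to zero
and the deficit transferred to the adjacent edge, preserving path lengths
as far as possible; the number of clamped edges is recorded in the
`n_clamped` attribute.  `patristic_distances()` returns path lengths
through the tree.

## Species-like groups

`cut_into_groups()` partitions ASVs into "species-like groups" — the
operational species proxy of the pipeline — at a fixed distance threshold
(default `0.04`, i.e. 96% nucleotide identity on the Jukes–Cantor scale,
a commonly used species-level cutoff for protein-coding markers).

Five criteria are offered:

* `"tree-clade"` (default): maximal monophyletic clades of the
  (midpoint-rooted) NJ tree whose **Jukes–Cantor diameter** — the largest
  pairwise JC distance among the clade's members — does not exceed the
  threshold.  The tree supplies the nesting structure; the diameter is
  measured on the distance matrix because the threshold is defined on the
  JC scale.  Patristic (path-length) diameters systematically exceed JC
  diameters: the JC correction is superadditive in *p*, so an NJ tree
  that represents JC distances additively stretches paths relative to the
  direct JC distance between two tips.  Cutting on patristic diameters
  therefore over-splits groups whose JC diameter is just under the
  threshold.
* `"tree-clade-patristic"`: the same clade search with patristic
  diameters, for the stricter reading; it always produces a refinement
  (never a coarsening) of the default.
* `"complete"`, `"single"`, `"average"`: hierarchical clustering on the JC
  matrix cut at the threshold height.  On well-separated data all
  criteria coincide; on marginal data complete linkage is the most
  conservative.

Downstream summaries are `group_counts()` (read counts per group),
`composition_matrix()` (relative abundances per sample, or averaged over
replicates per site), `prevalence_summary()` (site/sample occupancy
classes), and `place_reference()` (nearest-ASV assignment of an external
reference sequence).

## Population statistics

`alpha_diversity()` computes, per sample, observed richness, the
bias-corrected Chao1 estimator
$S_{obs} + F_1(F_1 - 1)\,/\,(2(F_2 + 1))$ (with the classic
$S_{obs} + F_1^2/(2F_2)$ as an option when doubletons exist), Shannon
entropy in nats, and the Gini–Simpson index.  Chao1 requires raw counts;
relative abundances are rejected.

`compare_alpha()` runs a tie-corrected Kruskal–Wallis omnibus across
sites followed by Dunn's z tests on all site pairs with Bonferroni
adjustment.  Two conventions matter at small sample sizes:

* Fully tied data yield $H = 0$, $p = 1$ (the NaN of the raw statistic is
  replaced), and zero-variance pairs get $z = 0$.
* With very few replicates per site (e.g. 3), the chi-square reference
  distribution is conservative: its true rejection rate at nominal 0.05
  is nearer 0.02.  `p_method = "permutation"` replaces the omnibus
  p-value by a Monte Carlo permutation p-value,
  $p = (1 + \#\{H^* \ge H\})/(n_{perm} + 1)$, which is calibrated at any
  sample size.  The asymptotic p remains the default for compatibility
  with the common usage of the test.

`doubling_time()` estimates exponential growth by least squares on
log-protein versus time ($t_d = \ln 2 / b$); a non-positive slope reports
no growth rather than a negative doubling time.
`adjusted_rand_index()` scores partition agreement and is used to compare
recovered groups with a simulation's ground truth.

## Ordination

`bray_curtis()` computes Bray–Curtis dissimilarity between samples on
group abundances via `vegan::vegdist`.  `nmds_embed()` is this package's
own nonmetric multidimensional scaling:

* Objective: Kruskal's stress-1,
  $\sigma_1 = \sqrt{\sum (\hat d - \theta)^2 / \sum \hat d^2}$, where
  $\theta$ is the isotonic regression of configuration distances on the
  rank order of the dissimilarities.  Ties are treated weakly (the
  primary approach): tied dissimilarities are sub-ordered by current
  configuration distance, so the monotone fit never forces equality
  inside a tie block.
* Optimization: alternating isotonic fit (`stats::isoreg`) and Guttman
  transform.  An update that would increase stress is rejected, which
  makes the stress trace within a start provably non-increasing.
* Starts: the first start is the classical metric scaling
  (principal-coordinate) configuration; the remaining `n_starts - 1`
  (default 20 total) are random.  The best final stress wins.  All
  randomness flows from the required `seed` argument, so fits are exactly
  reproducible.

Configurations that embed exactly reach stress below 1e-6; typical small
community matrices converge in well under the `max_iter = 500` cap at
`tol = 1e-7`.  `nmds_ellipses()` returns per-site covariance-ellipse
parameters (default 95%).

## Transcription ranking

`tpm_normalize()` converts counts to transcripts per million.  An
upper-quartile factor (each sample's 75th percentile of nonzero counts,
divided by the geometric mean of those quantiles) is applied before
length/depth normalization by default.  Because TPM renormalizes within
each sample, this factor provably cancels in the TPM values themselves;
it is retained in the exported `norm_count` column where cross-sample
scale matters.  With one sample the factor is identically 1.

`rank_transform()` ranks genes within a sample by descending TPM (average
ranks on ties) and derives `top_percentile` $= 100\,r/N$ and the inverse
percentile score $1 - r/N$.  Both are invariant to any strictly monotone
rescaling of TPM — the property that makes rank profiles comparable
across organisms and libraries with different normalization artifacts.

`categorize_transcription()` maps the top percentile to six ordered
levels: top 1% *extremely high*, 1–5% *very high*, 5–15% *high*, 15–30%
*moderate*, 30–50% *low*, bottom half *very low*; boundaries are closed
on the right, and the factor is ordered with *extremely high* greatest.
`dominant_homolog()` reports, per homolog group and sample, the most
highly transcribed member (ties broken lexicographically and flagged).

`compare_rank_profiles()` tests whether a fixed gene set shifts rank
levels between samples: genes are blocks in a Friedman test, followed by
one-sided Wilcoxon signed-rank tests in both directions per sample pair,
Bonferroni-adjusted over unordered pairs.  Exact signed-rank p-values are
used whenever ties and zeros permit; identical profiles yield statistic 0
and p = 1 by the same convention as above.

## The synthetic-data generator

The generator is a first-class interface, not a test fixture.  Its model:

1. `simulate_species_pool()` draws a uniform-random ancestor and derives
   species centroid sequences by per-site substitution, rejection-sampling
   until all pairwise JC distances clear `min_between_jc` (default 0.08).
   The substitution rate targets pairwise divergence at 1.5× the floor, so
   acceptance is fast in feasible regimes; infeasible packings fail with a
   clear error after `max_tries` attempts per centroid.
2. `simulate_asv_variants()` mutates each centroid at no more than
   $\lfloor p_{max} L \rfloor$ sites, where $p_{max}$ inverts
   `max_within_jc` (default 0.02), so every variant is **guaranteed**
   within its species' radius.  Requiring
   `max_within_jc < min_between_jc / 2` makes species separable by the
   triangle inequality — recovery of the true partition is then a
   mathematical property of the design, not luck.
3. `simulate_site_abundances()` assigns geometric rank-abundances
   (`theta = 0.3`) with an independent species permutation per site, so
   sites share species but differ in structure.
4. `simulate_count_table()` splits species abundance over its variants by
   a symmetric Dirichlet draw, then samples each replicate multinomially
   at exact depth (default 50,000; 4 sites × 3 replicates).
5. `simulate_expression_table()` builds log-normal expression with a
   configurable set of dominant genes holding an exact TPM share, then
   Poisson counts at a fixed library size.

What the generator does **not** cover: sequencing error and chimeras
(reads are error-free, so dereplication equals denoising), indels and
length variation, rate heterogeneity across sites or lineages (the JC
model is also the simulation model), compositional correlations between
sites beyond shared species identity, and any phylogenetic signal beyond
the star-like centroid/variant structure.  Parameter-recovery results on
these simulations are therefore a *correctness* check of the pipeline,
not evidence about its robustness to real sequencing noise.

## Numerical conventions

* Saturation ($p \ge 0.75$) is an error everywhere except reference
  placement.
* All stochastic functions take an explicit integer `seed` and are pure
  functions of it; global RNG state is never consulted or disturbed
  (`withr::with_seed` internally).
* Group, ASV, and protein identifiers are deterministic: ordered by
  descending abundance/size with lexicographic tie-breaks.
* Tests bound classic NJ at 1e-9 against additive oracles and BIONJ at
  1e-5 (backend precision), NMDS exact embeddings at 1e-6 stress, and
  closed-form statistics at standard double precision.

## Limitations

The package analyses one clade at a time and assumes the input reads are
already assigned to that clade; it provides no taxonomy assignment, no
multiple alignment, no denoising, and no phylogenetic inference beyond
distance-based NJ.  The species-like groups are an operational unit tied
to the chosen threshold and criterion; biological interpretation beyond
"sequence cluster at 96% identity" requires external evidence.  The
permutation omnibus is Monte Carlo, not exhaustive, and its p-values have
resolution $1/(n_{perm}+1)$.  NMDS solutions are only defined up to
rotation, reflection, and translation; coordinates are centered but not
otherwise aligned across fits.
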