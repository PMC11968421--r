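---
title: "Methods: stomach-content metabarcoding diet analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stomach-content metabarcoding diet analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietbarcode)
```

This vignette documents the statistical methods behind `dietbarcode`, the
assumptions they make, the tunable parameters and their defaults, and the
design decisions taken where several defensible choices existed. It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Scope and data model

The package starts downstream of bioinformatic read processing: its inputs
are an OTU-by-sample matrix of non-negative integer read counts, a taxonomy
table (seven Linnaean ranks plus an `identity_flag` in
annotated/unidentified/host), per-stomach metadata (group, standard length,
weight, sex, fullness grade 0–5, GPS coordinates), an optional
environmental table per analysis unit, and an optional rooted phylogeny
over the OTUs. Raw FASTQ processing, OTU clustering, chimera removal and
taxonomy assignment are deliberately out of scope.

Two preprocessing rules are fixed by design:

* **Host reads are removed first.** Predator DNA dominates stomach
  amplicons; taxa flagged `host` are dropped before any normalization so
  that read depths and proportions describe prey only.
* **Depth homogenization is rarefaction without replacement.** Each sample
  is subsampled (multivariate hypergeometric, `vegan::rrarefy`) to a common
  depth, by default the minimum post-filter sample total. The target depth
  is configurable because no single depth suits all designs; without
  replacement is chosen because it reproduces the finite-sample composition
  exactly when the depth equals the sample total.

"Unidentified" reads are kept as a first-class taxon at every rank. They
are real stomach content whose taxonomy failed, and excluding them
rescales everyone else's proportions; diet profiles and overlap therefore
include the Unidentified row (the packaged report-table fixtures confirm
that group RRA columns only sum to 100 with it included). A flag on
`diversity_indices()` allows excluding it from per-sample indices, but the
default retains it.

## Diet composition metrics

FO (frequency of occurrence) treats a taxon as present in a stomach when it
has at least `min_reads` reads after rarefaction; the default threshold of
one read is the most inclusive choice and is exposed because metabarcoding
studies sometimes use higher cutoffs against index-hopping. RRA averages
per-stomach read proportions, so each stomach contributes equally
regardless of its depth — the standard semi-quantitative interpretation of
metabarcoding reads as relative biomass.

Food-category RRA is the sum of the member phyla's RRA (RRA is linear in
reads, so aggregation commutes with averaging; a property test asserts
this). Category FO from a group-level profile is reported as the maximum
member-phylum FO and labelled a lower bound: the union frequency is not
recoverable once per-stomach incidences have been aggregated away. When
raw counts are available, collapsing counts to categories first gives the
exact category FO.

Feeding strategies use the Costello-style FO-vs-RRA quadrants with cuts at
FO 50% and RRA 25% by default; values exactly at a cut classify to the
"high" side so that the rule is total and deterministic.

## Diversity, niche breadth and overlap

Per-sample H′, J and B are computed from read proportions at OTU rank by
default. The printed formulas use the natural logarithm, which is the
default; a base-2 option exists because per-sample Shannon values produced
by QIIME-era pipelines (H′ values approaching 5 for a few dozen taxa) are
in bits, and comparisons against such outputs need the matching base.
Group-level summaries report mean ± SE (sd/√n). J is undefined at S = 1
and reported as missing rather than forced to 0 or 1.

Schoener overlap is computed on pooled group-level RRA vectors at phylum
rank. Because published tables are rounded, input vectors are renormalized
to sum to one and a 2% tolerance on the input sum is accepted before
renormalization; the acceptance script reproduces the published overlap
ranges from rounded tables under exactly this rule. 1 − α is half the L1
distance, so α inherits symmetry and the [0, 1] range; property tests
verify this against direct evaluation.

## Community structure

Bray–Curtis works on counts or proportions via `vegan::vegdist`. Weighted
UniFrac is computed in-package by a single postorder traversal that
accumulates descendant read mass per branch; the normalized variant
(default) divides by `Σ len·(A+B)` so distances lie in [0, 1]. The
normalized default was chosen for boundedness — the raw variant sits
behind a flag. Tests compare the implementation against brute-force branch
enumeration, the star-tree half-L1 closed form, and the independent
`phyloseq::UniFrac` implementation, all at 1e-10.

NMDS minimizes Kruskal stress-1 with `vegan::monoMDS`, restarting from
random configurations (20 by default, seeded) and keeping the best
solution; k = 2 by default and stress < 0.2 is flagged as interpretable in
the print method. PERMANOVA uses Anderson's pseudo-F partition via
`vegan::adonis2` with free one-factor label permutation and the
`(1 + x)/(1 + N)` p estimator; for small designs vegan switches to
complete enumeration, and the tests confirm equality with an independent
full-enumeration oracle at n ≤ 6. Type-I error under an exchangeable
Dirichlet-multinomial null is checked at 0.05 ± 0.02 over 500 simulations.

The compact letter display uses pairwise Kruskal–Wallis tests (midranks,
tie correction) and the insert-and-absorb algorithm; no installed package
derives letters from a p-value matrix, so that step is implemented here.
P-value adjustment across pairs defaults to none, matching how such tables
are usually annotated, and is configurable.

The LDA effect size is a re-implementation of the LEfSe procedure:
relative abundances scaled to 1e6, per-taxon Kruskal–Wallis screen at
α = 0.05, then 30 bootstrap rounds (two-thirds subsampling per class) of a
linear discriminant (`MASS::lda` on slightly jittered features, to keep
within-class covariances non-singular); each round combines the raw
between-class mean difference with the LDA-projection difference, and the
average is reported on a log10 scale with the default flagging threshold
of 4. Samples are put in canonical order first so the flagged set cannot
depend on input column order. Scores follow the LEfSe convention but exact
equality with the Galaxy implementation is not promised — the contract is
threshold behavior: well-separated taxa score above 4, identically
distributed taxa are never flagged.

## Environmental drivers

VIF screening is iterative worst-first: compute `VIF = 1/(1 − R²)` for
every variable, drop the largest while any exceeds the threshold (10 by
default), recompute. Worst-first removal is standard practice and makes
the procedure deterministic; perfectly collinear variables surface as
infinite VIFs and leave first. Re-running the screen on its own output is
a no-op (tested).

Spearman correlations use midranks; p-values are exact (permutation null)
when there are no ties and n is small, falling back to the t approximation
otherwise. The standardized regression z-scores predictors, checks the
response with Shapiro–Wilk, and under `transform = "auto"` picks the
log or inverse transform with the better Shapiro–Wilk p when normality
fails, recording the choice. GLMs are IRLS fits via `stats::glm`
(binomial-logit for prey presence, gamma-log for strictly positive
indices), with gamma dispersion from the Pearson χ²/df and a separation
flag when binomial fitted probabilities collapse to 0/1.

Ordination follows the gradient-length rule: Hellinger-transform the
abundances (square root of sample proportions, making Euclidean methods
appropriate for compositions), run DCA (`vegan::decorana`: detrending by
26 segments, Hill's nonlinear rescaling), and read the first-axis gradient
length in SD units — below 3 SD use RDA, above 4 SD use CCA, in between
either is defensible and RDA is taken as the working default. CCA itself
is not implemented; a recommendation of CCA is reported as such and the
pipeline records a notice. Degenerate inputs where DCA cannot run are
treated as zero-length gradients.

RDA (via `vegan::rda`) reports axis variance both as a fraction of the
constrained variance and of the total variance, because either basis can
be meant by a printed "% explained" — reports label both. Permutation
tests (default n = 5000) cover the global model and the first axis;
envfit r² is computed against the first two axis site scores (the plotted
axes) with the same permutation count. Models exposing fewer than two
axes (single predictor, saturated fit) pad the second axis with NA rather
than failing.

Geographic distances are haversine great-circle distances on a 6371.0 km
Earth radius. The Mantel statistic defaults to Pearson correlation of the
lower triangles, with simultaneous row/column permutation of one matrix
and the `(1 + x)/(1 + N)` estimator (default 10,000 permutations); both r
and r² are reported because published Mantel summaries sometimes print
the square.

## The synthetic generator

`simulate_counts()` emulates a grouped stomach-content survey:

* **Design.** Two ready-made scenarios mirror a typical two-phase survey:
  five populations with 3–5 stomachs each (23 total) and four seasons of
  15 stomachs. Per-sample read depths are log-normal with median 1e5 and
  log-sd 0.15, matching the depth range such surveys report.
* **Compositional model.** Dirichlet-multinomial: one shared base
  composition; each group's mean composition shifts on the log scale by a
  known effect (±1 per SD of the first environmental variable on four
  responsive taxa, summing to zero across taxa) plus a mild unexplained
  group divergence (log-sd 0.3, emulating unmeasured local prey
  availability); each stomach draws its own composition from a Dirichlet
  with concentration θ = 20 around the group mean, then reads from a
  multinomial. θ = 20 gives the visible per-stomach heterogeneity (taxa
  with FO well below 100% but substantial group RRA) that motivates
  overdispersed models; θ → ∞ recovers pure multinomial sampling, which a
  consistency test exploits.
* **Why the shared base.** Drawing independent base compositions per group
  would make group identity confound the environment completely — no
  method could attribute the differences to the driver. With a shared
  base, the environmental effect is the systematic group difference, so
  driver-recovery benchmarks (envfit ranking the true driver first) have
  a well-defined truth.
* **Trimmings.** An "Unidentified" taxon takes a configured read fraction
  (5% default; 0 removes it). Taxonomy assigns OTUs to real phyla across
  the five food categories; the tree is a random bifurcation with
  exponential branch lengths; metadata includes allometric weights,
  jittered per-group GPS coordinates and fullness grades. Everything is
  byte-identical under a fixed seed.

What the generator does **not** emulate: sequence-level artefacts (PCR
bias, chimeras, index hopping), realistic phylogenies (branch lengths are
arbitrary), spatial autocorrelation beyond group membership, and
covariance between environmental variables. Passing tests therefore show
that the estimators and tests behave correctly under a clean
overdispersed compositional model — not that any particular field dataset
meets those assumptions.

`two_group_effect_scenario()` is the benchmarking entry point: two groups
differing by a stated logit shift on a known taxon subset, with truth
labels attached. Effect 0 gives an exchangeable null used for the
permutation-test calibrations.

## Numerical choices and degenerate inputs

* Report tables round half-up at 2 decimals (the convention of the
  published tables); test statistics at 3.
* All permutation procedures take an explicit seed; the pipeline default
  (20220101) is echoed in the run manifest, and seeding is done with
  `withr::with_seed` so the caller's RNG stream is untouched.
* Ties in rank tests use midranks with tie-corrected variances throughout.
* Zero-read samples error by name everywhere proportions are needed;
  empty groups error at group alignment; samples below the rarefaction
  depth are dropped with a warning listing them.
* Overlap inputs are renormalized within a 2% tolerance (rounded printed
  tables); vectors further from the simplex are rejected.

## Problem sizes used by the test suite

Calibration and benchmark tests run at deliberately small sizes chosen to
give adequate Monte-Carlo precision: 500 null simulations for the
PERMANOVA type-I check and 2000 for the (much cheaper) Mantel check
(binomial SE ≈ 0.01 and 0.005 at a 0.05 rate), 100 simulations for
PERMANOVA power and envfit driver-ranking, depths of 500–20,000 reads and
12–30 taxa for simulated communities. These sizes are a package choice
balancing precision against suite runtime; the estimators themselves are
size-agnostic.

## Known limitations

* CCA is a recommendation only; long-gradient data need another tool.
* The LEfSe re-implementation omits the subclass (within-group) stage of
  the original, which the one-factor designs here do not use.
* Category FO from aggregated profiles is a lower bound (see above).
* The exact "fullness index" convention varies between authors; this
  package defines it as the percentage of stomachs at grades 4–5 and the
  empty index as the percentage at grade 0, which is consistent with the
  values the shipped fixtures imply but is a documented choice, not an
  identity.
* Mantel tests on diet vs geography inherit the usual caveat that
  distance-matrix permutation tests have low power against spatially
  structured alternatives.
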