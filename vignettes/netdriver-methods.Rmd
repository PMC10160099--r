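---
title: "Hidden-driver inference: models, estimators and design choices"
author: "netdriver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hidden-driver inference: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A *hidden driver* is a regulator — a transcription factor or a signaling
protein — that drives a phenotype without itself being differentially
expressed: its regulatory output is altered post-translationally, through
complex formation, localization, phosphorylation, or upstream signaling
rather than through its own transcript or protein abundance. Case–control
differential expression is structurally blind to such regulators. They are,
however, visible *through their targets*: if a kinase's activity rises, the
expression of the genes it ultimately controls shifts coherently, even while
the kinase's own mRNA stays flat.

`netdriver` operationalizes this idea in three stages:

1. **Reverse-engineer a context-specific interactome** from a large
   expression cohort, via mutual information (MI) with bootstrap consensus
   and data-processing-inequality pruning, separately for transcription
   factors (TF) and signaling factors (SIG).
2. **Infer per-sample driver activity** as the signed-MI weighted mean of
   the driver's target expression.
3. **Test differential activity (DA)** and differential expression (DE)
   between two phenotype groups per omics modality (mRNA, whole proteome,
   phosphoproteome), **integrate** evidence across modalities by Stouffer's
   method, and rank drivers in a master table. Hidden drivers are the rows
   with strong integrated DA and null DE.

A seeded synthetic-data generator plants hidden drivers with known regulons,
activities and group shifts, so every stage of the pipeline is validated
against ground truth without any external cohort.

## Mutual-information estimation

Edges are scored by MI between two expression profiles. Two estimators are
provided (`compute_mi()`), both operating on ranks, in nats:

* **Adaptive recursive partitioning** (default, the ARACNe-lineage choice).
  Observations are mapped to distinct integer ranks (ties broken by sample
  position, deterministically — important for bootstrap resamples, where
  duplicated samples create ties). The unit rank square is split into four
  quadrants at the cell's marginal medians while a chi-square uniformity
  test over the quadrant counts rejects at alpha = 0.05 (critical value
  7.815, 3 df); cells with fewer than 8 points are never split. Each leaf
  contributes its empirical-vs-product-measure Kullback–Leibler term; since
  the leaves tile the square, the sum is non-negative.
* **Fixed-bin plug-in**: the exact plug-in MI over a k×k equal-frequency
  grid; when a margin has at most k distinct values, its values are used as
  categories directly, so discrete instances are scored on their exact
  support. This estimator is the analytic test oracle and a CLI option.

**Bias.** The significance-gated partition stops splitting once local
dependence is undetectable at alpha = 0.05, so residual within-cell
dependence is truncated away. In the linear-Gaussian family (closed form
MI = −½·log(1−ρ²)) the estimator recovers a stable ≈ 50–60 % of the true MI
at n = 2000. This multiplicative truncation bias is irrelevant for network
inference — thresholds are calibrated against the same estimator's null —
and the test suite asserts the estimate stays within a 0.35–1.1 band of the
closed form. Absolute MI values in network files should be read with this
in mind.

**Null threshold** (`mi_null_threshold()`). The per-bootstrap edge gate is
the (1−p)-quantile of MI between independently permuted rank vectors.
Because both estimators are rank-based with deterministic tie-break, this
null depends only on the sample size. The null has an atom at zero (an
independent pair usually fails the root test, giving MI exactly 0; ≥ 99 %
of mass at n ≥ 50), so coarse cutoffs are resolved as empirical quantiles,
and cutoffs beyond the Monte-Carlo resolution (default 20 000 permutations)
are extrapolated with an exponential fit to the top-100 exceedances. At
very small n the null is nearly atomic and the extrapolated deep tail is
approximate; the monotone decrease of the threshold in n is exact in the
empirical regime and only approximate at extrapolated depths.

## Network reconstruction

For each of n = 100 bootstraps (the recommended default), samples are drawn
with replacement (bootstrap b is seeded `seed + b`), MI is computed between
every driver and every other gene (candidate edges are driver→gene pairs;
driver–driver edges are allowed and appear in both regulons), edges below
the null threshold at the per-bootstrap significance level (default 1e−7)
are discarded, and DPI pruning is applied: in every triangle, edge (i,j) is
removed iff `mi(i,j) < min(mi(i,k), mi(k,j))·(1 − tolerance)` (default
tolerance 0), decisions evaluated simultaneously against the unpruned
graph. The weakest edge of a triangle is presumed indirect.

**Poisson consensus.** Across bootstraps, an edge's support count is
referred to a Poisson null: with T total edge occurrences over the E
candidate driver→gene pairs, μ = T/E and the consensus p-value is the
upper Poisson(μ) tail at the support count; edges with p < pc (default
1e−5) are retained. E is the *candidate* count, not the count of edges
observed at least once: μ is then a genuine noise-recurrence rate, and the
retention cutoff sits just above the support that bootstrap noise can
produce. (With observed-only E, μ converges to the mean support of true
edges whenever detection is good and the candidate space is small, and the
cutoff then lands inside the true-edge support distribution — retention
becomes unstable. We measured exactly this failure mode on synthetic
plants.) Retained edges carry the mean MI over supporting bootstraps and
the sign of the full-data Spearman correlation (average ranks for ties; a
zero correlation gives sign 0, which contributes no directional evidence
downstream).

**A deliberate property of the bootstrap null.** Bootstrap resampling
duplicates samples; duplicated points carry genuine joint structure, so the
per-bootstrap false-positive rate sits above the nominal permutation level.
This floor of weak, flickering candidates is what calibrates μ; the
consensus step then removes it (support counts of a few vs. cutoffs of
dozens). A side effect is that in *dense* candidate spaces, pairs with
moderate full-cohort sampling correlation (|r| ≈ 0.2 at n = 200) recur
often enough to be retained: on the synthetic benchmark about 40 % of
retained edges are such weak cohort-correlation edges rather than planted
ones. They carry small MI weights and null differential signal, and do not
measurably perturb driver ranking; on the sparser planted-network recovery
setting (10 drivers × 50 targets), precision and recall are both 1.0 at
n = 200.

## Network QC

`qc_report()` summarizes size, density, total-degree statistics,
eigenvector (L2-normalized) and PageRank (damping 0.85) centralities via
igraph, per-driver target sizes, and the scale-free check: the R² of the
OLS fit of log10 empirical degree frequency on log10 degree over distinct
total degrees (isolated nodes excluded). A mean regulon size outside
[100, 1000] raises a flag — a practitioner's rule of thumb that useful
genome-wide networks average several hundred targets per driver; scaled-
down synthetic networks trip this flag by construction and the flag is
informational only.

## Activity inference

With z the row-standardized expression of target t in sample s
(`std = TRUE` applies the z-transform first, the default) and regulon edges
carrying MI weight `mi_t` and sign `s_t`:

* weighted mean (default): `Σ_t s_t·mi_t·z_ts / Σ_t mi_t`
* mean: `(1/|T|)·Σ_t s_t·z_ts` (sign-directed, unweighted)
* mean_unsigned: `(1/|T|)·Σ_t z_ts` — the strict prototype form; kept
  because the contrast against it is scientifically meaningful (below)
* absmean: `(1/|T|)·Σ_t |z_ts|`
* maxmean: the mean positive part or mean negative part of `s_t·z_ts`,
  whichever is larger in magnitude

Activity is a weighted mean on the z scale, so it is invariant to rescaling
a regulon's MI weights, is negated by flipping all signs, and rises
monotonically in any positively-signed target — all asserted exactly in the
tests. Targets absent from a modality are dropped and the denominator is
recomputed; drivers with fewer than `min_targets` (default 5) usable
targets are excluded from that modality and reported. The default of 5
guards against unstable single-target activities on sparse proteomic
coverage.

**Why the sign and the weight matter.** A driver with a balanced regulon —
half its targets activated, half repressed — moves its targets in opposite
directions; unsigned averaging cancels the two halves and sees nothing.
The signed weighted mean re-aligns them. The synthetic benchmark plants
exactly one such balanced hidden driver, and the acceptance suite asserts
that the weighted-mean route detects it while the unsigned route does not.

## Differential statistics

`de_two_group()` is the moderated-t route: per-feature pooled-variance
two-sample comparison, with empirical-Bayes shrinkage of residual
variances toward a common prior. The prior (d0, s0²) is estimated by
moment matching on log variances (digamma/trigamma inversion, d0 clamped
to [0.1, 500]); the moderated variance is the convex combination
`(d0·s0² + d·s²)/(d0 + d)` and t is referred to d0 + d degrees of freedom.
At d0 → 0 the route reduces exactly to the ordinary pooled t (asserted to
1e−9); against the independent limma implementation on random data the
moderated t correlates > 0.999. Moderation is what makes n = 2 per group —
the realistic proteomics regime — testable at all.

`bid_two_group()` is the Bayesian linear-regression route
(`value ~ intercept + β·group`): `MLE` is OLS, whose β̂/se(β̂) equals the
unmoderated pooled t with a normal reference; `Bayesian` (default) places a
flat prior on coefficients and a scaled inverse-chi-square prior on the
residual variance (prior df a0 = 1, prior scale = the ensemble mean of
per-feature residual variances). The exact prior family here is a design
choice of this package: it is conjugate, washes out to MLE as a0 → 0
(asserted to 1e−6), and regularizes zero-residual-variance features, which
at n = 2 per group are common.

All tables carry logFC (group1 − group0, groups ordered lexicographically),
a two-sided p, the signed normal deviate z = sign(t)·Φ⁻¹(1 − p/2) — derived
from p rather than raw t so that z scales are comparable across modalities
with different df — and Benjamini–Hochberg adjusted p-values.

## Integration and the master table

Stouffer's method is canonical: `z_comb = Σ w_i·z_i / sqrt(Σ w_i²)`, equal
weights by default (√n weighting is a config option; the default is neutral
because modalities with n = 4 and n = 2 per group are already placed on a
common z scale). Fisher's combination of p-values (−2·Σ log p ~ χ²(2k)) is
offered secondarily — it loses sign, and the master table needs signed
evidence. p-values are floored at 1e−300 before logs. For two-sided inputs
Fisher is only concordance-gaining for |z| ≳ 1.5; at |z| ≈ 1 it can be
weaker than a single test, which is expected behavior of the statistic, not
an artifact.

`build_master_table()` joins per-modality DA and DE tables by driver,
Stouffer-integrates each across modalities (drivers absent from a modality
integrate over the modalities where they are present), re-applies BH across
drivers on the integrated p, and ranks by |integrated DA z| with
lexicographic tie-break. The assembly is a pure function: identical inputs
give byte-identical tables.

## Enrichment

`fisher_enrich()` is the one-sided hypergeometric overlap test per gene set
with BH across sets; the default universe is the measured gene set of the
supplying matrix, not the genome — unmeasured genes inflate enrichment.
`gsea_es()` is the weighted Kolmogorov–Smirnov running sum (hit increment
`|score|^exponent` normalized over hits, miss decrement 1/(N−|set|); ES =
signed extreme). Default exponent 1; the permutation null permutes *gene
labels*, not phenotypes, because DA designs here can have two samples per
group and phenotype permutation is degenerate. Two-set and activity-based
enrichment variants are out of scope.

## The synthetic generator

`generate_truth()` plants a bipartite driver→target network: edges are
assigned to drivers preferentially (regulon sizes are heavy-tailed —
`scale_free_r2` of the size distribution exceeds 0.6 at 500 drivers), each
target has exactly one driver so truth is unambiguous, weights are
log-normal (meanlog 0, sdlog 0.4) and signs are negative with probability
`frac_negative_edges`. Hidden drivers are modeled as master-regulator hubs
(regulon floor 30) — real positive-control drivers of this kind are hubs,
and a driver must keep ≥ `min_targets` usable targets after 30 % phospho
coverage to be observable there at all. The first hidden driver receives an
exactly sign-balanced regulon (the configuration unsigned averaging
misses).

`simulate_expression()` is linear-Gaussian: latent activity
`a ~ N(shift·1[group 1], 1)`; target expression `s·w·a + N(0, noise_sd)`;
driver own expression `a + N(0, driver_noise_sd)`. Under this model the
MI between activity and a target has the closed form −½·log(1−ρ²) with
ρ = w/√(w²+σ²), which the estimator tests exploit. Two regimes:

* **Driver-inference (group-comparison) matrices**: hidden drivers'
  own-gene expression is *decoupled* — standard normal, independent of
  activity and flat across groups. This is the hidden-driver phenomenon:
  strong DA, null DE.
* **Network-construction cohort** (`decouple_hidden = FALSE`): every
  driver's own expression tracks its activity (tightly, driver noise sd
  0.25). This is a modeling necessity, not a contradiction: MI-based
  reverse engineering can only discover a driver's regulon through the
  driver's own measured profile. Biologically it corresponds to the usual
  situation that a regulator's transcript does covary with its activity
  across a large heterogeneous cohort, while in the specific two-condition
  comparison its regulation is post-transcriptional.

`make_benchmark_suite()` freezes the benchmark conditions: 160 drivers
(8 hidden, one balanced), mean regulon 6 with hub floors as above, a
200-sample construction cohort, and three driver-inference modalities sized
like a small stimulation experiment — mRNA n = 4+4 at full coverage, whole
proteome n = 2+2 at 70 % coverage, phosphoproteome n = 2+2 at 30 %
coverage. The hidden-driver activity shift is 4 latent-activity standard
deviations: strong experimental perturbations (e.g. receptor stimulation
time courses) produce adjusted p-values near 1e−12 at n = 4 per group,
which implies standardized effects of this magnitude; 4 is the conservative
end of that regime. The whole bundle derives from one seed and is
byte-stable.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: count-level sequencing noise (profiles are
Gaussian on the log scale by construction), not-at-random proteomic
missingness (coverage is a uniform random subset), batch effects, correlated
regulons (each target has one driver), and drivers whose construction-cohort
expression is fully decoupled from activity (such drivers are invisible to
expression-based network inference by any method).

## Numerical and testing choices

* All randomness flows from explicit integer seeds; internal seeding is
  localized (`with_local_seed`) and never disturbs the caller's RNG.
* Rank tie-break is by sample position — bit-reproducible across platforms.
* Degenerate inputs fail loudly: zero-sd rows in `z_transform`, < 2 groups
  or empty usable driver sets, gene sets covering the whole ranking.
* Problem sizes in the test and acceptance suites are scaled to desk
  hardware: the 50-seed hidden-driver benchmark uses the 160-driver bundle
  above (~7 s per seed); network-recovery checks use 10 drivers × 50
  targets across cohort sizes 20–200; calibration checks use 2000 null
  features. These sizes are the package's own validation conditions.

## Known limitations

* The adaptive MI estimator's truncation bias (≈ 40–50 % at n = 2000)
  makes absolute MI values estimator-specific; only relative comparisons
  and null-calibrated thresholds are meaningful.
* In dense candidate spaces the consensus retains weak cohort-correlation
  edges (see above); regulon *membership* lists should be read as
  cohort-dependencies, not as direct physical targets.
* Only two-group designs are supported; multi-group contrasts, covariates
  and survival association are out of scope.
* The deep-tail (1e−7) MI threshold is an exponential extrapolation; its
  Monte-Carlo uncertainty is a few percent of the threshold at the default
  20 000 permutations.
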