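---
title: "tadcnv: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tadcnv: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`tadcnv` treats CNV pathogenicity prediction as supervised classification on
functional features computed *within the variant's TAD environment*. The
underlying biological assumption is that TAD boundaries delimit the set of
regulatory contacts a CNV can disturb, so candidate elements for every
feature are restricted to the TAD(s) the CNV intersects; a CNV spanning
several TADs draws candidates from the union of those environments, and a
CNV outside every annotated TAD cannot be scored at all (it is reported on a
side list instead of receiving a fabricated feature vector).

The classifier is a random forest over 12 default features (distances to the
closest gene, DDG2P gene, enhancer, CTCF site and TAD boundary; LOEUF, p(HI)
and HI log odds of the closest gene; conservation of the closest enhancer;
stability of the closest boundary; a pcHi-C overlap score; and the distinct-
exon overlap count). Scores are the forest's class-1 probability, so a
score of 0.8 reads as "80% of the evidence-weighted trees consider this
variant pathogenic-like".

Assumptions worth keeping in mind:

* **Labels are trustworthy and binary.** Real curation labels
  (pathogenic / likely pathogenic / unknown) are collapsed upstream by
  `filter_cnvs(allowed_labels = ...)`; the model itself sees two classes.
* **Size is a nuisance variable, not a feature.** Pathogenic and benign call
  sets come from different assays with very different size spectra, so
  training data are size-matched first (below). Variant length is *never* a
  model feature.
* **DEL and DUP are different problems.** Models carry an `svtype` tag and
  `predict()` refuses mismatched data; train separate models per type.

# Preprocessing and the no-leakage discipline

Missing feature values (e.g. no enhancer in the environment) are imputed
with the *training-set* mean per feature; features are then min–max scaled
to [0, 1] with *training-set* extremes. Both transforms are stored in the
model object, so prediction-time preprocessing is bit-identical to training.
Inside `cross_validate()` the imputer and scaler are re-fitted within every
fold on that fold's training part only — the per-fold parameters are
returned (`$prep`) precisely so tests can prove, by mutating held-out rows,
that no information leaks. Constant training columns scale to 0 (any
constant is uninformative); out-of-range test values are deliberately not
clipped, which preserves score ordering.

# Size matching and ranking

`ecdf_size_bins()` builds 60 equal-probability bins from the benign size
distribution (linear-interpolation quantiles, duplicate edges collapsed;
sizes outside the range clamp into the terminal bins). The source text for
this procedure uses both "bin size 60" and "60 bins"; we follow the second
reading — 60 equal-probability ECDF bins — because the ranking procedure
states it unambiguously, and the parameter is configurable regardless.
`size_match()` keeps `min(n_path, n_benign)` variants per bin from each
class, sampled without replacement.

The ranking analysis builds batches of 1 pathogenic + 99 size-matched
controls. Pathogenic variants larger than the largest control are discarded;
bins holding fewer than 99 controls produce no batch (the source only
defines the "99 or more" branch; skipping preserves the fixed batch size)
and such variants are reported in a `skipped` table. Ranks are 1-based;
score ties are broken uniformly at random under the batch seed, with a
pessimistic `"pathogenic_last"` mode for sensitivity analysis.

# The random forest

No random-forest implementation is available in the target environment, so
the forest is implemented in Rcpp: CART trees on Gini impurity, `mtry =
floor(sqrt(p))` features per split (midpoint thresholds between distinct
values), unlimited depth, minimum leaf size 1, 500 trees, and a per-class
stratified bootstrap (each class resampled to its own size) so class balance
survives resampling. All randomness flows through R's RNG — `set.seed()`
makes training, fold assignment and permutation importance exactly
reproducible. Out-of-bag (OOB) bookkeeping is first-class: the in-bag matrix
is stored, OOB scores are computed at training time, and
`oob_accuracy(model, x)` recomputes OOB accuracy on a *modified* training
matrix, which is what cluster permutation importance needs. Hyperparameters
can be grid-searched via `tune_grid` (scored by within-training 5-fold CV
AUC), off by default.

# Feature importance over correlated clusters

Individual permutation importance is biased when features are correlated:
permuting one member of a correlated group leaves its proxies intact. We
therefore cluster features on partial correlation (computed from the inverse
covariance; a singular covariance gets a `1e-6` ridge, with a message) and
permute whole clusters with one shared row permutation, reporting the mean
and SD of OOB-accuracy loss over 30 seeds.

One design point was genuinely open. The build contract fixed the clustering
distance as `1 − |pcorr|`, whose range is [0, 1]: at the conventional flat
cut of exactly 1, *every* merge height is ≤ 1 and all features collapse into
a single cluster, making per-cluster importance vacuous. The scientific
Python stack the original analysis used defines correlation distance as the
signed `1 − r` (range [0, 2]), under which a cut of 1 separates positively
correlated groups from independent and anti-correlated ones and produces the
multi-cluster structure the method is about. `cluster_features()` keeps the
absolute distance as default for contract fidelity and offers
`distance = "signed"`; the acceptance suite uses the signed variant at cut 1.
With the absolute metric, use a cut below 1 (e.g. 0.9).

# Enrichment testing

`enrichment_test()` is a GAT-style constrained bootstrap. The workspace is
split into isochores — maximal runs of GC-track windows sharing one of
`n_gc_classes` equal-width GC classes — and every merged query segment is
re-placed uniformly at random inside an isochore of its own GC class,
length preserved, for each of `n_samples` draws (default 10,000; the draws
are shared across annotation tracks). The statistic is the segment-overlap
count (a segment counts once however many annotation intervals it touches).
Empirical p-values use the add-one pseudocount `(k + 1)/(n + 1)`, so `p ≥
1/(n + 1)` always. GC conditioning matters because CNV formation is not
uniform along the genome; without it, compositional biases masquerade as
enrichment.

Two numerical details are worth making explicit:

* **Directional p-values.** Enrichment and depletion are tested one-sided
  and the smaller p is reported with its direction, *not doubled*. That
  reported minimum is a directional summary: its null distribution is
  conservative in the small-p tail (ties between integer counts and the
  pseudocount see to that) but its support is bounded near 0.5, so it is not
  — and cannot be — uniform over [0, 1]. The one-sided `p_enriched` /
  `p_depleted` columns are exposed for calibration work, and the acceptance
  suite checks uniformity on the one-sided p plus tail-conservativeness of
  the reported minimum.
* **Degenerate placements.** A segment larger than every isochore of its
  class falls back to any isochore large enough (counted and warned); an
  annotation covering the whole workspace yields observed = expected,
  log2FC = 0, p = 1; observed > 0 with expected = 0 reports `Inf` with the
  `fc_defined` flag unset.

q-values are Benjamini–Hochberg across the annotation tracks of one call
(`correct_pvalues()`); the conventional significance threshold downstream is
q ≤ 0.01. `compare_fold_changes()` contrasts two result sets (e.g.
pathogenic vs benign CNVs) with a joint-significance flag.

# The synthetic world

`generate_genome()` builds a toy genome — by default 2 chromosomes × 10 Mb,
20 TADs per chromosome separated by 10 kb boundaries, 3 genes / 5 enhancers /
5 CTCF sites per TAD — with score distributions chosen to caricature the
real tracks: p(HI) ~ Beta(0.5, 0.5) (so roughly a fifth of genes exceed the
0.9 haploinsufficiency threshold, giving the planting step targets), LOEUF ~
Gamma(2, 0.4) truncated at 2 (right-skewed, mass near the intolerant end),
HI log odds = logit(p(HI)) + N(0, 0.5) (strongly but not perfectly
correlated with p(HI), as in real constraint tables), enhancer conservation
~ Beta(2, 5), boundary stability ~ Beta(2, 2), 5% of gene scores missing so
the imputer is always exercised. The GC track is either uniform (one
isochore per chromosome) or blocky (alternating 0.35 / 0.55 blocks, giving
several isochores and a real GC-conditioning constraint).

`generate_cnvs()` plants the class signal: a pathogenic CNV overlaps a
p(HI) > 0.9 gene with probability 0.9 and otherwise avoids such genes; a
benign CNV hits with probability 0.1. Sizes are log-uniform (pathogenic
5–200 kb, benign 2–100 kb — overlapping but shifted, so size matching has
work to do). These are the stated conditions of the package's validation
world, set once; the null world sets both hit probabilities to 0 with equal
size ranges.

What a green test establishes — and what it does not: the simulator
validates that the pipeline *recovers a known planted signal* (held-out AUC
above the pre-registered 0.80 bound, chance performance on the null world,
the haploinsufficiency cluster ranked first in importance) and that every
interval operation agrees with brute-force oracles. It does not emulate
segmental duplications, assay-specific breakpoint noise, population
structure in allele frequencies, chromosome-scale GC gradients, or the
label noise of real curation databases, so performance numbers on the toy
world say nothing quantitative about performance on patient data.

# Other numerical choices and conventions

* Coordinates are 0-based half-open throughout (BED convention); VCF input
  (1-based inclusive POS/END) is converted on read.
* The ">50 bp" size filter is strict; a 50 bp variant is removed.
* The allele-frequency cap has a `strict` (default) and `inclusive` mode
  because the source material uses both "< 0.1" and "≤ 0.1".
* Reciprocal-overlap dedup uses single-linkage transitive closure; equal-size
  ties break lexicographically by (chrom, start, end, id); under source
  priority, unknown sources sort last with a warning.
* LOEUF semantics are standard — low LOEUF = pLoF-intolerant — with an
  `"inverted"` switch, because the source text contains a transposed
  sentence contradicting both the score's definition and its own results.
* The coding-penalty transform replaces (p(HI), HI log odds, LOEUF) with
  (0, −10, 2) on rows with no exon overlap — each the value of least
  regulatory importance — and is idempotent.
* Closest-element ties break toward the smaller start; score ties at the F1
  threshold are non-pathogenic (strictly greater than 0.5 is required).

# Known limitations

* TAD calling itself is out of scope; environments come from user-supplied
  boundary/region files.
* The pcHi-C score divides by LOEUF, so genes with missing or zero LOEUF are
  skipped (with a warning) rather than imputed.
* The enrichment sampler preserves per-segment GC class but not inter-segment
  spacing; long-range clustering of CNVs is not modelled.
* `cluster_permutation_importance` permutes the *preprocessed training
  matrix*; importance on held-out data is not implemented (the OOB samples
  play that role, as in the underlying method).
* The published models' exact weights and headline AUCs are not reproducible
  without access-controlled data; this package validates the method by
  parameter recovery instead.
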