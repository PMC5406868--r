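---
title: "Cross-species microarray analysis with gDNA probe masking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species microarray analysis with gDNA probe masking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csmarray)
```

## The problem

When no expression array exists for a species, RNA can be hybridised to an
array designed for a close relative (cross-species hybridisation). Sequence
divergence makes some probes hybridise poorly, which depresses and distorts
the summarized expression values. The remedy implemented here is genomic-DNA
masking: genomic DNA of the target species is hybridised to the same array,
and only probe pairs whose gDNA intensity exceeds a threshold $\tau$ — direct
evidence that the probe matches the target genome — are retained in a
genotype-specific custom chip definition. All downstream summarization uses
only the retained probes.

The package implements the full analysis chain for a two-genotype
dehydration-stress design (water-sufficient, water-limited and recovery
treatments): masking, masked RMA-style summarization, expressed-gene calling
from the ranked-intensity curve, differential expression with a
responsive/perturbed classification against the recovery treatment, and
Spearman co-expression networks with transcription-factor degree ranking.
Because such studies often leave no public raw data, the package ships a
synthetic-data generator that emulates the design and is used for all
validation.

## Masking

`select_probe_pairs()` retains probe pair $j$ iff its gDNA intensity
$I_j > \tau$ (strict; ties at the threshold are excluded — the convention is
arbitrary but documented and fixed), and retains a probe set iff at least
`min_pairs_per_set` (default 1) of its pairs survive. With the default
minimum, a gene is lost only when *all* of its probes are lost, which is why
retained probe-set counts decline much more slowly with $\tau$ than
probe-pair counts: `sweep_thresholds()` tabulates exactly this. Threshold
units are linear-scale intensities on whatever scale the data are on;
absolute values are not transferable between scanners or to the synthetic
scale.

## Masked RMA summarization

`rma_summarize()` performs, over the retained probes only:

1. $\log_2$ transform;
2. quantile normalization across hybridisations — every column is mapped to
   the per-rank mean of the column-sorted values; ties within a column
   receive the mean of the reference values at their tied ranks;
3. per-probe-set median polish of the additive model
   $\log_2 I_{js} = \mu + \alpha_j + \beta_s + \varepsilon_{js}$, with the
   per-sample summary $\mu + \beta_s$.

Median polish uses Tukey's alternating median sweeps (rows first), stopping
when the total absolute residual changes by less than `polish_tolerance`
(relative, default 0.01) or after `max_polish_iterations` (default 10)
sweeps. It is exact on additive matrices and robust to isolated aberrant
cells; multiplicative probe affinities become additive probe effects
$\alpha_j$ after the log transform and cancel out of the summaries.

Two deliberate deviations from textbook RMA:

* **No convolution background correction.** The normal-plus-exponential
  deconvolution step is omitted; the synthetic generator has no optical
  background component, and the masking step already removes the dominant
  background contamination (non-binding probes). `background_correct()` is a
  no-op hook where a model could be inserted.
* **Normalize-after-mask.** Quantile normalization is computed over retained
  probes only, mirroring summarization from a custom chip definition. The
  alternative (normalize the full array, then mask) is available by
  summarizing with a full mask first.

Note that quantile normalization forces identical column distributions, so
it necessarily perturbs planted fold changes by a small amount; exactness
checks in the test-suite therefore run with `normalize = FALSE`, which
`summarization_config()` exposes.

## Expressed-gene calling

`relative_expression()` rescales per-set mean expression so that 1.0 is the
array average. Sorted in descending order the values form a roughly
sigmoidal curve; `find_inflection()` smooths it with a centred moving
average (window 51) and returns the interior rank at which the absolute
first difference is smallest — the end of the high-expression plateau. The
"point of inflection" language used for such curves is internally
inconsistent (a sigmoid's inflection is its *steepest* point); the
shallowest-gradient reading is taken as authoritative since it is the one
that separates the expressed plateau from the descent into background.
Exact gradient ties break to the smallest rank, i.e. the more stringent
cutoff. The search is confined to the interior 10–90% of ranks to avoid the
noisy curve ends, and both the window and the band are configurable.

Two caveats. First, the cutoff is data-derived, not universal; a fixed
historical cutoff (such as 0.97 relative units) can be supplied via
`override_cutoff`. Second, the synthetic generator draws all baselines from
one log-normal population — it has no separate unexpressed population — so
on synthetic data the shallowest gradient sits near mid-curve rather than at
a two-thirds plateau end; passing tests demonstrate the estimator's
correctness against a brute-force scan, not the biological shape of a real
ranked curve. The ranked curve is computed per genotype from the
water-sufficient samples, the state of the transcriptome before any
treatment.

## Differential expression and classification

`call_degs()` tests each probe set with a two-sided Welch (unequal-variance)
t-test — the pooled-variance variant is a flag — adjusts p-values with
Benjamini–Hochberg step-up FDR over all probe sets of the contrast, and
calls a DEG when $q \le 0.05$ **and** fold change $> 2$ (strict, on
$2^{|\Delta \log_2|}$). When both groups have zero variance the test is
degenerate: equal means give $p = 1$; different means give $p = 0$ with a
flag, so noise-free data remain analysable. BH is applied per contrast, not
over the union of contrasts.

Stress DEGs are classified by `classify_response()`: a DEG is
dehydration-*responsive* when the recovery-vs-water-sufficient contrast is
non-significant for it (expression returned to the control level after
re-watering), else dehydration-*perturbed* (a persistent state change).
Non-significance is weak evidence of return — with three recovery
replicates the recovery contrast has modest power, so borderline perturbed
genes tend to be absorbed into the responsive class, biasing the recovered
responsive fraction upward of the planted value. The alternative reading
(significance of the water-limited-vs-recovery contrast as evidence of
return) is available as `rule = "stress_vs_recovery"`.

PCA (`pca_variance()`) centres each probe set and reports per-component
variance fractions and sample scores, the standard QC view; the
`delta_delta_ct()` helper implements the $2^{-\Delta\Delta C_t}$ relative
quantification used when validating array calls by qPCR.

## Co-expression networks

`spearman_matrix()` computes average-rank Spearman correlations across all
samples of a genotype; constant probe sets give undefined correlations,
which never become edges. `build_network()` links two DEG probe sets when
$|\rho| \ge 0.9$ by default. The threshold is interpreted on $|\rho|$ so
that anti-correlated stress-induced/stress-repressed pairs connect, which is
what a mixed up/down dehydration module looks like; `mode = "positive"`
restricts to positive correlation. The "whole" network of a genotype spans
the union of DEGs from its three pairwise treatment contrasts; the
"dehydration-specific" subnetwork is the induced subgraph on the
water-limited-vs-water-sufficient DEGs. Per-genotype dehydration networks
are merged with node provenance (`genotype_origin`: either genotype or
`both`; conflicting direction annotations are flagged, not dropped), and
`degree_table()` ranks transcription-factor nodes by degree in the whole and
dehydration-specific networks. Functional roles come from an annotation
table with a small controlled vocabulary (`role_categories()`); they are
supplied, never inferred.

## The synthetic generator

The generator plants every quantity the pipeline is later asked to recover:

* **Design**: two genotypes; 3 water-sufficient, 4 water-limited and 3
  recovery replicates each; 11 probe pairs per probe set.
* **Divergence** is Bernoulli probe dropout: each probe pair carries one
  shared uniform draw $u$ and binds genotype $g$ iff $u <$
  `bind_prob[g]` (default 0.9). Equal bind probabilities give identical
  binding patterns — the near-identical-genomes regime — while the masks
  still differ slightly through background draws that cross the threshold.
  A sequence-evolution model is deliberately out of scope: probe-level
  dropout is sufficient to exercise masking and reproduces the
  sets-decline-slower-than-pairs behaviour.
* **Intensities**: binding probes draw
  $a_j \cdot 2^{\mathcal N(\mu_{\text{sig}}, \sigma)}$ with multiplicative
  log-normal affinities $a_j$ (these motivate median polish); non-binding
  probes draw log-normal background. Defaults
  ($\mu_{\text{sig}} = 10$, $\mu_{\text{bg}} = 6$, $\sigma = 1$ on the
  $\log_2$ scale) are fixture choices on an arbitrary but internally
  consistent scale.
* **Differential expression**: 100 DE sets per genotype, 9 common to both
  (common sets share their direction), signed $\log_2$ fold changes drawn
  from $\pm U(1, 2)$ — mostly below 4-fold; exactly 75% of each genotype's
  DE sets are responsive (effect vanishes at recovery), 25% perturbed
  (effect retained in full at recovery; no attenuated intermediate is
  modelled).
* **Modules**: co-expression modules share a per-sample latent factor
  $\mathcal N(0, 1)$ added on the $\log_2$ scale; members are drawn from
  the DE sets of alternating genotypes (overflowing into non-DE sets), so
  the DEG-restricted networks contain recoverable dense subgraphs.
* **Noise**: probe-level $\log_2$ noise SD 0.25 by default; 0 gives exact
  planted values for fully binding probe sets, which the identity tests
  use.

Everything is deterministic given the seed; `run_all()` streams one
top-level seed to all stages, and planted counts are exact by construction,
not in expectation.

What the generator does **not** emulate: optical background and spatial
artefacts, batch effects, mismatch probes, an unexpressed gene population,
sequence-level divergence, and fold-change-dependent variance. Passing
recovery tests therefore validate the estimators and the pipeline plumbing
under the stated statistical model, not performance on real chips.

## Numerical choices and degenerate inputs

* Threshold comparison is strict `>`; masks built at increasing $\tau$ are
  nested.
* The default working threshold for synthetic data is $\tau = 2^8 = 256$,
  the geometric midpoint of the signal ($2^{10}$) and background ($2^6$)
  scales.
* Quantile normalization of a single column is a no-op with a warning.
* Median polish on a single-probe set returns that probe's values.
* Degenerate zero-variance tests are flagged rather than returning `NaN`.
* A constant expression matrix yields PCA fractions of 0 with a `constant`
  flag.
* TSV writers emit sorted rows and 17-significant-digit numerics, so output
  is byte-stable and round-trips exactly.

## Problem sizes

The validation suite runs the end-to-end design at 2,000 probe sets
(22,000 probe pairs, 20 hybridisations), the mask sweep at 10,000 sets,
DE/classification recovery at 2,000 sets with 100 planted DEGs, and module
recovery at 200 sets with five 10-set modules — sizes chosen so the full
suite completes in a few minutes on a single core while keeping every
recovery check comfortably powered. `scripts/acceptance.R` re-runs the same
computations from scratch at the same sizes.

## Known limitations

* Non-significance as "returned to baseline" inflates the responsive class;
  an equivalence test would be more rigorous.
* The fold-change gate is applied to the point estimate; no shrinkage or
  moderated variance is used (moderated tests are an explicit non-goal).
* The mask comparison across genotypes is on probe-set identifiers; no
  joint mask is constructed.
* GraphML/SIF export covers attributes, not layout; rendering is left to
  Cytoscape-class tools.
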