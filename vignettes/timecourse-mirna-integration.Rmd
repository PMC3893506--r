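---
title: "Integrating time-course mRNA and microRNA expression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating time-course mRNA and microRNA expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

After a treatment, transcriptional programs unfold over hours: some genes
rise steadily, others fall, and part of that regulation is post-
transcriptional, mediated by microRNAs that repress their target mRNAs.
Given (i) a short time course of gene expression log-ratios against a
time-0 control, (ii) a matched microRNA time course from the same samples,
and (iii) a table of computationally predicted miRNA–target relationships,
`tempomir` answers four questions in sequence:

1. Which genes follow a coherent temporal pattern, and is that pattern
   statistically surprising?
2. Which predicted miRNA–target pairs behave like genuine repressions,
   i.e. show significantly negative expression correlation?
3. Which biological pathways do the pattern genes — and separately the
   miRNA targets and non-targets among them — fall into, and which
   pathways shift coherently in activity?
4. Do co-expressed genes share promoter architecture (transcription-factor
   binding-site content), and which genes sit at the topological core of
   the affected pathways?

Because studies of this design frequently leave no public raw data, the
package ships a synthetic-data generator with planted ground truth, so
every stage is testable end to end and its operating characteristics
(FDR calibration, sensitivity, precision) are measurable.

# Data model

All expression is carried as log2 ratios versus the time-0 control, in a
features × time matrix (`expression_matrix`). The control column itself is
not stored: its ratio is identically zero. Wherever a method needs the
full trajectory — profile assignment and pair correlation — the implicit
baseline 0 is prepended, so a 6-point treatment grid (1, 2, 4, 8, 12,
24 h) yields 7-point trajectories anchored at (0, 0). The anchor is a real
measurement constraint (the control is compared with itself), and it
stabilizes correlations between short series.

Preprocessing from raw probe intensities follows the standard microarray
path: probes are kept when signal exceeds 1.4× the local background in at
least one sample (strictly; the rule is one-sample because a probe well
measured anywhere carries information), columns are quantile-normalized
(via `limma::normalizeQuantiles`, ties receiving the mean of tied-rank row
means), duplicated spots are averaged per feature, and ratios are taken
against the control column with a +1 intensity offset when zeros are
present. The design assumes pooled replicates — one column per time point —
so no replicate variance model is attempted.

# Temporal patterns

Candidate model profiles are integer shapes starting at level 0 with
per-step changes bounded by `c` (default 2), enumerated exhaustively —
`(2c+1)^(T-1)` shapes — and thinned to `m` (default 50) representatives by
a deterministic farthest-first greedy pass under the dissimilarity
`1 − cor(shape_i, shape_j)`, seeded with the first candidate in
enumeration order. These defaults are common practice for short
time-series profile analysis; they are not data-derived. Constant shapes
are excluded (they have no direction), except the flat profile when
`c = 0`.

Each gene changed beyond 2-fold (miRNAs: 1.5-fold) at some time point is
assigned to the profile maximizing Pearson correlation with its
trajectory; ties break to the lower profile id, and zero-variance
trajectories stay unassigned. Correlation makes assignment invariant to
positive affine transforms of a trajectory, which is the behavior one
wants when genes share shape but not amplitude.

Significance of a profile is a question about its membership count. In
each of 1000 permutation rounds every trajectory is independently
time-shuffled and re-assigned; the per-profile empirical p is
`(1 + #{rounds with permuted count ≥ observed}) / (1 + n_perm)`. That p is
floored at `1/(n_perm+1) ≈ 0.001`, so a Benjamini–Hochberg pass over 50
profiles can mathematically never reach an adjusted value below 0.025 when
only a few profiles are real — a resolution artifact, not evidence of
absence. The significance flag therefore uses a pooled-null p: the
observed count is compared against the permuted counts of *all* profiles
and rounds jointly (50 × 1000 draws), the same pooling device the
integration stage uses. Both columns (`p`, `p_pooled`) are reported; BH
runs on the pooled one, and the default cut is 0.001. Significant profiles
are labeled up- or down-patterns by the sign of the mean final log2 level
of their members.

# MicroRNA-target integration

This is the package's core statistic. The candidate universe mirrors the
workflow: predicted pairs among temporally changed features (the
restriction is a flag, `restrict_to_changed`; the false-discovery
calibration below runs with it off so the null check is not vacuous).
Pearson correlation is computed over the anchored trajectories and only
negative pairs are retained — repression predicts anti-correlation.

The null is built by shuffling each miRNA's time order independently in
each of 1000 rounds and recomputing all retained pair correlations. The
permuted coefficients are pooled across pairs and rounds into one null
sample: with ~50 pairs this gives p-value resolution near `1/(50 × 1000)`,
which an FDR cut of 0.01 needs — per-pair permutation p floored at 1/1001
could never clear Benjamini–Hochberg there. The per-pair one-sided p is
the pooled left-tail frequency of the observed r; BH runs across pairs and
pairs below 0.01 are selected. Pooling assumes the pairs' null
correlations are exchangeable; with trajectories of equal length and a
shared anchor that is a mild assumption, and the calibration test measures
its consequences directly (selected fraction on null data ≈ 0, well under
the nominal 0.01).

Shuffling the miRNA rather than the gene is an arbitrary choice of
permutation unit; under the null the two are distributionally equivalent,
and a property test checks the symmetry indirectly through calibration.

# Pathway statistics

Enrichment is Fisher's exact test (two-sided, computed by summing
hypergeometric probabilities at most as likely as the observed table) on
the 2×2 of list × pathway membership over the measured background — all
genes on the array, not the genome, because only measured genes could have
entered the list. BH adjusts across pathways. The up- and down-patterns
are tested separately, each also split into miRNA targets and non-targets,
which is the comparison that shows whether post-transcriptional regulation
concentrates in particular functions.

Pathway activity at a time point is the unweighted mean of member genes'
log2 ratios — a linear combination that accumulates many small coordinated
changes and is size-invariant. The test statistic is the maximum over time
of |activity|; its null resamples random gene sets of the same size from
the measured genes (a competitive null preserving the statistic's
size-dependent variance), 1000 rounds, BH across pathways, cut 0.01. A
pathway spanning the whole matrix gets p = 1 by construction: resampling
cannot change the set. Significant activity profiles are hierarchically
clustered (average linkage).

# Core nodes and promoter similarity

The directed graphs of the significant pathways are merged (node and edge
union, duplicate edges collapsed, self-loops dropped; edge types are
annotations only — the centrality uses topology, not weights). Relative
betweenness centrality — shortest-path betweenness with endpoints
excluded, fractional credit across equal-length paths, normalized by
`(n−1)(n−2)` — is computed with `igraph` and verified in the tests against
an exhaustive path-enumeration oracle. Nodes strictly above 0.01,
intersected with the selected miRNA targets, are the core
miRNA-regulated genes.

Promoters are the −2000..+500 window around the TSS in transcription
direction (0-based half-open arithmetic; BED input is native to that
convention), truncated at contig edges and reverse-complemented on the
minus strand. Position weight matrices come from count matrices with a
Laplace pseudocount of 1 on the probability scale; no log-odds background
model is applied because none is specified by the matcher convention being
emulated. A window matches when its score reaches
`min + f·(max − min)` with `f = 0.9`; the interpolated convention is the
default because it is well defined for any weight scale, and the
`f·max` alternative is available via a flag (`convention = "max"`, which
is also the convention of `Biostrings::matchPWM`, used as an independent
cross-check in the tests). Both strands are scanned by default — binding
sites function on either strand — and windows containing N are skipped.

Gene–gene similarity is the Jaccard index of binarized binding-site
presence: joint absence of a matrix says nothing about two promoters and
contributes nothing. A count-weighted variant (`sum(min)/sum(max)`) is
available but presence is the default — match counts at a 90% threshold
are noisy, presence is robust. Clustering on `1 − J` with average linkage
orders genes by promoter architecture.

# The synthetic generator

`synthetic_config()` defaults define the study conditions:

* 500 genes, 50 miRNAs, time grid {1, 2, 4, 8, 12, 24} h plus the
  implicit time-0 control — a 7-point course like the design emulated.
* 10% of genes planted up, 10% down, as a saturating ramp
  `effect · (1 − 2^(−t/4h))` (normalized to hit the peak exactly at 24 h);
  down-genes are mirrored. The two monotone classes match the pattern
  structure the analysis is meant to find, without inventing oscillations.
* Noise is i.i.d. Gaussian on log2 ratios, sd 0.3 (0.25 in the temporal
  benchmark) — the upper end of realistic array noise for pooled samples.
* 50 planted miRNA–target repressions: the miRNA profile is `−k` times
  the target's clean profile with `k ~ U(0.5, 1)`, plus noise; 20 decoy
  predictions per miRNA point at genes that are pure noise. Every true
  pair is present in the prediction table (recall 1 by construction), so
  measured sensitivity isolates the statistics from prediction coverage.
* The default peak effect is 3 log2 units (8-fold). This represents the
  strong-responder class that the integration stage actually consumes:
  genes passing a 2-fold-minimum filter in mitogen-response settings
  typically peak far above the threshold, and with 7 time points and
  noise on both series a 4-fold peak leaves true-pair correlations near
  −0.85, which no permutation test can separate from the null at
  FDR < 0.01 — the planted-recovery benchmark would measure an
  information-theoretic wall rather than the method. The temporal
  benchmark still runs at a 4-fold peak (effect 2), where assignment,
  unlike pair selection, has ample signal.
* Pathways are 20 disjoint sets of 20 genes; the first two are carved
  from the up- and down-genes and carry the planted activity shifts. Each
  pathway graph is a hub construction — half the members feed the hub,
  the hub feeds the other half, extra edges stay within a side — so the
  hub provably carries every cross-side shortest path and is the known
  central node.
* Promoters are uniform random DNA (2500 bp) on alternating strands; the
  up-group genes share the consensus of PWMs 1–3 inserted once each, the
  down-group shares PWMs 4–6. PWMs are synthetic count matrices with a
  dominant consensus base (12:1:1:1).
* One master seed drives everything through labeled sub-streams
  (`derive_seed`), so bundles are bit-reproducible and any stage can be
  re-run in isolation.

What the generator does *not* emulate: probe-level array artifacts,
spatial/dye effects, correlated gene–gene noise, miRNA seed-match
structure (predictions are declared, not computed), overlapping pathway
membership, and promoter base composition or repeat structure. Passing
tests therefore demonstrate that the statistics are implemented correctly
and calibrated under the stated noise model — not that real arrays would
yield the same operating characteristics.

# Numerical choices and degenerate inputs

* All fold thresholds are strict inequalities; log2 is used internally
  (fold 2 ↔ +1, fold 0.5 ↔ −1).
* Empirical p-values are `(1 + exceedances) / (1 + draws)` throughout, so
  they never reach 0 and are valid under the permutation null.
* Zero-variance trajectories are excluded from assignment and correlation
  with a report, not an error; empty candidate sets return empty results.
* Quantile-normalization ties: mean of tied ranks' row means.
* Fisher's test uses the conventional `(1 + 1e−7)` relative tolerance when
  comparing table probabilities, matching `stats::fisher.test`.
* Graphs with fewer than 3 nodes have zero betweenness by definition of
  the normalization; isolated nodes score 0.
* Sequences shorter than a PWM yield zero matches, not an error.
* Problem sizes in the shipped tests and acceptance script (500 genes ×
  50 miRNAs × 7 points, 1000 permutations, 20 null replicates, oracle
  sweeps to N = 30 and 100 random graphs/scans) were chosen so the full
  benchmark is reproducible on a laptop in minutes.

# Known limitations

* The pooled permutation null assumes exchangeability across pairs
  (and across profiles for the pattern flag); strong heteroscedasticity
  across features would distort it. Calibration on null data is the
  guard, and it is part of the test suite.
* With 7 time points the information ceiling is real: pairs whose true
  anti-correlation is weaker than roughly −0.9 cannot clear FDR < 0.01
  under any permutation scheme. Sensitivity claims are therefore specific
  to effect size and noise level.
* The activity statistic is unweighted; methods that weight member genes
  or standardize per gene would respond differently to pathways dominated
  by one large effect.
* Pattern labels (up/down) use the sign of the final time point's mean
  level; trajectories that return to baseline by the last time point
  would need a different labeling rule.
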