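# tempomir

Integrative analysis of short time-course mRNA and microRNA expression.

Treatments that reprogram a tissue — here the motivating setting is a
hepatoprotective herbal extract acting on primary hepatocytes over
1–24 h — produce temporally coherent gene-expression patterns, and part of
that regulation is post-transcriptional. `tempomir` is for computational
biologists who have a features × time matrix of log2 expression ratios for
genes and for microRNAs, plus a table of predicted miRNA→target
relationships, and want to know which predicted pairs behave like real
repressions and what biology they touch.

The workflow, each stage a documented function:

1. **Preprocess** — background filtering (signal > 1.4× local background),
   quantile normalization, duplicate-spot averaging, log2 ratios vs the
   time-0 control.
2. **Temporal patterns** — genes changed >2-fold (miRNAs >1.5-fold) at any
   time point are assigned to enumerated model profiles (integer shapes,
   per-step change ≤ c) by maximum Pearson correlation; profile membership
   counts are tested by a 1000-round permutation test with BH correction.
3. **miRNA-target integration** (the core statistic) — for every predicted
   pair, Pearson r over the anchored trajectories; pairs with r < 0 are
   tested against a null pooled over 1000 time-shufflings of all miRNA
   profiles:

       p_i = (1 + #{ r_null <= r_i }) / (1 + N_null),   BH across pairs,
       selected iff FDR < 0.01

4. **Pathways** — Fisher's exact enrichment (targets vs non-targets per
   pattern, BH-adjusted) and a pathway activity score (mean member log2
   ratio per time point) tested against random equal-size gene sets.
5. **Core nodes** — relative betweenness centrality on the merged directed
   graphs of significant pathways; nodes > 0.01 ∩ selected targets.
6. **Promoter TFBS** — PWM scanning of −2000..+500 promoter windows at a
   90% match-score fraction; genes clustered by Jaccard similarity of
   binding-site presence (joint absence carries no weight).

A synthetic-data generator (`generate_dataset` / `null_dataset`) plants
temporal responders, true miRNA-target repressions among decoy
predictions, active pathways with known hub nodes, and promoter motif
groups — so every stage's sensitivity, precision and FDR calibration are
measured in the test suite rather than assumed.

## Worked example

The `analysis/` directory holds the numbered drivers of the full study on
the default synthetic bundle (seed 1). Running them in order:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_temporal_patterns.R
Rscript analysis/03_integration.R
Rscript analysis/04_pathways.R
Rscript analysis/05_core_nodes.R
Rscript analysis/06_promoter_tfbs.R
```

prints, among other lines:

```
102 of 500 genes pass the 2-fold change filter
2 of 50 profiles significant; up-pattern 50 genes, down-pattern 50 genes
planted recovery: up 1.00, down 1.00
51 candidate anti-correlated pairs, 42 selected at FDR < 0.01 (42 target genes, 42 miRNAs)
planted-pair sensitivity 0.84, precision 1.00
up    all          n= 50  top pathway pw01 (p=1.77e-22, fdr=3.53e-21)
2 of 20 pathways with significant activity
40 nodes, 2 with centrality > 0.01, 1 of them selected miRNA targets
planted hubs of the significant pathways recovered: 2 of 2
mean Jaccard within patterns 0.564 vs between 0.051; 2-way split purity 1.00
```

Reading this: of 500 simulated genes, the 2-fold filter recovers the ~100
planted responders; permutation testing finds exactly the two planted
temporal patterns; the permutation FDR selects 42 predicted pairs, all of
them planted repressions (84% of the 50 planted pairs — pairs with weak
repression coupling k fall below the 7-time-point information limit); the
two planted active pathways, their hub genes, and the promoter motif
groups are all recovered. Stage tables land under `results/`.

The same end-to-end run is available as one call:

```r
library(tempomir)
bundle <- generate_dataset(synthetic_config(seed = 1))
report <- run_pipeline(bundle, pipeline_config(seed = 1), out_dir = "results/run")
report
```

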