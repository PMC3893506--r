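#!/usr/bin/env Rscript
# Pathway-level analysis: Fisher-exact enrichment (Benjamini-Hochberg
# adjusted) of the up- and down-pattern genes and of their miRNA-target /
# non-target partitions, plus the pathway activity statistic (mean member
# log2 ratio per time point) tested against 1000 random equal-size gene
# sets and clustered by activity similarity.

suppressMessages(library(tempomir))

seed <- 1L
bundle <- read_bundle("results/bundle")
patterns <- read.delim("results/temporal/pattern_genes.tsv")
integration <- read.delim("results/integration/integration.tsv")
class(integration) <- c("integration_result", "data.frame")
dir.create("results/pathways", recursive = TRUE, showWarnings = FALSE)

background <- rownames(bundle$gene_expr)
for (pat in c("up", "down")) {
  genes <- patterns$gene_id[patterns$pattern == pat]
  part <- partition_by_target_status(genes, integration)
  for (sub in c("all", "targets", "non_targets")) {
    lst <- switch(sub, all = genes, targets = part$targets,
                  non_targets = part$non_targets)
    res <- enrich(lst, background, bundle$pathways)
    f <- sprintf("results/pathways/enrichment_%s_%s.tsv", pat, sub)
    write.table(res, f, sep = "\t", quote = FALSE, row.names = FALSE)
    top <- res[order(res$p), ][1, ]
    if (nrow(res))
      cat(sprintf("%-5s %-12s n=%3d  top pathway %s (p=%.2e, fdr=%.2e)\n",
                  pat, sub, length(lst), top$pathway_id, top$p, top$fdr))
  }
}

act <- activity_significance(bundle$gene_expr, bundle$pathways,
                             n_perm = 1000L, fdr_cut = 0.01,
                             seed = derive_seed(seed, "stage-activity"))
cat(sprintf("%d of %d pathways with significant activity\n",
            sum(act$significant), nrow(act)))
write.table(act, "results/pathways/activity_stats.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
mat <- attr(act, "activity")
write.table(data.frame(pathway_id = rownames(mat), mat, check.names = FALSE),
            "results/pathways/activity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
if (sum(act$significant) >= 2) {
  cl <- hierarchical_cluster(mat[act$pathway_id[act$significant], ,
                                 drop = FALSE])
  writeLines(cluster_newick(cl), "results/pathways/activity_clusters.nwk")
}
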