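#!/usr/bin/env Rscript
# MicroRNA-target identification: correlate every predicted miRNA-target
# pair over the time course (candidates restricted to temporally changed
# genes and miRNAs, as the workflow prescribes), keep negative correlations,
# and select pairs by permutation FDR < 0.01 with a null pooled over 1000
# time-shuffling rounds of all miRNA profiles.

suppressMessages(library(tempomir))

seed <- 1L
bundle <- read_bundle("results/bundle")
dir.create("results/integration", recursive = TRUE, showWarnings = FALSE)

res <- integrate_expression(bundle$gene_expr, bundle$mirna_expr,
                            bundle$predictions, restrict_to_changed = TRUE,
                            n_perm = 1000L, fdr_cut = 0.01,
                            seed = derive_seed(seed, "stage-integration"))
cat(sprintf("%d candidate anti-correlated pairs, %d selected at FDR < 0.01 (%d target genes, %d miRNAs)\n",
            nrow(res), sum(res$selected),
            length(selected_targets(res)),
            length(unique(res$mirna_id[res$selected]))))

write.table(as.data.frame(res), "results/integration/integration.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
# bipartite edge list of the selected regulator-target network
write.table(res[res$selected, c("mirna_id", "gene_id", "r")],
            "results/integration/target_network.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- read.delim("results/bundle/truth_true_pairs.tsv")
sel <- res[res$selected, c("gene_id", "mirna_id")]
hit <- nrow(merge(sel, truth[, c("gene_id", "mirna_id")]))
cat(sprintf("planted-pair sensitivity %.2f, precision %.2f\n",
            hit / nrow(truth), hit / max(1, nrow(sel))))
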