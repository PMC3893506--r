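#!/usr/bin/env Rscript
# Promoter architecture of the co-expressed genes: extract the -2000/+500
# window around each pattern gene's TSS, scan with the PWM collection at a
# 90% match-score fraction, binarize to binding-site presence, and cluster
# genes by Jaccard similarity (joint absence carries no weight). With
# group-shared planted motifs the up- and down-pattern genes separate into
# distinct similarity clusters.

suppressMessages(library(tempomir))

bundle <- read_bundle("results/bundle")
patterns <- read.delim("results/temporal/pattern_genes.tsv")
dir.create("results/promoters", recursive = TRUE, showWarnings = FALSE)

tss <- bundle$tss[bundle$tss$name %in% patterns$gene_id, , drop = FALSE]
promoters <- extract_promoters(bundle$genome, tss)
cat(sprintf("scanning %d promoters with %d PWMs\n",
            length(promoters), length(bundle$pwms)))

counts <- tfbs_profile_matrix(promoters, bundle$pwms,
                              min_score_fraction = 0.9)
J <- jaccard_matrix(counts)
cl <- hierarchical_cluster(J, distance = as.dist(1 - J))

write.table(data.frame(gene_id = rownames(counts), counts,
                       check.names = FALSE),
            "results/promoters/tfbs_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(gene_id = rownames(J), J, check.names = FALSE),
            "results/promoters/tfbs_similarity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(cluster_newick(cl), "results/promoters/tfbs_clusters.nwk")

up <- intersect(patterns$gene_id[patterns$pattern == "up"], rownames(J))
dn <- intersect(patterns$gene_id[patterns$pattern == "down"], rownames(J))
within <- mean(c(J[up, up][upper.tri(J[up, up])],
                 J[dn, dn][upper.tri(J[dn, dn])]))
between <- mean(J[up, dn])
split2 <- cutree(cl$hclust, k = 2)
purity <- mean(c(split2[up] == names(which.max(table(split2[up]))),
                 split2[dn] == names(which.max(table(split2[dn])))))
cat(sprintf("mean Jaccard within patterns %.3f vs between %.3f; 2-way split purity %.2f\n",
            within, between, purity))
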