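#!/usr/bin/env Rscript
# Temporal-pattern detection: select genes changed beyond 2-fold (either
# direction) at any time point, assign them to model temporal profiles by
# maximum Pearson correlation, and test profile-membership counts with a
# 1000-round permutation test. Significant profiles are labeled as the
# temporal up- and down-patterns by the sign of their members' final level.

suppressMessages(library(tempomir))

seed <- 1L
bundle <- read_bundle("results/bundle")
dir.create("results/temporal", recursive = TRUE, showWarnings = FALSE)

changed <- select_changed_features(bundle$gene_expr, up_fold = 2,
                                   down_fold = 0.5)
cat(sprintf("%d of %d genes pass the 2-fold change filter\n",
            length(changed), nrow(bundle$gene_expr)))

expr <- expression_matrix(unclass(bundle$gene_expr)[changed, , drop = FALSE])
pcfg <- profile_config(c = 2L, m = 50L, n_perm = 1000L, fdr_cut = 0.001,
                       seed = derive_seed(seed, "stage-patterns"))
profiles <- generate_model_profiles(ncol(expr) + 1L, pcfg)
asg <- assign_profiles(expr, profiles)
asg <- profile_significance(asg, expr, pcfg)
members <- pattern_members(asg, expr)

st <- asg$profile_stats
cat(sprintf("%d of %d profiles significant; up-pattern %d genes, down-pattern %d genes\n",
            sum(st$significant), nrow(st),
            length(members$up), length(members$down)))

write.table(asg$assignment, "results/temporal/assignment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(st, "results/temporal/profile_stats.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(gene_id = c(members$up, members$down),
                       pattern = rep(c("up", "down"),
                                     c(length(members$up),
                                       length(members$down)))),
            "results/temporal/pattern_genes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# how well the detected patterns recover the planted truth
truth <- read.delim("results/bundle/truth_temporal.tsv")
up_rec <- mean(truth$gene_id[truth$direction == "up"] %in% members$up)
dn_rec <- mean(truth$gene_id[truth$direction == "down"] %in% members$down)
cat(sprintf("planted recovery: up %.2f, down %.2f\n", up_rec, dn_rec))
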