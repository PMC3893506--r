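#!/usr/bin/env Rscript
# Core-gene selection: merge the directed graphs of the pathways with
# significant activity, compute relative betweenness centrality on the
# merged network, and intersect nodes above the 0.01 cut with the selected
# miRNA targets -- the network's core miRNA-regulated genes.

suppressMessages(library(tempomir))

bundle <- read_bundle("results/bundle")
act <- read.delim("results/pathways/activity_stats.tsv")
integration <- read.delim("results/integration/integration.tsv")
class(integration) <- c("integration_result", "data.frame")
dir.create("results/core_nodes", recursive = TRUE, showWarnings = FALSE)

sig_pw <- act$pathway_id[act$significant]
edges <- bundle$pathway_edges
edges <- edges[edges$pathway_id %in% sig_pw, , drop = FALSE]
cat(sprintf("merging %d significant pathways (%d edges)\n",
            length(sig_pw), nrow(edges)))

merged <- merge_graphs(split(edges, edges$pathway_id))
centrality <- relative_betweenness(merged)
targets <- selected_targets(integration)
core_all <- select_core_nodes(centrality, cut = 0.01)
core_targets <- select_core_nodes(centrality, cut = 0.01, targets = targets)
centrality$core <- centrality$node %in% core_all
centrality$core_mirna_target <- centrality$node %in% core_targets

cat(sprintf("%d nodes, %d with centrality > 0.01, %d of them selected miRNA targets\n",
            nrow(centrality), length(core_all), length(core_targets)))
truth <- read.delim("results/bundle/truth_central_nodes.tsv")
cat(sprintf("planted hubs of the significant pathways recovered: %d of %d\n",
            sum(truth$gene_id[truth$pathway_id %in% sig_pw] %in% core_all),
            sum(truth$pathway_id %in% sig_pw)))

write.table(centrality[order(-centrality$centrality), ],
            "results/core_nodes/centrality.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
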