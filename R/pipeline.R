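#' Pipeline configuration
#'
#' Collects every stage threshold and permutation count of the integrated
#' workflow, with the defaults the analysis uses throughout: gene change
#' folds 2 / 0.5, miRNA fold 1.5, temporal-pattern FDR 0.001, integration
#' FDR 0.01, activity FDR 0.01, centrality cut 0.01, PWM match fraction
#' 0.9, 1000 permutations per randomized stage.
#'
#' @param up_fold,down_fold,mirna_fold Temporal-change fold thresholds.
#' @param pattern_fdr,integration_fdr,activity_fdr FDR cuts per stage.
#' @param centrality_cut Relative betweenness cut for core nodes.
#' @param pwm_fraction Minimum PWM match-score fraction.
#' @param n_perm Permutation rounds used by every permutation test.
#' @param profile_c,profile_m Model-profile parameters.
#' @param seed Master seed; all stage streams derive from it.
#' @return A list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(up_fold = 2, down_fold = 0.5, mirna_fold = 1.5,
                            pattern_fdr = 0.001, integration_fdr = 0.01,
                            activity_fdr = 0.01, centrality_cut = 0.01,
                            pwm_fraction = 0.9, n_perm = 1000L,
                            profile_c = 2L, profile_m = 50L, seed = 1L) {
  if (!(up_fold > 1 && down_fold < 1 && down_fold > 0 && mirna_fold > 1))
    abort_input("fold thresholds out of range")
  for (f in c("pattern_fdr", "integration_fdr", "activity_fdr"))
    if (!(get(f) > 0 && get(f) < 1)) abort_input(f, " must be in (0, 1)")
  stopifnot_scalar_number(centrality_cut, "centrality_cut", min = 0)
  if (!(pwm_fraction > 0 && pwm_fraction <= 1))
    abort_input("pwm_fraction must be in (0, 1]")
  stopifnot_scalar_number(n_perm, "n_perm", min = 1)
  structure(list(up_fold = up_fold, down_fold = down_fold,
                 mirna_fold = mirna_fold, pattern_fdr = pattern_fdr,
                 integration_fdr = integration_fdr,
                 activity_fdr = activity_fdr,
                 centrality_cut = centrality_cut,
                 pwm_fraction = pwm_fraction, n_perm = as.integer(n_perm),
                 profile_c = as.integer(profile_c),
                 profile_m = as.integer(profile_m),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Partition pattern genes by selected-target status
#'
#' Splits a set of temporal-pattern genes into microRNA targets (selected
#' by the integration stage) and non-targets -- the partition the pathway
#' comparison of target and non-target gene function uses. Selected targets
#' outside the pattern set are reported in the \code{"extra_targets"}
#' attribute.
#'
#' @param pattern_genes Character vector of pattern gene ids.
#' @param integration An \code{"integration_result"}.
#' @return List with character vectors \code{targets} and
#'   \code{non_targets} (a disjoint cover of \code{pattern_genes}).
#' @export
partition_by_target_status <- function(pattern_genes, integration) {
  sel <- selected_targets(integration)
  out <- list(targets = intersect(pattern_genes, sel),
              non_targets = setdiff(pattern_genes, sel))
  attr(out, "extra_targets") <- setdiff(sel, pattern_genes)
  out
}

#' Run the full integrative time-course workflow
#'
#' Executes, in order: temporal-pattern detection on the gene matrix;
#' permutation-FDR integration of predicted miRNA-target pairs (restricted
#' to temporally changed features); pathway enrichment of the up- and
#' down-pattern genes and of their target / non-target partitions; pathway
#' activity with permutation significance and hierarchical clustering of
#' significant activity profiles; core-node selection by relative
#' betweenness on the merged graphs of significant pathways; and promoter
#' TFBS profiling with Jaccard similarity clustering of the pattern genes.
#' Every randomized stage derives its stream from the single seed, so the
#' run is fully reproducible.
#'
#' @param bundle A \code{"synthetic_bundle"} or the list returned by
#'   \code{\link{read_bundle}}.
#' @param config A \code{\link{pipeline_config}}.
#' @param out_dir Optional directory; when given, every stage table is
#'   written there as TSV and a manifest with md5 sums is included.
#' @return A list of class \code{"run_report"} with stage results, record
#'   counts, the parameter echo and (when written) the file manifest.
#' @export
run_pipeline <- function(bundle, config = pipeline_config(),
                         out_dir = NULL) {
  for (need in c("gene_expr", "mirna_expr", "predictions", "pathways"))
    if (is.null(bundle[[need]])) abort_input("bundle is missing ", need)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  # 1. temporal patterns
  changed <- select_changed_features(bundle$gene_expr, config$up_fold,
                                     config$down_fold)
  expr_sel <- expression_matrix(
    unclass(bundle$gene_expr)[changed, , drop = FALSE])
  pcfg <- profile_config(c = config$profile_c, m = config$profile_m,
                         n_perm = config$n_perm, fdr_cut = config$pattern_fdr,
                         seed = derive_seed(config$seed, "stage-patterns"))
  profiles <- generate_model_profiles(ncol(expr_sel) + 1L, pcfg)
  assignment <- assign_profiles(expr_sel, profiles)
  assignment <- profile_significance(assignment, expr_sel, pcfg)
  patterns <- pattern_members(assignment, expr_sel)
  tick("temporal_patterns")

  # 2. miRNA-target integration (paper workflow: changed features only)
  integration <- integrate_expression(
    bundle$gene_expr, bundle$mirna_expr, bundle$predictions,
    restrict_to_changed = TRUE, up_fold = config$up_fold,
    down_fold = config$down_fold, mirna_fold = config$mirna_fold,
    n_perm = config$n_perm, fdr_cut = config$integration_fdr,
    seed = derive_seed(config$seed, "stage-integration"))
  tick("integration")

  # 3. enrichment: each pattern, split by target status
  background <- rownames(bundle$gene_expr)
  enrichment <- list()
  partitions <- list()
  for (pat in c("up", "down")) {
    genes <- patterns[[pat]]
    part <- partition_by_target_status(genes, integration)
    partitions[[pat]] <- part
    enrichment[[paste0(pat, "_all")]] <-
      enrich(genes, background, bundle$pathways)
    enrichment[[paste0(pat, "_targets")]] <-
      enrich(part$targets, background, bundle$pathways)
    enrichment[[paste0(pat, "_non_targets")]] <-
      enrich(part$non_targets, background, bundle$pathways)
  }
  tick("enrichment")

  # 4. pathway activity + clustering of significant activity profiles
  activity <- activity_significance(
    bundle$gene_expr, bundle$pathways, n_perm = config$n_perm,
    fdr_cut = config$activity_fdr,
    seed = derive_seed(config$seed, "stage-activity"))
  act_mat <- attr(activity, "activity")
  sig_pw <- activity$pathway_id[activity$significant]
  activity_clustering <- if (length(sig_pw) >= 2L)
    hierarchical_cluster(act_mat[sig_pw, , drop = FALSE]) else NULL
  tick("activity")

  # 5. core nodes on merged graphs of significant pathways
  edges <- bundle$pathway_edges
  core_edges <- if (length(sig_pw))
    edges[edges$pathway_id %in% sig_pw, , drop = FALSE] else edges
  merged <- merge_graphs(split(core_edges, core_edges$pathway_id))
  centrality <- relative_betweenness(merged)
  core <- select_core_nodes(centrality, cut = config$centrality_cut,
                            targets = selected_targets(integration))
  centrality$core <- centrality$node %in% core
  tick("core_nodes")

  # 6. promoter TFBS similarity of pattern genes
  pattern_genes <- unique(c(patterns$up, patterns$down))
  tfbs <- NULL; similarity <- NULL; tfbs_clustering <- NULL
  if (length(pattern_genes) >= 2L && length(bundle$pwms) &&
      !is.null(bundle$genome) && nrow(bundle$tss)) {
    tss <- bundle$tss[bundle$tss$name %in% pattern_genes, , drop = FALSE]
    promoters <- extract_promoters(bundle$genome, tss)
    tfbs <- tfbs_profile_matrix(promoters, bundle$pwms,
                                min_score_fraction = config$pwm_fraction)
    similarity <- jaccard_matrix(tfbs)
    tfbs_clustering <- hierarchical_cluster(
      similarity, distance = as.dist(1 - similarity))
  }
  tick("promoter_tfbs")

  report <- structure(list(
    patterns = patterns,
    assignment = assignment,
    integration = integration,
    partitions = partitions,
    enrichment = enrichment,
    activity = activity,
    activity_clustering = activity_clustering,
    centrality = centrality,
    core_nodes = core,
    tfbs_counts = tfbs,
    tfbs_similarity = similarity,
    tfbs_clustering = tfbs_clustering,
    counts = list(
      features = nrow(bundle$gene_expr), mirnas = nrow(bundle$mirna_expr),
      changed_genes = length(changed),
      up_pattern = length(patterns$up), down_pattern = length(patterns$down),
      candidate_pairs = nrow(integration),
      selected_pairs = sum(integration$selected),
      selected_targets = length(selected_targets(integration)),
      significant_pathways = length(sig_pw),
      core_nodes = length(core)),
    parameters = unclass(config), seed = config$seed,
    timings = timings), class = "run_report")

  if (!is.null(out_dir)) report$manifest <- write_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-20s %s\n", nm, x$counts[[nm]]))
  invisible(x)
}

# write stage tables + md5 manifest; timings are excluded so that two runs
# with one seed serialize identically
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  wt <- function(df, f) {
    write.table(df, fp(f), sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }
  files <- c(
    wt(report$assignment$assignment, "pattern_assignment.tsv"),
    wt(report$assignment$profile_stats, "profile_stats.tsv"),
    wt(data.frame(gene_id = c(report$patterns$up, report$patterns$down),
                  pattern = rep(c("up", "down"),
                                c(length(report$patterns$up),
                                  length(report$patterns$down)))),
       "pattern_genes.tsv"),
    wt(as.data.frame(report$integration), "integration.tsv"),
    wt(report$centrality, "centrality.tsv"))
  for (nm in names(report$enrichment))
    files <- c(files, wt(report$enrichment[[nm]],
                         sprintf("enrichment_%s.tsv", nm)))
  files <- c(files, wt(as.data.frame(report$activity), "activity_stats.tsv"))
  act <- attr(report$activity, "activity")
  files <- c(files, wt(data.frame(pathway_id = rownames(act), act,
                                  check.names = FALSE), "activity.tsv"))
  if (!is.null(report$activity_clustering)) {
    writeLines(cluster_newick(report$activity_clustering),
               fp("activity_clusters.nwk"))
    files <- c(files, "activity_clusters.nwk")
  }
  if (!is.null(report$tfbs_counts)) {
    files <- c(files,
               wt(data.frame(gene_id = rownames(report$tfbs_counts),
                             report$tfbs_counts, check.names = FALSE),
                  "tfbs_counts.tsv"),
               wt(data.frame(gene_id = rownames(report$tfbs_similarity),
                             report$tfbs_similarity, check.names = FALSE),
                  "tfbs_similarity.tsv"))
    if (!is.null(report$tfbs_clustering)) {
      writeLines(cluster_newick(report$tfbs_clustering),
                 fp("tfbs_clusters.nwk"))
      files <- c(files, "tfbs_clusters.nwk")
    }
  }
  counts_df <- data.frame(stage = names(report$counts),
                          count = unlist(report$counts))
  files <- c(files, wt(counts_df, "stage_counts.tsv"))
  # machine-readable twin of the report; timings excluded for determinism
  jsonlite::write_json(list(counts = report$counts,
                            parameters = report$parameters,
                            seed = report$seed),
                       fp("report.json"), auto_unbox = TRUE, digits = NA)
  files <- c(files, "report.json")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(vapply(files, fp,
                                                           character(1L)))),
                         stringsAsFactors = FALSE)
  write.table(manifest, fp("manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest
}
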