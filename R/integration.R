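#' Build or load a predicted miRNA-target map
#'
#' The prediction table is a two-column TSV (\code{mirna_id},
#' \code{gene_id}) with an optional third \code{score} column, in the style
#' of bulk downloads from target-prediction databases. Duplicate pairs are
#' dropped (first occurrence wins).
#'
#' @param pairs \code{data.frame} with columns \code{mirna_id},
#'   \code{gene_id} and optionally \code{score}.
#' @return A \code{data.frame} of class \code{"target_map"}.
#' @export
target_map <- function(pairs) {
  if (!all(c("mirna_id", "gene_id") %in% names(pairs)))
    abort_input("need columns mirna_id and gene_id")
  pairs$mirna_id <- as.character(pairs$mirna_id)
  pairs$gene_id <- as.character(pairs$gene_id)
  dup <- duplicated(pairs[c("mirna_id", "gene_id")])
  out <- pairs[!dup, intersect(c("mirna_id", "gene_id", "score"), names(pairs)),
               drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("target_map", "data.frame")
  out
}

#' @rdname target_map
#' @param path Path to the prediction TSV (header line required).
#' @export
load_target_predictions <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L)
    return(target_map(data.frame(mirna_id = character(),
                                 gene_id = character(),
                                 stringsAsFactors = FALSE)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n0 <- length(fields[[1L]])
  if (n0 < 2L) abort_input("line 1 of ", path, ": expected >= 2 columns")
  bad <- which(lengths(fields) != n0)
  if (length(bad))
    abort_input("line ", bad[1L] + 0L, " of ", path, ": expected ", n0,
                " tab-separated fields, found ", lengths(fields)[bad[1L]])
  header <- fields[[1L]]
  body <- fields[-1L]
  df <- data.frame(
    mirna_id = vapply(body, `[[`, "", 1L),
    gene_id = vapply(body, `[[`, "", 2L),
    stringsAsFactors = FALSE)
  if (n0 >= 3L) {
    sc <- suppressWarnings(as.numeric(vapply(body, `[[`, "", 3L)))
    df$score <- sc
  }
  names(df)[seq_len(min(3L, n0))] <-
    c("mirna_id", "gene_id", "score")[seq_len(min(3L, n0))]
  target_map(df)
}

#' Correlate predicted miRNA-target pairs over the time course
#'
#' Computes the Pearson correlation between each predicted miRNA's and
#' target gene's log2-ratio trajectories (the implicit time-0 baseline is
#' prepended to both) and keeps only pairs with a negative coefficient --
#' the sign a repressive interaction predicts. Pairs whose miRNA or gene is
#' not measured, or whose trajectory has zero variance, are skipped and
#' reported in the \code{"skipped"} attribute.
#'
#' @param gene_expr,mirna_expr \code{\link{expression_matrix}} objects
#'   sharing the same time labels (>= 3 time points).
#' @param predictions A \code{\link{target_map}}.
#' @param prepend_baseline Prepend the time-0 level to both trajectories
#'   (default TRUE).
#' @return \code{data.frame} with columns \code{gene_id}, \code{mirna_id},
#'   \code{r} for the retained (negatively correlated) pairs.
#' @export
correlate_pairs <- function(gene_expr, mirna_expr, predictions,
                            prepend_baseline = TRUE) {
  if (!identical(colnames(gene_expr), colnames(mirna_expr)))
    abort_input("gene and miRNA matrices must share the same time labels")
  G <- trajectory_matrix(gene_expr, prepend_baseline)
  M <- trajectory_matrix(mirna_expr, prepend_baseline)
  if (ncol(G) < 3L) abort_input("need at least 3 time points")
  pr <- predictions
  measured <- pr$gene_id %in% rownames(G) & pr$mirna_id %in% rownames(M)
  pr_m <- pr[measured, , drop = FALSE]
  Gs <- standardize_rows(G)[pr_m$gene_id, , drop = FALSE]
  Ms <- standardize_rows(M)[pr_m$mirna_id, , drop = FALSE]
  r <- rowSums(Gs * Ms) / (ncol(G) - 1L)
  zerovar <- is.na(r)
  out <- data.frame(gene_id = pr_m$gene_id, mirna_id = pr_m$mirna_id,
                    r = r, stringsAsFactors = FALSE)[!zerovar & r < 0, ,
                                                     drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- rbind(
    data.frame(gene_id = pr$gene_id[!measured],
               mirna_id = pr$mirna_id[!measured],
               reason = rep("unmeasured", sum(!measured)),
               stringsAsFactors = FALSE),
    data.frame(gene_id = pr_m$gene_id[zerovar],
               mirna_id = pr_m$mirna_id[zerovar],
               reason = rep("zero_variance", sum(zerovar)),
               stringsAsFactors = FALSE))
  out
}

#' Permutation-based FDR selection of anti-correlated pairs
#'
#' For each permutation round, every miRNA trajectory's time order is
#' independently shuffled and all pair correlations are recomputed; the
#' permuted coefficients are pooled across pairs and rounds into one null
#' sample, giving p-value resolution much finer than \code{1/(n_perm + 1)}.
#' The per-pair one-sided p (toward negative correlation) is
#' \code{(1 + null draws <= observed r) / (1 + total null draws)}, adjusted
#' across pairs by Benjamini-Hochberg; a pair is selected when its adjusted
#' value falls below \code{fdr_cut}.
#'
#' @param pairs Retained pairs from \code{\link{correlate_pairs}} on the
#'   same matrices.
#' @param gene_expr,mirna_expr The expression matrices the pairs came from.
#' @param n_perm Permutation rounds (default 1000).
#' @param fdr_cut Selection threshold on the adjusted value (default 0.01).
#' @param seed Integer seed.
#' @param prepend_baseline Must match the \code{correlate_pairs} call.
#' @return \code{data.frame} of class \code{"integration_result"} with
#'   columns \code{gene_id}, \code{mirna_id}, \code{r}, \code{p_perm},
#'   \code{fdr}, \code{selected}.
#' @export
permutation_fdr <- function(pairs, gene_expr, mirna_expr, n_perm = 1000L,
                            fdr_cut = 0.01, seed = 1L,
                            prepend_baseline = TRUE) {
  stopifnot_scalar_number(n_perm, "n_perm", min = 1)
  stopifnot_scalar_number(fdr_cut, "fdr_cut", min = 0, strict_min = TRUE)
  if (nrow(pairs) == 0L) {
    out <- data.frame(gene_id = character(), mirna_id = character(),
                      r = numeric(), p_perm = numeric(), fdr = numeric(),
                      selected = logical(), stringsAsFactors = FALSE)
    class(out) <- c("integration_result", "data.frame")
    return(out)
  }
  G <- trajectory_matrix(gene_expr, prepend_baseline)
  M <- trajectory_matrix(mirna_expr, prepend_baseline)
  T <- ncol(G)
  Gs <- standardize_rows(G)[pairs$gene_id, , drop = FALSE]
  mir_ids <- unique(pairs$mirna_id)
  Ms_u <- standardize_rows(M)[mir_ids, , drop = FALSE]
  mir_idx <- match(pairs$mirna_id, mir_ids)
  null_r <- matrix(NA_real_, nrow(pairs), n_perm)
  with_seed(derive_seed(seed, "integration-permutation"), {
    for (b in seq_len(n_perm)) {
      Mp <- t(apply(Ms_u, 1L, sample))
      null_r[, b] <- rowSums(Gs * Mp[mir_idx, , drop = FALSE]) / (T - 1L)
    }
  })
  null_sorted <- sort(as.vector(null_r))
  p <- (1 + findInterval(pairs$r, null_sorted)) / (1 + length(null_sorted))
  out <- data.frame(gene_id = pairs$gene_id, mirna_id = pairs$mirna_id,
                    r = pairs$r, p_perm = p,
                    fdr = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out$selected <- out$fdr < fdr_cut
  rownames(out) <- NULL
  class(out) <- c("integration_result", "data.frame")
  out
}

#' Full integration workflow: filter, correlate, select
#'
#' Mirrors the study workflow: optionally restrict the candidate universe
#' to temporally changed features (genes beyond \code{up_fold}/
#' \code{down_fold}, miRNAs beyond \code{mirna_fold} in either direction),
#' correlate every predicted pair, keep negative coefficients and apply the
#' permutation FDR.
#'
#' @inheritParams permutation_fdr
#' @param predictions A \code{\link{target_map}}.
#' @param restrict_to_changed Apply the temporal-change filters first
#'   (default TRUE).
#' @param up_fold,down_fold Gene fold thresholds (defaults 2, 0.5).
#' @param mirna_fold Symmetric miRNA fold threshold (default 1.5).
#' @return An \code{"integration_result"} (see \code{\link{permutation_fdr}}).
#' @export
integrate_expression <- function(gene_expr, mirna_expr, predictions,
                                 restrict_to_changed = TRUE,
                                 up_fold = 2, down_fold = 0.5,
                                 mirna_fold = 1.5,
                                 n_perm = 1000L, fdr_cut = 0.01, seed = 1L) {
  if (restrict_to_changed) {
    genes <- select_changed_features(gene_expr, up_fold, down_fold)
    mirnas <- select_changed_features(mirna_expr, mirna_fold, 1 / mirna_fold)
    gene_expr <- expression_matrix(unclass(gene_expr)[genes, , drop = FALSE])
    mirna_expr <- expression_matrix(unclass(mirna_expr)[mirnas, , drop = FALSE])
  }
  pairs <- correlate_pairs(gene_expr, mirna_expr, predictions)
  permutation_fdr(pairs, gene_expr, mirna_expr, n_perm = n_perm,
                  fdr_cut = fdr_cut, seed = seed)
}

#' Selected target genes of an integration result
#'
#' @param integration An \code{"integration_result"}.
#' @return Character vector of unique selected target gene ids.
#' @export
selected_targets <- function(integration) {
  unique(integration$gene_id[integration$selected])
}
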