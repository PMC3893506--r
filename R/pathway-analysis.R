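#' Read / write gene sets in GMT format
#'
#' @param path File path. Each GMT line is
#'   \code{pathway_id <TAB> description <TAB> gene1 <TAB> gene2 ...}.
#' @return \code{read_gmt} returns a named list of character vectors (a
#'   pathway set); the writer returns \code{path} invisibly.
#' @export
read_gmt <- function(path) {
  if (file.size(path) == 0L) return(setNames(list(), character()))
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param pathways Named list of character vectors.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(id) {
    paste(c(id, id, pathways[[id]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p-value obtained by summing, over the hypergeometric distribution
#' fixed at the observed margins, the probabilities of every table at most
#' as probable as the observed one (with the conventional tiny relative
#' tolerance for floating-point ties).
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!identical(dim(tab), c(2L, 2L)) || any(tab < 0) ||
      any(tab != round(tab)))
    abort_input("need a 2x2 table of nonnegative integer counts")
  if (sum(tab) == 0) abort_input("at least one margin must be positive")
  m <- sum(tab[1L, ])          # row-1 total (white balls)
  n <- sum(tab[2L, ])          # row-2 total
  k <- sum(tab[, 1L])          # column-1 total (draws)
  x <- tab[1L, 1L]
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(x, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Pathway enrichment of a gene list by Fisher's exact test
#'
#' For each pathway the 2x2 table (in list & in pathway, in list & out, out
#' of list & in pathway, neither) is formed over the measured background and
#' tested with \code{\link{fisher_exact_2x2}}; p-values are adjusted across
#' pathways by Benjamini-Hochberg. Pathways with no background gene are
#' excluded and reported in the \code{"excluded"} attribute.
#'
#' @param gene_list Character vector, a subset of \code{background}.
#' @param background All measured gene ids.
#' @param pathways Named list of gene-id vectors.
#' @param fdr_cut Flagging threshold on the adjusted value (default 0.05).
#' @return \code{data.frame} with \code{pathway_id}, \code{overlap},
#'   \code{pathway_size} (in background), \code{list_size}, \code{p},
#'   \code{fdr}, \code{significant}.
#' @export
enrich <- function(gene_list, background, pathways, fdr_cut = 0.05) {
  background <- unique(background)
  if (length(background) == 0L) abort_input("empty background")
  gene_list <- unique(gene_list)
  if (!all(gene_list %in% background))
    abort_input("gene_list must be a subset of background")
  in_bg <- lapply(pathways, intersect, background)
  excluded <- names(pathways)[lengths(in_bg) == 0L]
  keep <- lengths(in_bg) > 0L
  rows <- lapply(names(pathways)[keep], function(id) {
    pset <- in_bg[[id]]
    a <- length(intersect(gene_list, pset))
    b <- length(gene_list) - a
    c_ <- length(pset) - a
    d <- length(background) - a - b - c_
    data.frame(pathway_id = id, overlap = a, pathway_size = length(pset),
               list_size = length(gene_list),
               p = fisher_exact_2x2(matrix(c(a, c_, b, d), 2L, 2L)),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pathway_id = character(), overlap = integer(),
               pathway_size = integer(), list_size = integer(),
               p = numeric(), stringsAsFactors = FALSE)
  out$fdr <- p.adjust(out$p, method = "BH")
  out$significant <- out$fdr < fdr_cut
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Pathway activity profiles over time
#'
#' The activity of a pathway at a time point is the unweighted mean of its
#' measured members' log2 ratios -- a linear combination that accumulates
#' many small coordinated changes. Pathways with no measured member are
#' omitted and reported in the \code{"omitted"} attribute.
#'
#' @param expr An \code{\link{expression_matrix}} of log2 ratios.
#' @param pathways Named list of gene-id vectors.
#' @return A pathways x time numeric matrix of activities.
#' @export
pathway_activity <- function(expr, pathways) {
  vals <- unclass(expr)
  members <- lapply(pathways, intersect, rownames(vals))
  keep <- lengths(members) > 0L
  act <- t(vapply(members[keep], function(g) {
    colMeans(vals[g, , drop = FALSE])
  }, numeric(ncol(vals))))
  if (sum(keep) == 1L) {
    act <- matrix(act, nrow = 1L, dimnames = list(names(members)[keep],
                                                  colnames(vals)))
  }
  attr(act, "omitted") <- names(pathways)[!keep]
  act
}

#' Permutation significance of pathway activity
#'
#' The test statistic per pathway is the maximum over time of the absolute
#' activity. Its null is the same statistic on \code{n_perm} random gene
#' sets of equal size drawn from the measured genes (a competitive null
#' that preserves the statistic's size-dependent variance); the empirical p
#' is \code{(1 + null >= observed) / (1 + n_perm)}, Benjamini-Hochberg
#' adjusted across pathways and flagged below \code{fdr_cut}.
#'
#' @inheritParams pathway_activity
#' @param n_perm Permutation rounds (default 1000).
#' @param fdr_cut Selection threshold (default 0.01).
#' @param seed Integer seed.
#' @return \code{data.frame} with \code{pathway_id}, \code{stat}, \code{p},
#'   \code{fdr}, \code{significant}; the activity matrix is attached as the
#'   \code{"activity"} attribute.
#' @export
activity_significance <- function(expr, pathways, n_perm = 1000L,
                                  fdr_cut = 0.01, seed = 1L) {
  stopifnot_scalar_number(n_perm, "n_perm", min = 1)
  act <- pathway_activity(expr, pathways)
  vals <- unclass(expr)
  n_genes <- nrow(vals)
  obs <- apply(abs(act), 1L, max)
  sizes <- vapply(rownames(act), function(id)
    length(intersect(pathways[[id]], rownames(vals))), integer(1L))
  p <- setNames(numeric(length(obs)), names(obs))
  with_seed(derive_seed(seed, "activity-permutation"), {
    for (s in unique(sizes)) {
      which_s <- names(sizes)[sizes == s]
      if (s >= n_genes) {        # permutation cannot change the set
        p[which_s] <- 1
        next
      }
      null_stat <- vapply(seq_len(n_perm), function(b) {
        idx <- sample.int(n_genes, s)
        max(abs(colMeans(vals[idx, , drop = FALSE])))
      }, numeric(1L))
      for (id in which_s)
        p[id] <- (1 + sum(null_stat >= obs[id])) / (1 + n_perm)
    }
  })
  out <- data.frame(pathway_id = rownames(act), stat = unname(obs),
                    p = unname(p), fdr = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out$significant <- out$fdr < fdr_cut
  rownames(out) <- NULL
  attr(out, "activity") <- act
  out
}

#' Agglomerative hierarchical clustering of profile rows
#'
#' Thin deterministic wrapper around \code{stats::hclust}: Euclidean or
#' correlation (1 - r) distances, a chosen linkage, and a stable leaf
#' ordering.
#'
#' @param profile_matrix Numeric matrix, rows are the objects clustered.
#' @param linkage Linkage method (default \code{"average"}).
#' @param distance \code{"euclidean"}, \code{"correlation"}, or a
#'   precomputed \code{\link[stats]{dist}}.
#' @return A list with \code{merge}, \code{height}, \code{order},
#'   \code{labels} and the underlying \code{hclust} object.
#' @export
hierarchical_cluster <- function(profile_matrix, linkage = "average",
                                 distance = "euclidean") {
  if (inherits(distance, "dist")) {
    d <- distance
  } else {
    m <- as.matrix(profile_matrix)
    if (nrow(m) < 2L) abort_input("need at least 2 rows to cluster")
    d <- switch(distance,
                euclidean = dist(m),
                correlation = as.dist(1 - cor(t(m))),
                abort_input("unknown distance '", distance, "'"))
  }
  if (any(!is.finite(d))) abort_input("non-finite distances")
  hc <- hclust(d, method = linkage)
  list(merge = hc$merge, height = hc$height, order = hc$order,
       labels = hc$labels, hclust = hc)
}

#' Export a clustering as a Newick-like nested string
#'
#' @param cl Result of \code{\link{hierarchical_cluster}}.
#' @return A single Newick string (semicolon-terminated).
#' @export
cluster_newick <- function(cl) {
  hc <- cl$hclust
  lab <- hc$labels %||% as.character(seq_len(nrow(hc$merge) + 1L))
  node <- function(i) {
    if (i < 0) lab[-i]
    else sprintf("(%s,%s):%g", node(hc$merge[i, 1L]), node(hc$merge[i, 2L]),
                 hc$height[i])
  }
  paste0(sprintf("(%s,%s);", node(hc$merge[nrow(hc$merge), 1L]),
                 node(hc$merge[nrow(hc$merge), 2L])))
}
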