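#' Configuration for the synthetic time-course generator
#'
#' Describes a synthetic treatment experiment: genes and microRNAs are
#' profiled at a series of post-treatment times against an untreated time-0
#' control, a fraction of genes is planted with a saturating temporal
#' up- or down-response, a subset of predicted miRNA-target pairs is planted
#' as genuine repressions (the miRNA profile is the negated, scaled clean
#' target profile), and pathways, directed pathway graphs and promoter
#' sequences carry planted activity shifts, central hub nodes and shared
#' motif content respectively.
#'
#' Defaults emulate the study design the package targets: six sampling times
#' between 1 h and 24 h plus the implicit time-0 control, i.i.d. Gaussian
#' noise on log2 ratios, a peak planted effect of 3 log2 units (8-fold, the
#' strong-responder class the integration stage consumes), and a predicted
#' target table of one true target per miRNA plus 20 decoy predictions.
#'
#' @param n_genes,n_mirnas Feature counts.
#' @param time_points_h Strictly increasing positive sampling times (hours);
#'   the time-0 control is implicit.
#' @param frac_up,frac_down Fractions of genes planted as temporally
#'   up-/down-regulated; their sum must not exceed 1.
#' @param n_true_pairs Number of planted miRNA-target repressions; targets
#'   are drawn from the planted temporal genes.
#' @param decoys_per_mirna Predicted-but-unregulated targets per miRNA.
#' @param effect_log2 Peak log2 effect of planted temporal genes.
#' @param noise_sd Gaussian standard deviation added to every log2 ratio.
#' @param n_pathways,pathway_size Gene-set structure.
#' @param n_pwms,motif_len,promoter_len Promoter/motif structure (bases).
#' @param seed Integer master seed; every stream derives from it.
#' @return A validated list with class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(n_genes = 500L, n_mirnas = 50L,
                             time_points_h = c(1, 2, 4, 8, 12, 24),
                             frac_up = 0.1, frac_down = 0.1,
                             n_true_pairs = 50L, decoys_per_mirna = 20L,
                             effect_log2 = 3, noise_sd = 0.3,
                             n_pathways = 20L, pathway_size = 20L,
                             n_pwms = 30L, motif_len = 10L,
                             promoter_len = 2500L, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
              time_points_h = as.numeric(time_points_h),
              frac_up = frac_up, frac_down = frac_down,
              n_true_pairs = as.integer(n_true_pairs),
              decoys_per_mirna = as.integer(decoys_per_mirna),
              effect_log2 = effect_log2, noise_sd = noise_sd,
              n_pathways = as.integer(n_pathways),
              pathway_size = as.integer(pathway_size),
              n_pwms = as.integer(n_pwms), motif_len = as.integer(motif_len),
              promoter_len = as.integer(promoter_len), seed = as.integer(seed))
  for (f in c("n_genes", "n_mirnas", "n_true_pairs", "decoys_per_mirna",
              "n_pathways", "pathway_size", "n_pwms", "motif_len",
              "promoter_len"))
    stopifnot_scalar_number(cfg[[f]], f, min = 0)
  stopifnot_scalar_number(cfg$noise_sd, "noise_sd", min = 0)
  stopifnot_scalar_number(cfg$frac_up, "frac_up", min = 0)
  stopifnot_scalar_number(cfg$frac_down, "frac_down", min = 0)
  stopifnot_scalar_number(cfg$effect_log2, "effect_log2")
  if (cfg$frac_up + cfg$frac_down > 1)
    abort_input("frac_up + frac_down must be <= 1")
  tp <- cfg$time_points_h
  if (length(tp) < 1L || any(!is.finite(tp)) || any(tp <= 0) ||
      any(diff(tp) <= 0))
    abort_input("time_points_h must be strictly increasing and positive")
  stopifnot_scalar_number(cfg$seed, "seed")
  class(cfg) <- "synthetic_config"
  cfg
}

# clean saturating up-ramp over the treatment times, hitting `effect` exactly
# at the final time point (half-rise at t_half hours)
saturating_ramp <- function(time_points_h, effect, t_half = 4) {
  raw <- 1 - 2^(-time_points_h / t_half)
  effect * raw / raw[length(raw)]
}

time_labels_of <- function(cfg) paste0(format(cfg$time_points_h, trim = TRUE), "h")

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

pwm_consensus <- function(counts) {
  c("A", "C", "G", "T")[apply(counts, 2L, which.max)]
}

#' Generate a synthetic input bundle with known ground truth
#'
#' Produces every input the downstream workflow consumes -- gene and miRNA
#' log2-ratio matrices, a predicted-target table, pathway gene sets and
#' directed edge lists, a genome with TSS annotations and a PFM collection --
#' together with truth tables naming every planted temporal gene, true
#' miRNA-target pair, active pathway, central graph node and motif-sharing
#' promoter group. Deterministic for a fixed seed.
#'
#' Planted up-genes follow a saturating ramp reaching \code{effect_log2} at
#' the final time; down-genes are the mirror image. A planted pair's miRNA
#' profile is \code{-k} times the target's clean profile (k ~ U(0.5, 1))
#' before noise; decoy predictions point to genes with independent noise
#' profiles. Each pathway graph is built around a designated hub: half the
#' members feed into it and the other half are fed by it, so the hub is its
#' known central node.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @return A list of class \code{"synthetic_bundle"} with elements
#'   \code{gene_expr}, \code{mirna_expr}, \code{predictions},
#'   \code{pathways}, \code{pathway_edges}, \code{genome}, \code{tss},
#'   \code{pwms}, \code{truth} and \code{config}.
#' @seealso \code{\link{null_dataset}}, \code{\link{write_bundle}}
#' @export
generate_dataset <- function(config) {
  build_dataset(config, planted = TRUE)
}

#' Generate a structurally identical bundle with no planted effects
#'
#' Same shapes, formats and prediction-table structure as
#' \code{\link{generate_dataset}}, but every expression profile is pure
#' noise, no motifs are inserted, and all truth tables are empty. Used for
#' false-discovery calibration of the permutation machinery.
#'
#' @inheritParams generate_dataset
#' @return A \code{"synthetic_bundle"} whose truth tables have zero rows.
#' @export
null_dataset <- function(config) {
  build_dataset(config, planted = FALSE)
}

build_dataset <- function(config, planted) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, as.list(config))
  cfg <- config
  tl <- time_labels_of(cfg)
  tn <- length(tl)
  gene_ids <- if (cfg$n_genes) sprintf("g%04d", seq_len(cfg$n_genes)) else character()
  mirna_ids <- if (cfg$n_mirnas) sprintf("mir%03d", seq_len(cfg$n_mirnas)) else character()

  n_up <- if (planted) round(cfg$frac_up * cfg$n_genes) else 0L
  n_down <- if (planted) round(cfg$frac_down * cfg$n_genes) else 0L

  plant <- with_seed(derive_seed(cfg$seed, "plant-layout"), {
    temporal <- sample(gene_ids, n_up + n_down)
    list(up = temporal[seq_len(n_up)],
         down = temporal[n_up + seq_len(n_down)])
  })
  null_genes <- setdiff(gene_ids, c(plant$up, plant$down))

  ramp <- saturating_ramp(cfg$time_points_h, cfg$effect_log2)

  gene_vals <- with_seed(derive_seed(cfg$seed, "gene-expression"), {
    m <- matrix(rnorm(cfg$n_genes * tn, 0, cfg$noise_sd),
                nrow = cfg$n_genes, ncol = tn,
                dimnames = list(gene_ids, tl))
    if (length(plant$up))
      m[plant$up, ] <- m[plant$up, ] + rep(ramp, each = length(plant$up))
    if (length(plant$down))
      m[plant$down, ] <- m[plant$down, ] - rep(ramp, each = length(plant$down))
    m
  })
  gene_expr <- expression_matrix(gene_vals, feature_ids = gene_ids,
                                 time_labels = tl)

  # planted pairs: targets drawn from temporal genes; each miRNA serves one
  # direction class so its single profile can repress all its targets
  n_pairs <- if (planted) cfg$n_true_pairs else 0L
  if (n_pairs > n_up + n_down)
    abort_input("n_true_pairs exceeds the number of planted temporal genes")
  if (n_pairs > 0L && cfg$n_mirnas == 0L)
    abort_input("n_true_pairs requires n_mirnas > 0")
  pair_info <- with_seed(derive_seed(cfg$seed, "true-pairs"), {
    targets <- sample(c(plant$up, plant$down), n_pairs)
    dir <- ifelse(targets %in% plant$up, "up", "down")
    n_mir_up <- if (n_pairs) max(length(unique(targets[dir == "up"])) > 0,
                                 round(cfg$n_mirnas * mean(dir == "up"))) else 0L
    n_mir_up <- min(n_mir_up, cfg$n_mirnas - (any(dir == "down")))
    mir_up <- mirna_ids[seq_len(n_mir_up)]
    mir_down <- setdiff(mirna_ids, mir_up)
    assign_cls <- function(tg, pool) {
      if (!length(tg)) return(character())
      pool[(seq_along(tg) - 1L) %% length(pool) + 1L]
    }
    mirna <- character(n_pairs)
    mirna[dir == "up"] <- assign_cls(targets[dir == "up"], mir_up)
    mirna[dir == "down"] <- assign_cls(targets[dir == "down"], mir_down)
    k_mir <- setNames(runif(cfg$n_mirnas, 0.5, 1), mirna_ids)
    data.frame(mirna_id = mirna, gene_id = targets, direction = dir,
               k = unname(k_mir[mirna]), stringsAsFactors = FALSE)
  })

  mirna_vals <- with_seed(derive_seed(cfg$seed, "mirna-expression"), {
    m <- matrix(rnorm(cfg$n_mirnas * tn, 0, cfg$noise_sd),
                nrow = cfg$n_mirnas, ncol = tn,
                dimnames = list(mirna_ids, tl))
    if (nrow(pair_info)) {
      per_mir <- pair_info[!duplicated(pair_info$mirna_id), ]
      for (i in seq_len(nrow(per_mir))) {
        sgn <- if (per_mir$direction[i] == "up") 1 else -1
        m[per_mir$mirna_id[i], ] <-
          m[per_mir$mirna_id[i], ] - per_mir$k[i] * sgn * ramp
      }
    }
    m
  })
  mirna_expr <- expression_matrix(mirna_vals, feature_ids = mirna_ids,
                                  time_labels = tl)

  predictions <- with_seed(derive_seed(cfg$seed, "decoys"), {
    rows <- list(pair_info[, c("mirna_id", "gene_id")])
    pool <- if (length(null_genes)) null_genes else gene_ids
    nd <- min(cfg$decoys_per_mirna, length(pool))
    for (mid in mirna_ids) {
      if (nd > 0L)
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = mid, gene_id = sample(pool, nd),
          stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out <- out[!duplicated(out[c("mirna_id", "gene_id")]), , drop = FALSE]
    rownames(out) <- NULL
    target_map(out)
  })

  # pathways: the first two (when planted) are carved from the up/down genes
  # and carry the activity shift; the rest are drawn from the null pool
  pw <- with_seed(derive_seed(cfg$seed, "pathways"), {
    ids <- if (cfg$n_pathways) sprintf("pw%02d", seq_len(cfg$n_pathways)) else character()
    sets <- list(); active <- character(); act_dir <- character()
    take <- function(pool, n) sample(pool, min(n, length(pool)))
    remaining <- if (length(null_genes)) null_genes else gene_ids
    for (i in seq_along(ids)) {
      if (planted && i == 1L && length(plant$up)) {
        sets[[ids[i]]] <- take(plant$up, cfg$pathway_size)
        active <- c(active, ids[i]); act_dir <- c(act_dir, "up")
      } else if (planted && i == 2L && length(plant$down)) {
        sets[[ids[i]]] <- take(plant$down, cfg$pathway_size)
        active <- c(active, ids[i]); act_dir <- c(act_dir, "down")
      } else {
        if (length(remaining) >= cfg$pathway_size) {
          sets[[ids[i]]] <- take(remaining, cfg$pathway_size)
          remaining <- setdiff(remaining, sets[[ids[i]]])
        } else if (length(gene_ids)) {
          sets[[ids[i]]] <- take(gene_ids, cfg$pathway_size)
        } else sets[[ids[i]]] <- character()
      }
    }
    sets <- Filter(length, sets)
    list(sets = sets, active = active, act_dir = act_dir)
  })

  edges_central <- with_seed(derive_seed(cfg$seed, "pathway-graphs"), {
    edges <- list(); centers <- list()
    for (pid in names(pw$sets)) {
      memb <- pw$sets[[pid]]
      if (length(memb) < 3L) next
      hub <- memb[1L]
      rest <- memb[-1L]
      half <- length(rest) %/% 2L
      into <- rest[seq_len(half)]
      outof <- rest[-seq_len(half)]
      e <- rbind(
        data.frame(pathway_id = pid, source = into, target = hub,
                   edge_type = "activation", stringsAsFactors = FALSE),
        data.frame(pathway_id = pid, source = hub, target = outof,
                   edge_type = "activation", stringsAsFactors = FALSE))
      # sparse extra wiring on one side only, so the hub keeps every
      # cross-side shortest path
      add_side <- function(side) {
        if (length(side) < 2L) return(NULL)
        n_extra <- max(1L, length(side) %/% 4L)
        src <- sample(side, n_extra, replace = TRUE)
        tgt <- sample(side, n_extra, replace = TRUE)
        keep <- src != tgt
        if (!any(keep)) return(NULL)
        data.frame(pathway_id = pid, source = src[keep], target = tgt[keep],
                   edge_type = "inhibition", stringsAsFactors = FALSE)
      }
      e <- rbind(e, add_side(into), add_side(outof))
      edges[[pid]] <- e
      centers[[pid]] <- data.frame(pathway_id = pid, gene_id = hub,
                                   stringsAsFactors = FALSE)
    }
    list(edges = if (length(edges)) do.call(rbind, edges) else
           data.frame(pathway_id = character(), source = character(),
                      target = character(), edge_type = character(),
                      stringsAsFactors = FALSE),
         centers = if (length(centers) && planted) do.call(rbind, centers) else
           data.frame(pathway_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE))
  })
  rownames(edges_central$edges) <- NULL
  rownames(edges_central$centers) <- NULL

  pwms <- with_seed(derive_seed(cfg$seed, "pwms"), {
    lapply(seq_len(cfg$n_pwms), function(i) {
      consensus <- sample(c("A", "C", "G", "T"), cfg$motif_len, replace = TRUE)
      counts <- matrix(1L, 4L, cfg$motif_len,
                       dimnames = list(c("A", "C", "G", "T"), NULL))
      counts[cbind(match(consensus, rownames(counts)),
                   seq_len(cfg$motif_len))] <- 12L
      pwm_from_counts(counts, pseudocount = 1, id = sprintf("M%03d", i))
    })
  })

  prom <- with_seed(derive_seed(cfg$seed, "promoters"), {
    upstream <- 2000L; downstream <- 500L
    contigs <- character(0); tss_rows <- list(); motif_rows <- list()
    group_pwms <- list(up = pwms[seq_len(min(3L, length(pwms)))],
                       down = if (length(pwms) > 3L)
                         pwms[3L + seq_len(min(3L, length(pwms) - 3L))] else list())
    for (i in seq_along(gene_ids)) {
      g <- gene_ids[i]
      seq_p <- random_dna(cfg$promoter_len)
      grp <- if (planted && g %in% plant$up) "up"
             else if (planted && g %in% plant$down) "down" else NA_character_
      if (!is.na(grp) && length(group_pwms[[grp]])) {
        for (pw_i in group_pwms[[grp]]) {
          cons <- paste(pwm_consensus(pw_i$counts), collapse = "")
          w <- nchar(cons)
          if (cfg$promoter_len >= w) {
            pos <- sample.int(cfg$promoter_len - w + 1L, 1L)
            substr(seq_p, pos, pos + w - 1L) <- cons
          }
        }
        motif_rows[[g]] <- data.frame(
          gene_id = g, group = grp,
          pwm_ids = paste(vapply(group_pwms[[grp]], `[[`, "", "id"),
                          collapse = ","),
          stringsAsFactors = FALSE)
      }
      strand <- if (i %% 2L) "+" else "-"
      chrom <- paste0("chr_", g)
      if (strand == "+") {
        contigs[chrom] <- seq_p
        tss0 <- max(0L, cfg$promoter_len - downstream)
      } else {
        contigs[chrom] <- revcomp_chr(seq_p)
        tss0 <- min(downstream - 1L, cfg$promoter_len - 1L)
      }
      tss_rows[[g]] <- data.frame(chrom = chrom, start = tss0,
                                  end = tss0 + 1L, name = g, score = 0L,
                                  strand = strand, stringsAsFactors = FALSE)
    }
    list(genome = contigs,
         tss = if (length(tss_rows)) do.call(rbind, tss_rows) else
           data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = integer(),
                      strand = character(), stringsAsFactors = FALSE),
         motif_groups = if (length(motif_rows)) do.call(rbind, motif_rows) else
           data.frame(gene_id = character(), group = character(),
                      pwm_ids = character(), stringsAsFactors = FALSE))
  })
  rownames(prom$tss) <- NULL
  rownames(prom$motif_groups) <- NULL

  truth <- list(
    temporal = data.frame(
      gene_id = c(plant$up, plant$down),
      direction = rep(c("up", "down"), c(length(plant$up), length(plant$down))),
      stringsAsFactors = FALSE),
    true_pairs = pair_info,
    active_pathways = data.frame(pathway_id = pw$active,
                                 direction = pw$act_dir,
                                 stringsAsFactors = FALSE),
    central_nodes = edges_central$centers,
    motif_groups = prom$motif_groups)

  structure(list(gene_expr = gene_expr, mirna_expr = mirna_expr,
                 predictions = predictions, pathways = pw$sets,
                 pathway_edges = edges_central$edges,
                 genome = prom$genome, tss = prom$tss, pwms = pwms,
                 truth = truth, config = cfg),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_bundle> %d genes, %d miRNAs, %d time points, ",
                     "%d predicted pairs, %d pathways, %d PWMs\n"),
              nrow(x$gene_expr), nrow(x$mirna_expr), ncol(x$gene_expr),
              nrow(x$predictions), length(x$pathways), length(x$pwms)))
  cat(sprintf("  planted: %d temporal genes, %d true pairs\n",
              nrow(x$truth$temporal), nrow(x$truth$true_pairs)))
  invisible(x)
}

#' Serialize a synthetic bundle to plain-text files
#'
#' Writes every artifact in the interchange format its consumer reads:
#' expression TSVs, a two-column prediction TSV, GMT gene sets, a directed
#' edge-list TSV, a genome FASTA with BED6 TSS records, JASPAR-style PFM
#' text and one TSV per truth table.
#'
#' @param bundle A \code{"synthetic_bundle"}.
#' @param directory Output directory (created if needed).
#' @return Invisibly, a manifest \code{data.frame} with columns \code{kind}
#'   and \code{file}.
#' @export
write_bundle <- function(bundle, directory) {
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    abort_input("cannot create directory ", directory)
  fp <- function(f) file.path(directory, f)
  manifest <- list()
  add <- function(kind, file) manifest[[length(manifest) + 1L]] <<-
    data.frame(kind = kind, file = file, stringsAsFactors = FALSE)

  write_expression_matrix(bundle$gene_expr, fp("gene_expr.tsv"))
  add("gene_expr", "gene_expr.tsv")
  write_expression_matrix(bundle$mirna_expr, fp("mirna_expr.tsv"))
  add("mirna_expr", "mirna_expr.tsv")

  write.table(as.data.frame(bundle$predictions), fp("predictions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  add("predictions", "predictions.tsv")

  write_gmt(bundle$pathways, fp("pathways.gmt"))
  add("pathways_gmt", "pathways.gmt")

  write.table(bundle$pathway_edges, fp("pathway_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  add("pathway_edges", "pathway_edges.tsv")

  genome <- Biostrings::DNAStringSet(
    if (length(bundle$genome)) bundle$genome else character())
  Biostrings::writeXStringSet(genome, fp("genome.fasta"))
  add("genome_fasta", "genome.fasta")

  write.table(bundle$tss, fp("tss.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  add("tss_bed", "tss.bed")

  write_pfms(bundle$pwms, fp("pwms.pfm"))
  add("pwms_pfm", "pwms.pfm")

  for (nm in names(bundle$truth)) {
    f <- sprintf("truth_%s.tsv", nm)
    write.table(bundle$truth[[nm]], fp(f), sep = "\t", quote = FALSE,
                row.names = FALSE)
    add(paste0("truth_", nm), f)
  }
  manifest <- do.call(rbind, manifest)
  invisible(manifest)
}

#' Read a bundle directory written by \code{\link{write_bundle}}
#'
#' @param directory Directory containing the bundle files.
#' @return A list with the re-read artifacts (expression matrices,
#'   predictions, pathways, edges, genome, TSS table, PWMs, truth tables).
#' @export
read_bundle <- function(directory) {
  fp <- function(f) file.path(directory, f)
  genome_set <- Biostrings::readDNAStringSet(fp("genome.fasta"))
  tss <- tryCatch(
    read.delim(fp("tss.bed"), header = FALSE,
               col.names = c("chrom", "start", "end", "name", "score",
                             "strand")),
    error = function(e) data.frame(chrom = character(), start = integer(),
                                   end = integer(), name = character(),
                                   score = integer(), strand = character()))
  truth <- lapply(c(temporal = "truth_temporal.tsv",
                    true_pairs = "truth_true_pairs.tsv",
                    active_pathways = "truth_active_pathways.tsv",
                    central_nodes = "truth_central_nodes.tsv",
                    motif_groups = "truth_motif_groups.tsv"),
                  function(f) read.delim(fp(f), colClasses = NA))
  list(gene_expr = read_expression_matrix(fp("gene_expr.tsv")),
       mirna_expr = read_expression_matrix(fp("mirna_expr.tsv")),
       predictions = load_target_predictions(fp("predictions.tsv")),
       pathways = read_gmt(fp("pathways.gmt")),
       pathway_edges = read_pathway_edges(fp("pathway_edges.tsv")),
       genome = setNames(as.character(genome_set), names(genome_set)),
       tss = tss,
       pwms = read_pfms(fp("pwms.pfm")),
       truth = truth)
}
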