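bed6 <- function(chrom, tss0, name, strand) {
  data.frame(chrom = chrom, start = tss0, end = tss0 + 1L, name = name,
             score = 0L, strand = strand, stringsAsFactors = FALSE)
}

test_that("promoter windows follow the -2000/+500 stranded arithmetic", {
  set.seed(44)
  contig <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                  collapse = "")
  genome <- c(chr1 = contig)
  # + strand, tss = 2000 -> [0, 2500), length 2500
  p <- extract_promoters(genome, bed6("chr1", 2000L, "g1", "+"))
  expect_equal(unname(Biostrings::width(p)), 2500L)
  expect_equal(as.character(p[[1]]), substr(contig, 1, 2500))
  # truncation at the contig start: tss = 100 -> length 600
  p2 <- extract_promoters(genome, bed6("chr1", 100L, "g2", "+"))
  expect_equal(unname(Biostrings::width(p2)), 600L)
  # - strand window [tss-499, tss+2001) reverse-complemented
  p3 <- extract_promoters(genome, bed6("chr1", 499L, "g3", "-"))
  expect_equal(as.character(p3[[1]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(contig, 1, 2500)))))
  expect_error(extract_promoters(genome, bed6("chrX", 10L, "g4", "+")),
               "chrX")
  expect_error(extract_promoters(genome, bed6("chr1", 10L, "g5", ".")),
               "strand")
})

test_that("minus-strand extraction mirrors the plus strand exactly", {
  # on a contig and its reverse complement, the two extractions agree
  set.seed(9)
  fwd <- paste(sample(c("A", "C", "G", "T"), 2600, replace = TRUE),
               collapse = "")
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fwd)))
  p_plus <- extract_promoters(c(c1 = fwd), bed6("c1", 2000L, "g", "+"))
  p_minus <- extract_promoters(c(c1 = rev),
                               bed6("c1", 2600L - 2001L, "g", "-"))
  expect_equal(as.character(p_plus[[1]]), as.character(p_minus[[1]]))
})

test_that("PWM construction normalizes counts with a pseudocount", {
  counts <- matrix(c(10, 0, 0, 0), 4, 1)
  pwm <- pwm_from_counts(counts, pseudocount = 0)
  expect_equal(unname(pwm$weights[, 1]), c(1, 0, 0, 0))
  pwm2 <- pwm_from_counts(matrix(5, 4, 3), pseudocount = 0)
  expect_true(all(pwm2$weights == 0.25))
  pwm3 <- pwm_from_counts(matrix(c(3, 1, 0, 0), 4, 1), pseudocount = 1)
  expect_equal(unname(pwm3$weights[, 1]), c(4, 2, 1, 1) / 8)
  expect_equal(pwm3$max_score, 0.5)
  expect_equal(pwm3$min_score, 0.125)
  expect_error(pwm_from_counts(matrix(1, 3, 2)), "4 x width")
  expect_error(pwm_from_counts(matrix(0, 4, 1), pseudocount = 0), "zero")
})

test_that("PFM text round-trips through writer and parser", {
  pwms <- list(pwm_from_counts(matrix(c(8, 1, 1, 0, 0, 10, 0, 0), 4, 2),
                               id = "M001"),
               pwm_from_counts(matrix(1:12, 4, 3), id = "M002"))
  f <- tempfile(fileext = ".pfm")
  write_pfms(pwms, f)
  back <- read_pfms(f)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$id, "M001")
  expect_equal(back[[2]]$counts, pwms[[2]]$counts, ignore_attr = TRUE)
  expect_equal(back[[1]]$weights, pwms[[1]]$weights, ignore_attr = TRUE)
})

test_that("PWM scanning counts matches per the documented conventions", {
  # width-1 matrix certain for A: "ACA" has 2 forward hits, none on the
  # reverse complement (TGT)
  pwmA <- pwm_from_counts(matrix(c(1, 0, 0, 0), 4, 1), pseudocount = 0)
  expect_equal(scan_pwm("ACA", pwmA)$count, 2L)
  expect_equal(scan_pwm("ACA", pwmA, both_strands = FALSE)$count, 2L)
  expect_equal(scan_pwm("TGT", pwmA, both_strands = FALSE)$count, 0L)
  # a uniform matrix scores every window at its (flat) maximum
  pwmU <- pwm_from_counts(matrix(1, 4, 2), pseudocount = 0)
  expect_equal(scan_pwm("ACGTAC", pwmU, min_score_fraction = 1,
                        both_strands = FALSE)$count, 5L)
  # windows containing N never match
  expect_equal(scan_pwm("NNN", pwmA)$count, 0L)
  expect_equal(scan_pwm("ANA", pwmA, both_strands = FALSE)$count, 2L)
  # sequences shorter than the width yield zero matches, not an error
  pwm3 <- pwm_from_counts(matrix(c(9, 0, 0, 0), 4, 3) + 0, pseudocount = 1)
  expect_equal(scan_pwm("AC", pwm3)$count, 0L)
  expect_error(scan_pwm("ACGT", pwmA, min_score_fraction = 0), "fraction")
})

test_that("scanning agrees with the brute-force window scorer", {
  set.seed(29)
  for (i in 1:40) {
    w <- sample(3:8, 1)
    counts <- matrix(rpois(4 * w, 3), 4, w)
    if (any(colSums(counts) == 0)) counts <- counts + 1
    pwm <- pwm_from_counts(counts, pseudocount = 1)
    n <- sample(30:80, 1)
    seq_chr <- paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
                            prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
                     collapse = "")
    fr <- sample(c(0.7, 0.8, 0.9), 1)
    conv <- sample(c("minmax", "max"), 1)
    expect_equal(scan_pwm(seq_chr, pwm, fr, TRUE, conv)$count,
                 oracle_scan_count(seq_chr, pwm, fr, TRUE, conv),
                 label = sprintf("case %d", i))
  }
})

test_that("scanning agrees with Biostrings matchPWM on clean sequences", {
  # independent cross-check under the max-score convention, single strand
  set.seed(51)
  for (i in 1:10) {
    counts <- matrix(rpois(4 * 6, 4) + 1, 4, 6,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    pwm <- pwm_from_counts(counts, pseudocount = 0)
    seq_chr <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                     collapse = "")
    mine <- scan_pwm(seq_chr, pwm, 0.8, both_strands = FALSE,
                     convention = "max")$count
    ref <- length(Biostrings::matchPWM(pwm$weights,
                                       Biostrings::DNAString(seq_chr),
                                       min.score = "80%"))
    expect_equal(mine, ref)
  }
})

test_that("profile matrix is consistent with individual scans", {
  b <- generate_dataset(tiny_config())
  proms <- extract_promoters(b$genome, b$tss[1:6, ])
  pwms <- b$pwms[1:3]
  tf <- tfbs_profile_matrix(proms, pwms)
  expect_equal(dim(tf), c(6L, 3L))
  for (i in c(1L, 4L)) for (j in c(1L, 3L))
    expect_equal(tf[i, j], scan_pwm(proms[[i]], pwms[[j]])$count)
  expect_equal(ncol(tfbs_profile_matrix(proms, list())), 0L)
  dup <- c(proms, proms[1])
  names(dup) <- c(names(proms), names(proms)[1])
  expect_error(tfbs_profile_matrix(dup, pwms), "unique")
})

test_that("planted motifs are detected in their promoters", {
  b <- generate_dataset(tiny_config())
  mg <- b$truth$motif_groups
  up_gene <- mg$gene_id[mg$group == "up"][1]
  planted_pwm <- strsplit(mg$pwm_ids[mg$gene_id == up_gene], ",")[[1]][1]
  prom <- extract_promoters(b$genome, b$tss[b$tss$name == up_gene, ])
  pwm <- b$pwms[[which(vapply(b$pwms, `[[`, "", "id") == planted_pwm)]]
  expect_gte(scan_pwm(prom[[1]], pwm, 0.9)$count, 1L)
})

test_that("Jaccard similarity ignores joint absence", {
  prof <- rbind(g1 = c(2, 1, 1, 0), g2 = c(1, 0, 0, 0),
                g3 = c(2, 1, 1, 0), g4 = c(0, 0, 0, 0))
  J <- jaccard_matrix(prof)
  expect_equal(unname(J["g1", "g2"]), 1 / 3)
  expect_equal(unname(J["g1", "g3"]), 1)      # identical presence sets
  expect_equal(unname(J["g4", "g1"]), 0)      # empty profile
  expect_equal(unname(diag(J)), rep(1, 4))    # including the empty one
  expect_equal(J, t(J))
  # appending an everywhere-absent matrix changes nothing
  J2 <- jaccard_matrix(cbind(prof, extra = 0))
  expect_equal(J2, J)
  expect_true(all(J >= 0 & J <= 1))
  # count-weighted variant: min/max sums
  Jw <- jaccard_matrix(prof, weighted = TRUE)
  expect_equal(unname(Jw["g1", "g2"]), 1 / 4)
})

test_that("shared planted motifs separate co-expression groups", {
  # two groups of promoters, three planted motifs each; at zero sequence
  # noise between insertions the within-group similarity dominates and
  # average-linkage clustering splits the groups at the top
  b <- generate_dataset(synthetic_config(n_genes = 24L, n_mirnas = 2L,
                                         frac_up = 0.5, frac_down = 0.5,
                                         n_true_pairs = 0L,
                                         decoys_per_mirna = 1L,
                                         n_pathways = 2L, pathway_size = 5L,
                                         n_pwms = 6L, motif_len = 10L,
                                         promoter_len = 600L, seed = 13L))
  proms <- extract_promoters(b$genome, b$tss)
  tf <- tfbs_profile_matrix(proms, b$pwms, min_score_fraction = 0.95)
  J <- jaccard_matrix(tf)
  mg <- b$truth$motif_groups
  up <- mg$gene_id[mg$group == "up"]; dn <- mg$gene_id[mg$group == "down"]
  within <- mean(c(J[up, up][upper.tri(J[up, up])],
                   J[dn, dn][upper.tri(J[dn, dn])]))
  between <- mean(J[up, dn])
  expect_gt(within, between)
  cl <- hierarchical_cluster(J, distance = as.dist(1 - J))
  top_split <- cutree(cl$hclust, k = 2)
  expect_equal(length(unique(top_split[up])), 1L)
  expect_equal(length(unique(top_split[dn])), 1L)
  expect_false(top_split[up][1] == top_split[dn][1])
})
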