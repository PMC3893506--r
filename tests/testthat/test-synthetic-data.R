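test_that("config validation names the offending field", {
  expect_error(synthetic_config(frac_up = 0.7, frac_down = 0.5), "frac_up")
  expect_error(synthetic_config(noise_sd = -1), "noise_sd")
  expect_error(synthetic_config(time_points_h = c(2, 1)), "time_points_h")
  expect_error(synthetic_config(n_genes = -5), "n_genes")
})

test_that("noise-free plants reproduce their templates exactly", {
  cfg <- synthetic_config(n_genes = 20L, n_mirnas = 4L, frac_up = 0.05,
                          frac_down = 0, n_true_pairs = 1L,
                          decoys_per_mirna = 2L, effect_log2 = 2,
                          noise_sd = 0, n_pathways = 2L, pathway_size = 4L,
                          n_pwms = 6L, promoter_len = 200L, seed = 3L)
  b <- generate_dataset(cfg)
  up <- b$truth$temporal$gene_id[b$truth$temporal$direction == "up"]
  expect_length(up, 1L)
  traj <- unclass(b$gene_expr)[up, ]
  expect_true(all(diff(traj) >= 0))
  expect_equal(max(traj), 2)
  # planted pair is an exact negation up to scale -> r = -1
  pair <- b$truth$true_pairs
  g <- unclass(b$gene_expr)[pair$gene_id, ]
  m <- unclass(b$mirna_expr)[pair$mirna_id, ]
  expect_equal(cor(g, m), -1)
  expect_equal(m, -pair$k * g, ignore_attr = TRUE)
})

test_that("equal seeds give byte-identical bundles, different seeds differ", {
  b1 <- generate_dataset(tiny_config())
  b2 <- generate_dataset(tiny_config())
  expect_identical(b1, b2)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_bundle(b1, d1); write_bundle(b2, d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  b3 <- generate_dataset(synthetic_config(n_genes = 40L, n_mirnas = 8L,
                                          frac_up = 0.2, frac_down = 0.2,
                                          n_true_pairs = 8L,
                                          decoys_per_mirna = 3L,
                                          n_pathways = 4L, pathway_size = 8L,
                                          n_pwms = 8L, motif_len = 8L,
                                          promoter_len = 400L, seed = 12L))
  expect_false(identical(unclass(b1$gene_expr), unclass(b3$gene_expr)))
})

test_that("every planted quantity is internally consistent", {
  b <- generate_dataset(tiny_config())
  pr <- as.data.frame(b$predictions)
  tp <- b$truth$true_pairs
  # prediction-table coverage: every true pair is predicted
  expect_equal(nrow(merge(tp[c("mirna_id", "gene_id")], pr)), nrow(tp))
  expect_true(all(tp$gene_id %in% rownames(b$gene_expr)))
  expect_true(all(tp$mirna_id %in% rownames(b$mirna_expr)))
  expect_true(all(b$truth$temporal$gene_id %in% rownames(b$gene_expr)))
  expect_true(all(unlist(b$pathways) %in% rownames(b$gene_expr)))
  expect_true(all(b$truth$central_nodes$gene_id %in% unlist(b$pathways)))
  # decoys point at genes without planted temporal structure
  decoys <- pr[!paste(pr$mirna_id, pr$gene_id) %in%
                 paste(tp$mirna_id, tp$gene_id), ]
  expect_false(any(decoys$gene_id %in% b$truth$temporal$gene_id))
})

test_that("null bundles carry no signal and empty truth", {
  b <- null_dataset(tiny_config())
  expect_true(all(vapply(b$truth, nrow, 1L) == 0L))
  b0 <- null_dataset(synthetic_config(n_genes = 10L, n_mirnas = 3L,
                                      noise_sd = 0, decoys_per_mirna = 2L,
                                      n_pwms = 4L, promoter_len = 100L,
                                      n_pathways = 2L, pathway_size = 3L,
                                      seed = 5L))
  expect_true(all(unclass(b0$gene_expr) == 0))
  expect_true(all(unclass(b0$mirna_expr) == 0))
})

test_that("null-bundle pair correlations match the independence oracle", {
  # Monte-carlo oracle (1e5 draws) for mean |r| of two length-7 series that
  # share an exact (0,0) anchor and are otherwise independent normal: 0.3626
  b <- null_dataset(synthetic_config(n_genes = 200L, n_mirnas = 40L,
                                     decoys_per_mirna = 25L, n_pwms = 0L,
                                     n_pathways = 0L, promoter_len = 50L,
                                     seed = 21L))
  G <- cbind(0, unclass(b$gene_expr))
  M <- cbind(0, unclass(b$mirna_expr))
  set.seed(77)
  gi <- sample(nrow(G), 1000L, replace = TRUE)
  mi <- sample(nrow(M), 1000L, replace = TRUE)
  rs <- vapply(seq_len(1000L), function(i) cor(G[gi[i], ], M[mi[i], ]),
               numeric(1))
  expect_equal(mean(abs(rs)), 0.3626, tolerance = 0.05 / 0.3626)
})

test_that("bundles round-trip losslessly through the plain-text formats", {
  b <- generate_dataset(tiny_config())
  d <- file.path(tempdir(), "rt")
  manifest <- write_bundle(b, d)
  expect_gte(nrow(manifest), 8L)
  expect_true(all(file.exists(file.path(d, manifest$file))))
  rb <- read_bundle(d)
  expect_equal(unclass(rb$gene_expr), unclass(b$gene_expr), tolerance = 1e-9)
  expect_equal(unclass(rb$mirna_expr), unclass(b$mirna_expr),
               tolerance = 1e-9)
  expect_equal(as.data.frame(rb$predictions), as.data.frame(b$predictions))
  expect_equal(rb$pathways[names(b$pathways)], b$pathways)
  expect_equal(rb$genome, b$genome)
  expect_equal(nrow(rb$pathway_edges), nrow(b$pathway_edges))
  expect_equal(vapply(rb$pwms, `[[`, "", "id"),
               vapply(b$pwms, `[[`, "", "id"))
  expect_equal(rb$pwms[[1]]$counts, b$pwms[[1]]$counts,
               ignore_attr = TRUE)
})

test_that("a degenerate empty bundle still writes valid files", {
  cfg <- synthetic_config(n_genes = 0L, n_mirnas = 0L, n_true_pairs = 0L,
                          decoys_per_mirna = 0L, n_pathways = 0L,
                          n_pwms = 0L, seed = 1L)
  b <- generate_dataset(cfg)
  d <- file.path(tempdir(), "empty")
  manifest <- write_bundle(b, d)
  expect_true(all(file.exists(file.path(d, manifest$file))))
  expect_equal(nrow(read.delim(file.path(d, "gene_expr.tsv"))), 0L)
})
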