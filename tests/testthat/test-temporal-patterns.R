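expr_of <- function(vals, ids = paste0("f", seq_len(nrow(vals)))) {
  expression_matrix(vals, feature_ids = ids,
                    time_labels = paste0("t", seq_len(ncol(vals))))
}

test_that("fold-change selection applies strict linear thresholds", {
  vals <- log2(rbind(c(1.1, 2.3, 1.8),   # above 2 once -> kept
                     c(0.45, 1.0, 1.0),  # below 0.5 once -> kept
                     c(1.0, 1.0, 1.0),   # flat -> dropped
                     c(2.0, 1.0, 1.0)))  # exactly 2 is not > 2
  sel <- select_changed_features(expr_of(vals))
  expect_setequal(sel, c("f1", "f2"))
  # the milder miRNA threshold
  mir <- log2(rbind(c(1.6, 1.0), c(1.3, 1.2)))
  expect_equal(select_changed_features(expr_of(mir), 1.5, 1 / 1.5), "f1")
  expect_error(select_changed_features(expr_of(vals), 0.5, 2), "up_fold")
})

test_that("profile enumeration matches the (2c+1)^(T-1) count", {
  pr <- generate_model_profiles(4L, profile_config(c = 1L, m = 1000L))
  expect_equal(pr$n_candidates, 27L)
  expect_equal(nrow(pr$shapes), 27L)      # selection vacuous when m is large
  expect_true(all(pr$shapes[, 1] == 0))
  expect_true(all(abs(pr$shapes[, -1] - pr$shapes[, -4]) <= 1))
  expect_warning(pr0 <- generate_model_profiles(5L, profile_config(c = 0L,
                                                                   m = 3L)),
                 "flat")
  expect_equal(unname(pr0$shapes), matrix(0L, 1, 5))
  expect_error(generate_model_profiles(1L), "2 time points")
})

test_that("greedy selection returns m mutually dissimilar profiles", {
  pr <- generate_model_profiles(7L, profile_config(c = 2L, m = 50L))
  expect_equal(nrow(pr$shapes), 50L)
  expect_equal(pr$n_candidates, 15625L)
  # no constant shapes and no duplicated shapes among the selected
  expect_true(all(apply(pr$shapes, 1, function(s) any(s != s[1]))))
  expect_equal(anyDuplicated(pr$shapes), 0L)
  # deterministic
  pr2 <- generate_model_profiles(7L, profile_config(c = 2L, m = 50L))
  expect_identical(pr$shapes, pr2$shapes)
})

test_that("assignment maximizes correlation with sensible edge handling", {
  pr <- generate_model_profiles(4L, profile_config(c = 1L, m = 1000L))
  shapes <- pr$shapes
  # a trajectory equal to a shape is assigned there with r = 1
  target <- shapes[10, ]
  vals <- rbind(target[-1], c(0, 0, 0), -target[-1])
  asg <- assign_profiles(expr_of(vals), pr)
  a <- asg$assignment
  expect_equal(a$r[a$feature_id == "f1"], 1)
  expect_equal(unname(shapes[a$profile_id[a$feature_id == "f1"], ]),
               unname(target))
  # constant trajectory is left unassigned
  expect_false("f2" %in% a$feature_id)
  # the negated trajectory lands on the negated shape (also enumerated)
  expect_equal(unname(shapes[a$profile_id[a$feature_id == "f3"], ]),
               unname(-target))
  expect_equal(sum(asg$profile_stats$count), nrow(a))
  expect_error(assign_profiles(expr_of(vals),
                               structure(list(shapes = shapes[0, ]),
                                         class = "model_profiles")),
               "empty")
})

test_that("assignment is invariant to positive affine transforms", {
  pr <- generate_model_profiles(5L, profile_config(c = 1L, m = 30L))
  set.seed(9)
  vals <- matrix(rnorm(40), 10, 4)
  a1 <- assign_profiles(expr_of(vals), pr)$assignment
  a2 <- assign_profiles(expr_of(vals * 3.7), pr)$assignment
  expect_equal(a1$profile_id, a2$profile_id)
  expect_equal(a1$r, a2$r, tolerance = 1e-12)
})

test_that("noise-free concentration attains the minimum permutation p", {
  pr <- generate_model_profiles(5L, profile_config(c = 1L, m = 30L))
  shape <- pr$shapes[which(apply(pr$shapes, 1, function(s)
    all(diff(s) >= 0) && s[5] > 0))[1], ]
  vals <- matrix(rep(shape[-1], each = 200), 200, 4)
  expr <- expr_of(vals)
  cfg <- profile_config(c = 1L, m = 30L, n_perm = 200L, fdr_cut = 0.01,
                        seed = 4L)
  asg <- profile_significance(assign_profiles(expr, pr), expr, cfg)
  st <- asg$profile_stats
  hit <- st[st$count == 200L, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$p, 1 / 201)
  expect_true(hit$significant)
  # profiles nobody joined have p = 1 and p in [1/(n+1), 1] throughout
  expect_true(all(st$p[st$count == 0] == 1))
  expect_true(all(st$p >= 1 / 201 & st$p <= 1))
})

test_that("null data yields calibrated per-profile permutation p", {
  pr <- generate_model_profiles(5L, profile_config(c = 1L, m = 30L))
  set.seed(31)
  ps <- unlist(lapply(1:8, function(i) {
    vals <- matrix(rnorm(50 * 4), 50, 4)
    expr <- expr_of(vals)
    cfg <- profile_config(c = 1L, m = 30L, n_perm = 100L, seed = i)
    profile_significance(assign_profiles(expr, pr), expr,
                         cfg)$profile_stats$p
  }))
  expect_equal(mean(ps < 0.05), 0.05, tolerance = 0.6)
  expect_false(any(ps < 1 / 101))
})

test_that("pattern labels follow the sign of the final level", {
  pr <- generate_model_profiles(4L, profile_config(c = 1L, m = 30L))
  up <- c(1, 2, 3); dn <- -up
  vals <- rbind(matrix(rep(up, each = 30), 30), matrix(rep(dn, each = 30), 30))
  expr <- expr_of(vals)
  cfg <- profile_config(c = 1L, m = 30L, n_perm = 100L, fdr_cut = 0.01,
                        seed = 2L)
  asg <- profile_significance(assign_profiles(expr, pr), expr, cfg)
  lab <- label_patterns(asg, expr)
  expect_setequal(lab$pattern, c("up", "down"))
  memb <- pattern_members(asg, expr)
  expect_setequal(memb$up, paste0("f", 1:30))
  expect_setequal(memb$down, paste0("f", 31:60))
})
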