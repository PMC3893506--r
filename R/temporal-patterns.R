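#' Configuration for model-profile analysis
#'
#' Parameters of the short time-series profile method: candidate profiles
#' start at level 0 and move by at most \code{c} integer units per step; of
#' all \code{(2c+1)^(T-1)} candidates, \code{m} mutually dissimilar
#' representatives are kept; profile-membership counts are tested by a
#' permutation test with Benjamini-Hochberg correction.
#'
#' @param c Maximum units of change per step (integer >= 0); default 2.
#' @param m Number of representative profiles; default 50.
#' @param n_perm Permutation rounds; default 1000.
#' @param fdr_cut Significance threshold on the adjusted p; default 0.001.
#' @param seed Integer seed for the permutation stream.
#' @return A list of class \code{"profile_config"}.
#' @export
profile_config <- function(c = 2L, m = 50L, n_perm = 1000L,
                           fdr_cut = 0.001, seed = 1L) {
  stopifnot_scalar_number(c, "c", min = 0)
  stopifnot_scalar_number(m, "m", min = 1)
  stopifnot_scalar_number(n_perm, "n_perm", min = 1)
  stopifnot_scalar_number(fdr_cut, "fdr_cut", min = 0, strict_min = TRUE)
  if (fdr_cut >= 1) abort_input("fdr_cut must be < 1")
  structure(list(c = as.integer(c), m = as.integer(m),
                 n_perm = as.integer(n_perm), fdr_cut = fdr_cut,
                 seed = as.integer(seed)),
            class = "profile_config")
}

#' Select features changed at any time point
#'
#' Keeps a feature when its linear fold ratio exceeds \code{up_fold} or
#' falls below \code{down_fold} at one or more time points (strict
#' inequalities). Input values are log2 ratios.
#'
#' @param expr An \code{\link{expression_matrix}}.
#' @param up_fold,down_fold Linear fold thresholds with
#'   \code{up_fold > 1 > down_fold > 0}; defaults 2 and 0.5.
#' @return Character vector of retained feature ids.
#' @export
select_changed_features <- function(expr, up_fold = 2, down_fold = 0.5) {
  if (!(up_fold > 1 && down_fold < 1 && down_fold > 0))
    abort_input("need up_fold > 1 > down_fold > 0")
  lo <- log2(up_fold); hi <- log2(down_fold)
  keep <- rowSums(unclass(expr) > lo | unclass(expr) < hi) > 0L
  rownames(expr)[keep]
}

#' Enumerate and select model temporal profiles
#'
#' Enumerates every integer shape of length \code{T} that starts at 0 and
#' changes by at most \code{c} units per step. When more than \code{m}
#' non-constant candidates exist, a deterministic farthest-first greedy pass
#' keeps \code{m} shapes maximizing the minimum pairwise dissimilarity
#' \code{1 - cor(shape_i, shape_j)}, seeded with the first candidate in
#' enumeration order; ties go to the lower enumeration index. Constant
#' candidate shapes are excluded from selection except the single flat
#' profile when \code{c = 0}.
#'
#' @param T Number of time points (>= 2), including the 0-level start.
#' @param config A \code{\link{profile_config}}.
#' @return A list of class \code{"model_profiles"} with \code{shapes} (an
#'   m x T integer matrix, rows named by profile id) and
#'   \code{n_candidates}.
#' @export
generate_model_profiles <- function(T, config = profile_config()) {
  if (T < 2) abort_input("need at least 2 time points")
  cc <- config$c
  if (cc == 0L) {
    if (config$m > 1L)
      warning("c = 0 admits only the flat profile; returning 1 profile",
              call. = FALSE)
    shapes <- matrix(0L, 1L, T, dimnames = list("P1", NULL))
    return(structure(list(shapes = shapes, n_candidates = 1L),
                     class = "model_profiles"))
  }
  steps <- as.matrix(expand.grid(rep(list(seq.int(-cc, cc)), T - 1L),
                                 KEEP.OUT.ATTRS = FALSE))
  shapes <- cbind(0L, t(apply(steps, 1L, cumsum)))
  if (T == 2L) shapes <- cbind(0L, steps[, 1L])
  n_cand <- nrow(shapes)
  nonconst <- which(apply(shapes, 1L, function(s) any(s != s[1L])))
  if (length(nonconst) <= config$m) {
    sel <- seq_len(n_cand)  # selection vacuous: all candidates returned
  } else {
    cand <- shapes[nonconst, , drop = FALSE]
    std <- standardize_rows(cand) / sqrt(ncol(cand) - 1L)  # unit rows
    sel_loc <- 1L
    mind <- 1 - as.vector(std %*% std[1L, ])
    while (length(sel_loc) < config$m) {
      nxt <- which.max(mind)  # ties -> lowest index
      sel_loc <- c(sel_loc, nxt)
      mind <- pmin(mind, 1 - as.vector(std %*% std[nxt, ]))
      mind[sel_loc] <- -Inf
    }
    sel <- sort(nonconst[sel_loc])
  }
  out <- shapes[sel, , drop = FALSE]
  rownames(out) <- paste0("P", seq_len(nrow(out)))
  structure(list(shapes = out, n_candidates = n_cand),
            class = "model_profiles")
}

#' @export
print.model_profiles <- function(x, ...) {
  cat(sprintf("<model_profiles> %d profiles over %d time points (%d candidates)\n",
              nrow(x$shapes), ncol(x$shapes), x$n_candidates))
  invisible(x)
}

# features x T trajectory matrix used for assignment: log2 ratios with the
# implicit time-0 baseline prepended
trajectory_matrix <- function(expr, prepend = TRUE) {
  if (prepend) prepend_baseline(expr) else unclass(expr)
}

#' Assign features to their best-correlated model profile
#'
#' Each feature goes to the profile maximizing the Pearson correlation
#' between its trajectory (a 0 is prepended for the time-0 control) and the
#' profile shape; ties break toward the lowest profile id. Zero-variance
#' trajectories are left unassigned.
#'
#' @param expr An \code{\link{expression_matrix}} restricted to the
#'   features of interest.
#' @param profiles A \code{"model_profiles"} object.
#' @param prepend_baseline Prepend the implicit time-0 level (default TRUE).
#' @return A list of class \code{"pattern_assignment"} with
#'   \code{assignment} (feature_id, profile_id, r) and \code{profile_stats}
#'   (profile_id, count).
#' @export
assign_profiles <- function(expr, profiles, prepend_baseline = TRUE) {
  if (!inherits(profiles, "model_profiles") || nrow(profiles$shapes) == 0L)
    abort_input("empty profile list")
  traj <- trajectory_matrix(expr, prepend_baseline)
  if (ncol(traj) != ncol(profiles$shapes))
    abort_input("trajectory length does not match profile length")
  hit <- best_profile(traj, profiles$shapes)
  assigned <- !is.na(hit$idx)
  assignment <- data.frame(
    feature_id = rownames(expr)[assigned],
    profile_id = rownames(profiles$shapes)[hit$idx[assigned]],
    r = hit$r[assigned], stringsAsFactors = FALSE)
  counts <- table(factor(assignment$profile_id,
                         levels = rownames(profiles$shapes)))
  structure(list(assignment = assignment,
                 profile_stats = data.frame(
                   profile_id = names(counts), count = as.integer(counts),
                   stringsAsFactors = FALSE),
                 profiles = profiles,
                 prepend_baseline = prepend_baseline),
            class = "pattern_assignment")
}

# argmax-correlation assignment; returns NA idx for zero-variance rows
best_profile <- function(traj, shapes) {
  sh_std <- standardize_rows(shapes)
  sh_ok <- !is.na(sh_std[, 1L])
  tr_std <- standardize_rows(traj)
  r_mat <- tcrossprod(tr_std, sh_std[sh_ok, , drop = FALSE]) / (ncol(traj) - 1L)
  idx_ok <- which(sh_ok)
  idx <- rep(NA_integer_, nrow(traj)); rbest <- rep(NA_real_, nrow(traj))
  valid <- !is.na(tr_std[, 1L])
  if (any(valid)) {
    loc <- max.col(r_mat[valid, , drop = FALSE], ties.method = "first")
    idx[valid] <- idx_ok[loc]
    rbest[valid] <- r_mat[cbind(which(valid), loc)]
  }
  list(idx = idx, r = rbest)
}

#' @export
print.pattern_assignment <- function(x, ...) {
  cat(sprintf("<pattern_assignment> %d features over %d profiles\n",
              nrow(x$assignment), nrow(x$profiles$shapes)))
  if (!is.null(x$profile_stats$p))
    cat(sprintf("  %d significant profiles\n", sum(x$profile_stats$significant)))
  invisible(x)
}

#' Permutation significance of profile-membership counts
#'
#' In each of \code{n_perm} rounds every feature's trajectory is
#' independently time-shuffled and re-assigned; a profile's empirical
#' p-value is
#' \code{(1 + rounds with permuted count >= observed) / (1 + n_perm)}
#' (column \code{p}). Because that p is floored at \code{1/(n_perm + 1)},
#' a stringent FDR cut needs finer resolution: the significance flag is
#' therefore driven by a pooled-null p (column \code{p_pooled}) that
#' compares the observed count against the permuted counts of all profiles
#' and rounds jointly -- the same pooling device the pair-integration
#' stage uses -- adjusted across profiles by Benjamini-Hochberg and
#' flagged below \code{fdr_cut}.
#'
#' @param assignment A \code{"pattern_assignment"} from
#'   \code{\link{assign_profiles}} on \code{expr}.
#' @param expr The same \code{\link{expression_matrix}}.
#' @param config A \code{\link{profile_config}} (supplies \code{n_perm},
#'   \code{fdr_cut}, \code{seed}).
#' @return The assignment with \code{profile_stats} gaining columns
#'   \code{p}, \code{fdr} and \code{significant}.
#' @export
profile_significance <- function(assignment, expr, config = profile_config()) {
  if (config$n_perm < 1L) abort_input("n_perm must be >= 1")
  shapes <- assignment$profiles$shapes
  traj <- trajectory_matrix(expr, assignment$prepend_baseline)
  obs <- assignment$profile_stats$count
  n_prof <- nrow(shapes)
  T <- ncol(traj)
  null_counts <- matrix(0L, n_prof, config$n_perm)
  with_seed(derive_seed(config$seed, "profile-significance"), {
    for (b in seq_len(config$n_perm)) {
      perm <- t(apply(traj, 1L, sample))
      hit <- best_profile(perm, shapes)
      null_counts[, b] <- tabulate(hit$idx[!is.na(hit$idx)], nbins = n_prof)
    }
  })
  exceed <- rowSums(null_counts >= obs)
  pooled_sorted <- sort(as.vector(null_counts))
  n_pool <- length(pooled_sorted)
  # pooled tail count: permuted counts (any profile, any round) >= observed
  pooled_ge <- n_pool - findInterval(obs - 0.5, pooled_sorted)
  p <- (1 + exceed) / (1 + config$n_perm)
  st <- assignment$profile_stats
  st$p <- p
  st$p_pooled <- (1 + pooled_ge) / (1 + n_pool)
  st$fdr <- p.adjust(st$p_pooled, method = "BH")
  st$significant <- st$fdr < config$fdr_cut
  assignment$profile_stats <- st
  assignment
}

#' Label significant profiles as temporal up- or down-patterns
#'
#' A significant profile is an up-pattern when the mean final log2 level of
#' its member features is positive, a down-pattern when negative.
#'
#' @param assignment A \code{"pattern_assignment"} with significance.
#' @param expr The \code{\link{expression_matrix}} the assignment used.
#' @return \code{data.frame} with \code{profile_id}, \code{pattern}
#'   (\code{"up"}/\code{"down"}) for significant profiles.
#' @export
label_patterns <- function(assignment, expr) {
  st <- assignment$profile_stats
  if (is.null(st$significant)) abort_input("run profile_significance first")
  sig <- st$profile_id[st$significant]
  final <- unclass(expr)[, ncol(expr)]
  lab <- vapply(sig, function(pid) {
    memb <- assignment$assignment$feature_id[assignment$assignment$profile_id == pid]
    if (mean(final[memb]) >= 0) "up" else "down"
  }, character(1L))
  data.frame(profile_id = sig, pattern = unname(lab), stringsAsFactors = FALSE)
}

#' Features belonging to significant up-/down-patterns
#'
#' @inheritParams label_patterns
#' @return Named list with character vectors \code{up} and \code{down}.
#' @export
pattern_members <- function(assignment, expr) {
  lab <- label_patterns(assignment, expr)
  asg <- assignment$assignment
  list(up = asg$feature_id[asg$profile_id %in% lab$profile_id[lab$pattern == "up"]],
       down = asg$feature_id[asg$profile_id %in% lab$profile_id[lab$pattern == "down"]])
}
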