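# Independent oracles used to cross-check the implementation, plus small
# fixture builders. Everything here is deliberately naive (enumeration,
# brute force) and shares no code path with the package internals.

# all permutations of 1..n (n small)
perms_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# two-sided Fisher p by direct enumeration with choose() ratios
oracle_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c_ + d; k <- a + c_; N <- m + n
  support <- max(0, k - n):min(k, m)
  pr <- choose(m, support) * choose(n, k - support) / choose(N, k)
  p_obs <- choose(m, a) * choose(n, k - a) / choose(N, k)
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# betweenness by exhaustive simple-path enumeration (directed, unweighted)
oracle_betweenness <- function(nodes, edges) {
  adj <- lapply(nodes, function(v) edges$target[edges$source == v])
  names(adj) <- nodes
  all_paths <- function(s, t) {
    found <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) { found[[length(found) + 1L]] <<- path; return() }
      for (w in adj[[v]]) if (!w %in% path) walk(c(path, w))
    }
    walk(s)
    found
  }
  bw <- setNames(numeric(length(nodes)), nodes)
  for (s in nodes) for (t in nodes) {
    if (s == t) next
    paths <- all_paths(s, t)
    if (!length(paths)) next
    lens <- lengths(paths)
    shortest <- paths[lens == min(lens)]
    for (p in shortest) {
      inner <- setdiff(p, c(s, t))
      bw[inner] <- bw[inner] + 1 / length(shortest)
    }
  }
  n <- length(nodes)
  if (n < 3) bw[] <- 0 else bw <- bw / ((n - 1) * (n - 2))
  bw
}

# per-window PWM scorer, scalar arithmetic only
oracle_scan_count <- function(seq_chr, pwm, fraction, both_strands = TRUE,
                              convention = "minmax") {
  thr <- if (convention == "minmax")
    pwm$min_score + fraction * (pwm$max_score - pwm$min_score)
  else fraction * pwm$max_score
  count_strand <- function(s) {
    bases <- strsplit(s, "")[[1]]
    w <- pwm$width
    if (length(bases) < w) return(0L)
    hits <- 0L
    for (i in seq_len(length(bases) - w + 1L)) {
      win <- bases[i:(i + w - 1L)]
      if (any(!win %in% c("A", "C", "G", "T"))) next
      sc <- 0
      for (j in seq_len(w)) sc <- sc + pwm$weights[win[j], j]
      if (sc >= thr) hits <- hits + 1L
    }
    hits
  }
  n <- count_strand(seq_chr)
  if (both_strands) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    rc <- paste(rev(comp[strsplit(seq_chr, "")[[1]]]), collapse = "")
    n <- n + count_strand(rc)
  }
  n
}

# small bundle configs used across test files
tiny_config <- function(...) {
  synthetic_config(n_genes = 40L, n_mirnas = 8L, frac_up = 0.2,
                   frac_down = 0.2, n_true_pairs = 8L,
                   decoys_per_mirna = 3L, n_pathways = 4L,
                   pathway_size = 8L, n_pwms = 8L, motif_len = 8L,
                   promoter_len = 400L, seed = 11L, ...)
}

random_digraph <- function(n_nodes, p_edge = 0.4) {
  nodes <- letters[seq_len(n_nodes)]
  grid <- expand.grid(source = nodes, target = nodes,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$source != grid$target, ]
  grid[runif(nrow(grid)) < p_edge, c("source", "target")]
}
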