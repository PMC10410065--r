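# Independent oracles, deliberately written from the definitions and kept
# free of the package's own code paths.

# Benjamini-Hochberg step-up adjusted p-values with monotonicity
# enforcement, straight from the step-up definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Upper-tail hypergeometric P(X >= k) by explicit pmf enumeration.
hyper_tail_oracle <- function(N, K, n, k) {
  js <- max(0, k):min(K, n)
  js <- js[(n - js) <= (N - K)]
  if (!length(js)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Two-sided Fisher exact p for a 2x2 table: sum of hypergeometric table
# probabilities no larger than the observed table's probability.
fisher_p_oracle <- function(a, b, c, d) {
  m1 <- a + b
  cs <- a + c
  n_tot <- a + b + c + d
  lo <- max(0, cs - (n_tot - m1))
  hi <- min(m1, cs)
  xs <- lo:hi
  probs <- dhyper(xs, m1, n_tot - m1, cs)
  p_obs <- dhyper(a, m1, n_tot - m1, cs)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Breadth-first level assignment from a seed set, by hand.
bfs_levels_oracle <- function(edges, seeds, max_level) {
  adj <- list()
  add <- function(x, y) {
    adj[[x]] <<- unique(c(adj[[x]], y))
  }
  for (i in seq_len(nrow(edges))) {
    add(edges$protein_a[i], edges$protein_b[i])
    add(edges$protein_b[i], edges$protein_a[i])
  }
  level_of <- stats::setNames(rep(0L, length(seeds)), seeds)
  frontier <- seeds
  for (L in seq_len(max_level)) {
    nxt <- character(0)
    for (v in frontier) nxt <- c(nxt, adj[[v]])
    nxt <- setdiff(unique(nxt), names(level_of))
    if (!length(nxt)) break
    level_of[nxt] <- L
    frontier <- nxt
  }
  level_of
}

# Greedy clumping re-derived from its definition: sort by (p, id), accept
# iff r2 with all previously accepted within the window is < r2_max.
clump_oracle <- function(snps, pvalues, pos, r2_fun, r2_max, window_bp) {
  ord <- order(pvalues, snps)
  acc <- character(0)
  for (i in ord) {
    ok <- TRUE
    for (s in acc) {
      same_chrom <- pos$chrom[pos$snp_id == s] == pos$chrom[pos$snp_id == snps[i]]
      dist <- abs(pos$pos[pos$snp_id == s] - pos$pos[pos$snp_id == snps[i]])
      if (same_chrom && dist <= window_bp && r2_fun(s, snps[i]) >= r2_max) {
        ok <- FALSE
        break
      }
    }
    if (ok) acc <- c(acc, snps[i])
  }
  acc
}

# Connected components by boolean transitive closure of the adjacency
# matrix.
components_oracle <- function(ids, edge_a, edge_b) {
  n <- length(ids)
  A <- diag(TRUE, n)
  for (i in seq_along(edge_a)) {
    ia <- match(edge_a[i], ids)
    ib <- match(edge_b[i], ids)
    A[ia, ib] <- A[ib, ia] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  comp <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      next_id <- next_id + 1L
      comp[A[i, ]] <- next_id
    }
  }
  split(ids, comp)
}
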