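# Independent oracles used across tests: graph BFS for hex distances,
# brute-force scans for prefix/overlap selections, and the literal step-up
# definition of Benjamini-Hochberg.

# Shortest-path distances from one well to all wells on the hexagonal
# adjacency graph (breadth-first search; independent of the axial formula).
bfs_distances <- function(array, from_id) {
  w <- array$wells
  idx <- stats::setNames(seq_len(nrow(w)), paste(w$q, w$r))
  dirs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, -1), c(-1, 1))
  dist <- rep(NA_integer_, nrow(w))
  frontier <- which(w$well_id == from_id)
  dist[frontier] <- 0L
  while (length(frontier)) {
    nxt <- integer(0)
    for (i in frontier) {
      for (k in 1:6) {
        j <- idx[paste(w$q[i] + dirs[k, 1], w$r[i] + dirs[k, 2])]
        if (!is.na(j) && is.na(dist[j])) {
          dist[j] <- dist[i] + 1L
          nxt <- c(nxt, j)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

# Literal longest-dominating-prefix scan over all prefixes.
brute_top_genes <- function(basis, m) {
  ord <- order(basis[, m], decreasing = TRUE)
  best <- character(0)
  for (k in seq_along(ord)) {
    pref <- ord[seq_len(k)]
    dominates <- all(basis[pref, m] > apply(basis[pref, -m, drop = FALSE], 1, max))
    if (dominates) best <- rownames(basis)[pref] else break
  }
  best
}

# Literal best-overlap matching over all module pairs.
brute_match <- function(tops_a, tops_b, top_n, min_frac) {
  out <- NULL
  for (i in seq_along(tops_a)) {
    ov <- sapply(tops_b, function(tb) length(intersect(tops_a[[i]], tb)))
    j <- which(ov == max(ov))[1]
    if (ov[j] / top_n >= min_frac)
      out <- rbind(out, data.frame(module_a = names(tops_a)[i],
                                   module_b = names(tops_b)[j],
                                   overlap_count = ov[j]))
  }
  out
}

# Step-up BH from its definition: q_(i) = min_{j >= i} m * p_(j) / j.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- rev(cummin(rev(m * p[ord] / seq_len(m))))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Minimal gene_module_set stand-in for functions that only need rankings.
fake_module_set <- function(sorted_genes, basis = NULL) {
  structure(list(basis = basis, sorted_genes = sorted_genes,
                 rank = length(sorted_genes), tissue_tag = "T"),
            class = "gene_module_set")
}
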