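# Independent oracles used to check the package's primary code paths.
# Deliberately naive implementations: tables, enumeration, pair counting.

# order-w Markov chain trained by direct substring counting; scores a test
# sequence with per-outcome pseudocounts (the reference for ICM oracle mode)
oracle_chain_score <- function(train_seqs, test_seq, w, pseudo = 0.5) {
  ctx <- character(0)
  outc <- character(0)
  for (s in train_seqs) {
    n <- nchar(s)
    if (n < w + 1) next
    ctx <- c(ctx, substring(s, 1:(n - w), w:(n - 1)))
    outc <- c(outc, substring(s, (w + 1):n, (w + 1):n))
  }
  counts <- table(ctx, outc)
  bases <- c("A", "C", "G", "T")
  n <- nchar(test_seq)
  tctx <- substring(test_seq, 1:(n - w), w:(n - 1))
  tout <- substring(test_seq, (w + 1):n, (w + 1):n)
  score <- 0
  for (i in seq_along(tctx)) {
    cc <- tctx[i]
    cnt <- stats::setNames(numeric(4), bases)
    if (cc %in% rownames(counts))
      cnt[colnames(counts)] <- counts[cc, ]
    score <- score + log((cnt[tout[i]] + pseudo) / (sum(cnt) + 4 * pseudo))
  }
  unname(score)
}

# plug-in mutual information (bits) from two categorical vectors
oracle_mi <- function(x, y) {
  p <- table(x, y) / length(x)
  px <- rowSums(p)
  py <- colSums(p)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py))
    if (p[i, j] > 0) mi <- mi + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  unname(mi)
}

# exact minimum normalized cut by enumerating all bipartitions (n <= 14)
oracle_min_ncut <- function(edges, n) {
  W <- matrix(0, n, n)
  for (e in seq_len(nrow(edges))) {
    W[edges$i[e], edges$j[e]] <- edges$w[e]
    W[edges$j[e], edges$i[e]] <- edges$w[e]
  }
  deg <- rowSums(W)
  total <- sum(deg)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) { # vertex n always in B: halves the space
    inA <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    cut <- sum(W[inA, !inA])
    assocA <- sum(deg[inA])
    nc <- cut / assocA + cut / (total - assocA)
    if (nc < best) best <- nc
  }
  best
}

# adjusted Rand by brute-force pair counting
oracle_ari <- function(a, b) {
  n <- length(a)
  s_both <- 0; s_a <- 0; s_b <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ta <- a[i] == a[j]
    tb <- b[i] == b[j]
    if (ta && tb) s_both <- s_both + 1
    if (ta) s_a <- s_a + 1
    if (tb) s_b <- s_b + 1
  }
  n2 <- n * (n - 1) / 2
  expected <- s_a * s_b / n2
  maxi <- (s_a + s_b) / 2
  (s_both - expected) / (maxi - expected)
}

# random connected weighted graph as a neighbor_graph (small n)
random_connected_graph <- function(n, p = 0.4) {
  repeat {
    pairs <- utils::combn(n, 2)
    pick <- runif(ncol(pairs)) < p
    if (sum(pick) == 0) next
    edges <- data.frame(i = pairs[1, pick], j = pairs[2, pick],
                        w = runif(sum(pick), 0.1, 1))
    # BFS connectivity check
    adj <- lapply(seq_len(n), function(v)
      c(edges$j[edges$i == v], edges$i[edges$j == v]))
    seen <- logical(n)
    queue <- 1L
    seen[1] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) if (!seen[u]) { seen[u] <- TRUE; queue <- c(queue, u) }
    }
    if (all(seen))
      return(structure(list(n = n, edges = edges), class = "neighbor_graph"))
  }
}
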