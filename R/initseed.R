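#' Strand-symmetric k-mer frequency profile
#'
#' Counts all N-free `m`-mers of the sequence and of its reverse complement
#' (a genome signature should not depend on which strand was sequenced) and
#' normalises to sum 1.  Sequences shorter than `m` get the uniform profile.
#'
#' @param set a [seq_set()].
#' @param m k-mer size (default 5, the size used for composition-based
#'   bisection).
#' @return numeric matrix, one row per sequence, `4^m` columns named by
#'   k-mer.
#' @export
#' @examples
#' kmer_profiles(seq_set(c(x = "AAAA")), m = 1)  # A and T both 0.5
kmer_profiles <- function(set, m = 5L) {
  prof <- .kmer_profiles_cpp(set$seq, as.integer(m))
  bases <- c("A", "C", "G", "T")
  # lexicographic order over A<C<G<T matches the 2-bit packing with the
  # first base most significant
  mers <- sort(do.call(paste0, expand.grid(rep(list(bases), m))))
  colnames(prof) <- mers
  rownames(prof) <- set$id
  prof
}

#' @rdname kmer_profiles
#' @param s a single sequence (character) or single-record `seq_set`.
#' @export
kmer_profile <- function(s, m = 5L) {
  if (is.character(s)) s <- seq_set(s, ids = "s")
  drop(kmer_profiles(s, m)[1, ])
}

#' Project composition profiles to a low-dimensional space by PCA
#'
#' Centers the rows and projects onto the leading principal axes.  Axis signs
#' are fixed by convention (the largest-magnitude loading of each axis is
#' positive) so results are deterministic.
#'
#' @param profiles numeric matrix, observations in rows.
#' @param dims number of components (default 3).
#' @return list with `coords` (n x dims scores), `sdev` (component standard
#'   deviations, non-increasing).
#' @export
pca_project <- function(profiles, dims = 3L) {
  n <- nrow(profiles)
  if (n < dims) stopf("need at least dims = %d rows, got %d", dims, n)
  pc <- prcomp(profiles, center = TRUE, scale. = FALSE, rank. = dims)
  rot <- pc$rotation
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  dims <- min(dims, ncol(pc$x))
  list(coords = pc$x[, seq_len(dims), drop = FALSE],
       sdev = pc$sdev[seq_len(dims)])
}

#' Number of nearest neighbours as a function of the number of sequences
#'
#' `f(n) = 2 + floor(0.5 * floor(ln n))`, capped at `n - 1`.  Fewer
#' sequences need a less connected graph for the normalized cut to find a
#' clean bipartition; at typical metagenome sizes (tens of thousands of
#' reads) this lands near the classic six nearest neighbours.
#'
#' @param n number of sequences (>= 2).
#' @return integer >= 1.
#' @export
#' @examples
#' num_neighbors(100)    # 4
#' num_neighbors(30000)  # 7
num_neighbors <- function(n) {
  stopifnot(n >= 2)
  min(2L + floor(floor(log(n)) / 2), n - 1L)
}

#' Symmetrised k-nearest-neighbour graph with Gaussian weights
#'
#' Directed edges join each point to its `k_nn` Euclidean nearest neighbours
#' (distance ties broken by input order); the graph is the union of both
#' directions.  Edge weight is `exp(-d^2 / sigma^2)` with `sigma` the median
#' directed-neighbour distance, so weights lie in (0, 1] and decrease with
#' distance.
#'
#' @param points numeric matrix of coordinates (rows = vertices).
#' @param k_nn neighbours per vertex, `1 <= k_nn < n`.
#' @return object of class `neighbor_graph`: list with `n` and `edges`
#'   (data.frame `i`, `j`, `w` with `i < j`).
#' @export
knn_graph <- function(points, k_nn) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(k_nn >= 1, k_nn < n)
  nn <- .knn_cpp(points, as.integer(k_nn))
  sigma <- median(nn$dist)
  if (sigma == 0) sigma <- 1 # duplicate-heavy input: weights default to 1
  i <- rep(seq_len(n), k_nn)
  j <- as.vector(nn$idx)
  d <- as.vector(nn$dist)
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- (lo - 1) * n + hi
  keep <- !duplicated(key)
  edges <- data.frame(i = lo[keep], j = hi[keep],
                      w = exp(-(d[keep]^2) / sigma^2))
  structure(list(n = n, edges = edges), class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("neighbor_graph: %d vertices, %d edges\n", x$n, nrow(x$edges)))
  invisible(x)
}

graph_adjacency <- function(graph) {
  Matrix::sparseMatrix(
    i = c(graph$edges$i, graph$edges$j),
    j = c(graph$edges$j, graph$edges$i),
    x = c(graph$edges$w, graph$edges$w),
    dims = c(graph$n, graph$n))
}

# second-smallest eigenvector of the symmetric normalized Laplacian
# I - D^{-1/2} W D^{-1/2}; dense solve for small graphs, deflated power
# iteration on 2I - L (deterministic start) for large ones
fiedler_vector <- function(W, deg) {
  n <- nrow(W)
  dis <- 1 / sqrt(deg)
  if (n <= 1024) {
    L <- diag(n) - as.matrix(W) * tcrossprod(dis)
    ev <- eigen(L, symmetric = TRUE)
    return(ev$vectors[, n - 1])
  }
  v1 <- sqrt(deg) / sqrt(sum(deg))
  x <- seq_len(n) - (n + 1) / 2
  x <- x - sum(x * v1) * v1
  x <- x / sqrt(sum(x^2))
  for (it in seq_len(3000)) {
    y <- 2 * x - dis * as.numeric(W %*% (dis * x)) # (2I - L) x
    y <- y - sum(y * v1) * v1
    y <- y / sqrt(sum(y^2))
    if (max(abs(y - x)) < 1e-10 || max(abs(y + x)) < 1e-10) {
      x <- y
      break
    }
    x <- y
  }
  x
}

#' Approximate minimum normalized cut of a weighted graph
#'
#' Bipartitions the vertices to approximately minimise
#' `Ncut(A, B) = cut(A,B)/assoc(A,V) + cut(A,B)/assoc(B,V)` using the
#' spectral relaxation: the second-smallest eigenvector of the normalized
#' Laplacian is computed, vertices are sorted by their entry (rescaled by
#' `D^{-1/2}`), and every prefix split is swept to take the one with the
#' smallest Ncut.  A disconnected graph is split along its components
#' (cut 0) without touching the eigenproblem.
#'
#' @param graph a [knn_graph()] result.
#' @return list with integer vectors `a` and `b` (the two non-empty sides)
#'   and the achieved `ncut`.
#' @export
normalized_cut <- function(graph) {
  n <- graph$n
  if (n < 2) stopf("normalized cut needs at least 2 vertices")
  W <- graph_adjacency(graph)
  g <- igraph::graph_from_data_frame(graph$edges[, c("i", "j")],
                                     directed = FALSE,
                                     vertices = data.frame(seq_len(n)))
  comp <- igraph::components(g)
  if (comp$no > 1) {
    a <- which(comp$membership == comp$membership[1])
    return(list(a = a, b = setdiff(seq_len(n), a), ncut = 0))
  }
  deg <- as.numeric(Matrix::rowSums(W))
  y <- fiedler_vector(W, deg) / sqrt(deg)
  ord <- order(y, seq_len(n))
  # sweep: incrementally move vertices into A in eigenvector order
  adj <- vector("list", n)
  for (e in seq_len(nrow(graph$edges))) {
    i <- graph$edges$i[e]; j <- graph$edges$j[e]; w <- graph$edges$w[e]
    adj[[i]] <- rbind(adj[[i]], c(j, w))
    adj[[j]] <- rbind(adj[[j]], c(i, w))
  }
  total <- sum(deg)
  inA <- logical(n)
  cut <- 0; assocA <- 0
  best_ncut <- Inf; best_t <- 1
  for (t in seq_len(n - 1)) {
    v <- ord[t]
    wA <- 0
    nb <- adj[[v]]
    if (!is.null(nb)) wA <- sum(nb[inA[nb[, 1]], 2])
    cut <- cut + deg[v] - 2 * wA
    assocA <- assocA + deg[v]
    inA[v] <- TRUE
    nc <- cut / assocA + cut / (total - assocA)
    if (nc < best_ncut) {
      best_ncut <- nc
      best_t <- t
    }
  }
  a <- sort(ord[seq_len(best_t)])
  list(a = a, b = setdiff(seq_len(n), a), ncut = best_ncut)
}

#' Composition-based initial partition by recursive spectral bisection
#'
#' The classic composition pipeline: per-sequence strand-symmetric k-mer
#' profiles, PCA to three dimensions, a nearest-neighbour graph with
#' [num_neighbors()] neighbours, and a minimum normalized cut.  Bisection
#' repeats -- always splitting the current part holding the most sequenced
#' bp, so dominant organisms get resolved first -- until `k` parts exist.
#'
#' @param set a [seq_set()].
#' @param k desired number of clusters (`1 <= k <= n`).
#' @param m k-mer size (default 5).
#' @param dims PCA dimensions (default 3).
#' @param seed RNG seed (the procedure is deterministic; the seed guards any
#'   future stochastic component).
#' @return named integer assignment with exactly `k` non-empty clusters.
#' @export
compostbin_partition <- function(set, k, m = 5L, dims = 3L, seed = 1L) {
  n <- length(set$id)
  if (k < 1) stopf("k must be >= 1")
  if (k > n) stopf("k = %d exceeds the number of sequences (%d)", k, n)
  parts <- list(seq_len(n))
  bp <- nchar(set$seq)
  with_seed(seed, {
    while (length(parts) < k) {
      sizes <- vapply(parts, function(p) sum(bp[p]), 0)
      sizes[lengths(parts) < 2] <- -Inf
      target <- which.max(sizes)
      p <- parts[[target]]
      sub <- subset_seqs(set, p)
      prof <- kmer_profiles(sub, m)
      d <- min(dims, length(p) - 1L)
      coords <- pca_project(prof, d)$coords
      knn <- min(num_neighbors(length(p)), length(p) - 1L)
      g <- knn_graph(coords, knn)
      cut <- normalized_cut(g)
      parts[[target]] <- p[cut$a]
      parts[[length(parts) + 1L]] <- p[cut$b]
    }
  })
  a <- integer(n)
  for (ci in seq_along(parts)) a[parts[[ci]]] <- ci - 1L
  names(a) <- set$id
  a
}

#' Initial partition by Markov-chain Monte Carlo over fixed-order models
#'
#' A light re-implementation of likelihood-based binning: each cluster is a
#' fixed-order Markov chain (ML transition counts plus pseudocounts) with a
#' bp-share prior, and a Metropolis sampler proposes single-sequence
#' reassignments, always accepting likelihood improvements.  The best of
#' `n_starts` random restarts (by final log-likelihood) is returned.  Used
#' as an initialiser only; not a faithful port of any particular sampler.
#'
#' @param set a [seq_set()].
#' @param k number of clusters.
#' @param order Markov chain order, 2..4 (default 3).
#' @param n_starts random restarts (default 2).
#' @param steps Metropolis proposals per start (default `200 * n`).
#' @param pseudocount transition pseudocount (default 0.5).
#' @param both_strands count transitions on the read and its reverse
#'   complement (default `TRUE`); shotgun reads are unoriented, and a
#'   forward-only chain would sooner split clusters by strand than by
#'   genome.
#' @param seed RNG seed.
#' @return named integer assignment with `k` non-empty clusters (as an
#'   attribute, `loglik` holds the final objective).
#' @export
likelybin_partition <- function(set, k, order = 3L, n_starts = 2L,
                                steps = NULL, pseudocount = 0.5,
                                both_strands = TRUE, seed = 1L) {
  stopifnot(order %in% 2:4, k >= 1)
  n <- length(set$id)
  if (k > n) stopf("k = %d exceeds the number of sequences (%d)", k, n)
  if (is.null(steps)) steps <- 200L * n
  counts <- .markov_counts_cpp(set$seq, as.integer(order), both_strands)
  res <- with_seed(seed,
    .likelybin_cpp(counts, nchar(set$seq), as.integer(k),
                   as.integer(steps), as.integer(n_starts), pseudocount))
  a <- compact_assignment(structure(res$z, names = set$id))
  attr(a, "loglik") <- res$loglik
  a
}

#' Choose among candidate initial partitions by the CML criterion
#'
#' Different initialisers succeed on different data, so the pipeline runs
#' several and keeps the best.  Each candidate gets one full clustering
#' iteration (train models on its clusters, reassign every sequence), the
#' CML criterion of the resulting state is computed, and the post-iteration
#' assignment with the greatest CML wins.  Ties go to the earlier candidate.
#'
#' @param candidates list of assignments (may cover only a subsample of
#'   `set`; every sequence of `set` is assigned during the iteration).
#' @param set the full [seq_set()].
#' @param w ICM window width.
#' @param ... further arguments passed to [train_icm()].
#' @return the winning post-iteration assignment; attribute `cml` holds its
#'   criterion value, attribute `which` the index of the winning candidate.
#' @export
select_initialization <- function(candidates, set, w = 8L, ...) {
  stopifnot(length(candidates) >= 1)
  best <- NULL; best_cml <- -Inf; best_i <- 0L
  for (ci in seq_along(candidates)) {
    mp <- retrain_step(set, candidates[[ci]], w = w, ...)
    a <- assign_step(set, mp$models, mp$priors)
    cml <- cml_value(set, a, mp$models, mp$priors)
    if (cml > best_cml) {
      best <- a; best_cml <- cml; best_i <- ci
    }
  }
  attr(best, "cml") <- best_cml
  attr(best, "which") <- best_i
  best
}
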