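#' Enumerate context windows of a sequence set
#'
#' A context corpus is the multiset of (w+1)-wide windows over the training
#' sequences: the first `w` positions are the context, the last is the
#' outcome nucleotide being predicted.  Windows touching an `N` are dropped.
#'
#' @param set a [seq_set()].
#' @param w context width (>= 0).
#' @return object of class `context_corpus` with fields `w`, `context`
#'   (character, width-`w` strings) and `outcome` (single characters).
#' @export
#' @examples
#' cc <- build_corpus(seq_set(c(x = "ACGTA")), w = 2)
#' cc$context  # "AC" "CG" "GT"
#' cc$outcome  # "G"  "T"  "A"
build_corpus <- function(set, w) {
  stopifnot(w >= 0)
  ctx <- character(0)
  out <- character(0)
  for (s in set$seq) {
    n <- nchar(s)
    if (n < w + 1) next
    starts <- seq_len(n - w)
    win <- substring(s, starts, starts + w)
    keep <- !grepl("N", win, fixed = TRUE)
    ctx <- c(ctx, substring(win[keep], 1L, w))
    out <- c(out, substring(win[keep], w + 1L, w + 1L))
  }
  structure(list(w = as.integer(w), context = ctx, outcome = out),
            class = "context_corpus")
}

#' @export
print.context_corpus <- function(x, ...) {
  cat(sprintf("context_corpus: w = %d, %d windows\n", x$w, length(x$outcome)))
  invisible(x)
}

#' Mutual information between a context position and the outcome
#'
#' Plug-in (empirical) mutual information, in bits, between the nucleotide at
#' `position` of the context and the predicted nucleotide.  This is the
#' quantity the ICM trainer maximises when choosing split positions.
#'
#' @param corpus a [build_corpus()] result.
#' @param position context position, 1..w (position w is the base immediately
#'   preceding the outcome).
#' @return non-negative float (bits).
#' @export
mutual_information <- function(corpus, position) {
  stopifnot(inherits(corpus, "context_corpus"))
  if (length(corpus$outcome) == 0) stopf("empty corpus")
  if (position < 1 || position > corpus$w)
    stopf("position must be in 1..%d", corpus$w)
  x <- substring(corpus$context, position, position)
  tab <- table(x, corpus$outcome)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (p[i, j] > 0)
      mi <- mi + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  }
  max(0, mi)
}

#' Chi-square weighted interpolation of a child distribution with its parent
#'
#' Given outcome counts at a tree node and the parent's probability
#' distribution, computes the interpolation weight
#' `lambda = (1 - pval) * n / (n + n0)` where `pval` is the upper-tail
#' p-value of a chi-square goodness-of-fit test (df = 3) of the counts
#' against `n * parent_dist`, and returns the blended distribution
#' `lambda * child + (1 - lambda) * parent`.  The child's empirical
#' distribution gets `pseudocount` added per outcome first, so every entry of
#' the result is positive.
#'
#' @param child_counts numeric 4-vector of outcome counts (A, C, G, T).
#' @param parent_dist probability 4-vector summing to 1.
#' @param pseudocount pseudocount per outcome (default 0.5).
#' @param n0 count scale: at `n = n0` windows a maximally significant node
#'   gets lambda 0.5 (default 400).
#' @return list with `lambda`, `interp_dist`, `pval`.
#' @export
interpolate_dist <- function(child_counts, parent_dist, pseudocount = 0.5,
                             n0 = 400) {
  stopifnot(length(child_counts) == 4, length(parent_dist) == 4,
            all(child_counts >= 0))
  if (abs(sum(parent_dist) - 1) > 1e-6) stopf("parent_dist must sum to 1")
  n <- sum(child_counts)
  if (n == 0) {
    return(list(lambda = 0, interp_dist = as.numeric(parent_dist), pval = 1))
  }
  expd <- n * parent_dist
  if (any(expd == 0 & child_counts > 0)) {
    pval <- 0
  } else {
    ok <- expd > 0
    pval <- pchisq(sum((child_counts[ok] - expd[ok])^2 / expd[ok]),
                   df = 3, lower.tail = FALSE)
  }
  lambda <- (1 - pval) * n / (n + n0)
  emp <- (child_counts + pseudocount) / (n + 4 * pseudocount)
  list(lambda = lambda,
       interp_dist = lambda * emp + (1 - lambda) * as.numeric(parent_dist),
       pval = pval)
}

#' Train an interpolated context model (ICM)
#'
#' Builds a probabilistic decision tree over the `w` context positions.  At
#' each node the unused position with the greatest (conditional) mutual
#' information with the outcome is split into four branches; growth stops
#' when a node holds fewer than `min_split_windows` windows, when all
#' positions are used, or when a chi-square test cannot distinguish the
#' node's outcome distribution from its parent's at significance
#' `stop_alpha`.  Every node stores a distribution interpolated with its
#' parent per [interpolate_dist()] (the root interpolates against uniform).
#'
#' With `interpolate = FALSE` the weights are forced to 1 and the similarity
#' stop is disabled; combined with `min_split_windows = 1` the model is then
#' exactly a fixed order-`w` Markov chain with the same pseudocounts, which
#' is the package's oracle mode.
#'
#' @param set training [seq_set()].
#' @param w context window width; 0..15 (default 8; the effective order
#'   adapts to the data through the stopping rules).
#' @param min_split_windows minimum windows a node needs to be split
#'   (default 100).
#' @param pseudocount per-outcome pseudocount (default 0.5).
#' @param n0 interpolation count scale (default 400).
#' @param stop_alpha chi-square significance for the "distributions are
#'   similar, stop branching" rule: branching continues only while
#'   `pval <= stop_alpha` (default 0.05).
#' @param interpolate logical; `FALSE` gives oracle mode (see above).
#' @return object of class `icm_model`.
#' @export
train_icm <- function(set, w = 8L, min_split_windows = 100L,
                      pseudocount = 0.5, n0 = 400, stop_alpha = 0.05,
                      interpolate = TRUE) {
  fit <- .icm_train_cpp(set$seq, as.integer(w), as.integer(min_split_windows),
                        pseudocount, n0, stop_alpha, interpolate)
  structure(list(w = as.integer(w), pseudocount = pseudocount, n0 = n0,
                 stop_alpha = stop_alpha, interpolate = interpolate,
                 trained_bp = fit$trained_bp,
                 n_windows = fit$n_windows_total,
                 nodes = list(split_pos = fit$split_pos,
                              children = fit$children,
                              n_windows = fit$n_windows,
                              lambda = fit$lambda,
                              raw_dist = fit$raw_dist,
                              interp_dist = fit$interp_dist)),
            class = "icm_model")
}

#' @export
print.icm_model <- function(x, ...) {
  cat(sprintf(
    "icm_model: w = %d, %d nodes, trained on %.0f bp (%.0f windows)\n",
    x$w, length(x$nodes$split_pos), x$trained_bp, x$n_windows))
  invisible(x)
}

#' Log-likelihood of sequences under an ICM
#'
#' Walks each sequence and sums `log P(s_i | context)` for positions
#' `i = w+1 .. |s|`, descending the decision tree per the context bases and
#' reading the leaf's interpolated distribution.  Positions whose window
#' contains `N` contribute `log(1/4)`.  `strand_mode = "both-max"` also
#' scores the reverse complement and returns the per-sequence maximum, for
#' shotgun data of unknown orientation.
#'
#' @param model an [train_icm()] model.
#' @param set a [seq_set()] (every sequence must be longer than `w`).
#' @param strand_mode `"forward"` (default) or `"both-max"`.
#' @return numeric vector of log-probabilities (<= 0), one per sequence.
#' @export
score_sequences <- function(model, set,
                            strand_mode = c("forward", "both-max")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(model, "icm_model"))
  .icm_score_cpp(set$seq, model$w, model$nodes$split_pos,
                 model$nodes$children, model$nodes$interp_dist,
                 strand_mode == "both-max")
}

#' Serialize an ICM to a versioned JSON file
#'
#' @param model an `icm_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_icm <- function(model, path) {
  obj <- list(format = "scimmr-icm", version = 1L,
              w = model$w, pseudocount = model$pseudocount, n0 = model$n0,
              stop_alpha = model$stop_alpha, interpolate = model$interpolate,
              trained_bp = model$trained_bp, n_windows = model$n_windows,
              split_pos = model$nodes$split_pos,
              children = as.vector(model$nodes$children),
              node_windows = model$nodes$n_windows,
              lambda = model$nodes$lambda,
              raw_dist = as.vector(model$nodes$raw_dist),
              interp_dist = as.vector(model$nodes$interp_dist))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_icm
#' @export
read_icm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "scimmr-icm"))
    stopf("%s is not a scimmr ICM file", path)
  nn <- length(obj$split_pos)
  structure(list(w = as.integer(obj$w), pseudocount = obj$pseudocount,
                 n0 = obj$n0, stop_alpha = obj$stop_alpha,
                 interpolate = obj$interpolate, trained_bp = obj$trained_bp,
                 n_windows = obj$n_windows,
                 nodes = list(split_pos = as.integer(obj$split_pos),
                              children = matrix(as.integer(obj$children), nn, 4),
                              n_windows = obj$node_windows,
                              lambda = obj$lambda,
                              raw_dist = matrix(obj$raw_dist, nn, 4),
                              interp_dist = matrix(obj$interp_dist, nn, 4))),
            class = "icm_model")
}
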