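# internal: CML = sum_i [ log p_{z_i} + log P(s_i | model_{z_i}) ]
cml_value <- function(set, assignment, models, priors,
                      strand_mode = "forward") {
  cl <- as_assignment(assignment)[set$id]
  if (anyNA(cl)) stopf("assignment does not cover every sequence")
  total <- 0
  for (k in sort(unique(cl))) {
    idx <- which(cl == k)
    mdl <- if (k + 1 <= length(models)) models[[k + 1]] else NULL
    if (is.null(mdl)) stopf("no model for non-empty cluster %d", k)
    pk <- priors[k + 1]
    if (pk <= 0) stopf("zero prior for non-empty cluster %d", k)
    sc <- score_sequences(mdl, subset_seqs(set, idx), strand_mode)
    total <- total + sum(log(pk) + sc)
  }
  total
}

#' Classification maximum likelihood criterion of a cluster state
#'
#' The hard-assignment log-likelihood
#' `sum_k sum_{i in C_k} [log p_k + log P(s_i | model_k)]`.  Empty clusters
#' contribute nothing.  This is the objective the clustering loop locally
#' maximises.
#'
#' @param state a [run_scimm()] result.
#' @param set the [seq_set()] that was clustered.
#' @return float (log scale).
#' @export
cml_criterion <- function(state, set) {
  stopifnot(inherits(state, "scimm_state"))
  cml_value(set, state$assignment, state$models, state$priors,
            state$strand_mode)
}

#' Re-train per-cluster models and priors from an assignment
#'
#' Trains one ICM per non-empty cluster on its member sequences and sets the
#' cluster priors to their bp share (consistent with the bp-weighted
#' accuracy measures; the multinomial is over sequenced bases, not read
#' counts).  The assignment may cover only a subset of `set` -- that is how
#' initial models are trained on a subsample.
#'
#' @param set a [seq_set()].
#' @param assignment named integer cluster assignment.
#' @param w ICM window width.
#' @param prior_weight `"bp"` (default) weights priors by cluster bases;
#'   `"count"` by sequence counts.  Count weighting is the exact maximum
#'   likelihood M-step for the CML prior term (needed for the classical CEM
#'   monotonicity guarantee); bp weighting matches the bp-weighted view of
#'   abundance used everywhere else.
#' @param ... further arguments to [train_icm()].
#' @return list with `models` (list indexed by cluster id + 1; `NULL` for
#'   empty ids) and `priors` (numeric, sums to 1 over non-empty clusters).
#' @export
retrain_step <- function(set, assignment, w = 8L,
                         prior_weight = c("bp", "count"), ...) {
  prior_weight <- match.arg(prior_weight)
  cl <- as_assignment(assignment)
  cl <- cl[names(cl) %in% set$id]
  if (length(cl) == 0) stopf("assignment covers no sequence of the set")
  K <- max(cl) + 1L
  models <- vector("list", K)
  priors <- numeric(K)
  bp <- nchar(set$seq)
  names(bp) <- set$id
  for (k in 0:(K - 1L)) {
    ids <- names(cl)[cl == k]
    if (length(ids) == 0) next
    models[[k + 1]] <- train_icm(subset_seqs(set, ids), w = w, ...)
    priors[k + 1] <- if (prior_weight == "bp") sum(bp[ids]) else length(ids)
  }
  priors <- priors / sum(priors)
  list(models = models, priors = priors)
}

#' Maximum-posterior reassignment of every sequence
#'
#' Independently per sequence, picks the cluster maximising
#' `log p_k + log P(s | model_k)`.  Ties break toward the lowest cluster
#' index; clusters with no model never win.
#'
#' @param set a [seq_set()].
#' @param models,priors as produced by [retrain_step()].
#' @param strand_mode passed to [score_sequences()].
#' @return named integer assignment; attribute `posterior` carries each
#'   sequence's winning posterior (used for empty-cluster repair).
#' @export
assign_step <- function(set, models, priors, strand_mode = "forward") {
  K <- length(models)
  n <- length(set$id)
  post <- matrix(-Inf, n, K)
  for (k in seq_len(K)) {
    if (is.null(models[[k]]) || priors[k] <= 0) next
    post[, k] <- log(priors[k]) + score_sequences(models[[k]], set, strand_mode)
  }
  best <- max.col(post, ties.method = "first")
  a <- structure(best - 1L, names = set$id)
  attr(a, "posterior") <- post[cbind(seq_len(n), best)]
  a
}

# move the globally worst-scoring sequences into dead clusters so K survives
repair_empty_clusters <- function(assignment, K) {
  post <- attr(assignment, "posterior")
  used <- unique(assignment)
  dead <- setdiff(0:(K - 1L), used)
  if (length(dead) == 0) return(assignment)
  ord <- order(post) # worst first
  taken <- 0L
  for (k in dead) {
    repeat {
      taken <- taken + 1L
      i <- ord[taken]
      # never empty a singleton cluster by stealing its only member
      if (sum(assignment == assignment[i]) > 1) break
    }
    assignment[i] <- k
  }
  assignment
}

#' Iterative model-based clustering of sequences (classification EM)
#'
#' Alternates [retrain_step()] and [assign_step()] from an initial partition:
#' train one ICM per cluster, score every sequence under every model,
#' reassign each to its maximum-posterior cluster, and repeat until fewer
#' than `converge_frac` of the sequences change cluster (default 0.1%, the
#' point past which iterations shuffle a negligible handful of sequences) or
#' `max_iters` is hit.  The initial assignment may cover only a subsample:
#' it only seeds the first round of models, and every sequence is scored and
#' assigned from the first iteration on.  A cluster that loses all members
#' is reseeded with the worst-posterior sequence so `k` clusters survive.
#'
#' Because ICM training is heuristic rather than exact maximum likelihood,
#' the CML criterion is not guaranteed to increase monotonically; in oracle
#' mode (`interpolate = FALSE`, `min_split_windows = 1`, giving exact
#' fixed-order chains) the classical CEM monotonicity holds.
#'
#' @param set a [seq_set()].
#' @param k number of clusters to maintain.
#' @param init named integer assignment with at most `k` clusters (e.g. from
#'   [compostbin_partition()], [likelybin_partition()], [physcimm_seed()]).
#' @param w ICM window width (default 8).
#' @param max_iters iteration cap (default 100); the halting rule fired well
#'   before this in every experiment we ran, but the theoretical guarantee
#'   is forfeited with ICM heuristics, so a cap is kept.
#' @param converge_frac halting threshold on the fraction of sequences that
#'   changed cluster (default 0.001).
#' @param strand_mode passed to [score_sequences()].
#' @param prior_weight see [retrain_step()].
#' @param quiet suppress per-iteration messages.
#' @param ... further arguments to [train_icm()].
#' @return object of class `scimm_state`: `assignment` (compacted),
#'   `models`, `priors`, `cml`, `iteration`, `converged` and a per-iteration
#'   `history` data.frame (`iter`, `changed`, `cml`).
#' @export
run_scimm <- function(set, k, init, w = 8L, max_iters = 100L,
                      converge_frac = 0.001, strand_mode = "forward",
                      prior_weight = c("bp", "count"), quiet = FALSE, ...) {
  prior_weight <- match.arg(prior_weight)
  stopifnot(k >= 1)
  init <- as_assignment(init)
  if (max(init) + 1L > k)
    stopf("initial partition has %d clusters but k = %d", max(init) + 1L, k)
  n <- length(set$id)
  prev <- if (all(set$id %in% names(init))) init[set$id] else NULL
  assignment <- init
  history <- data.frame(iter = integer(), changed = integer(),
                        cml = numeric())
  models <- NULL; priors <- NULL
  converged <- FALSE
  iter <- 0L
  while (iter < max_iters) {
    iter <- iter + 1L
    mp <- retrain_step(set, assignment, w = w, prior_weight = prior_weight,
                       ...)
    # pad to K = k so reseeded clusters keep their slot
    length(mp$models) <- max(length(mp$models), k)
    mp$priors <- c(mp$priors, numeric(k - length(mp$priors)))
    a <- assign_step(set, mp$models, mp$priors, strand_mode)
    cml <- cml_value(set, a, mp$models, mp$priors, strand_mode)
    a <- repair_empty_clusters(a, k)
    changed <- if (is.null(prev)) n else sum(a != prev)
    history <- rbind(history,
                     data.frame(iter = iter, changed = changed, cml = cml))
    if (!quiet)
      message(sprintf("iter %3d: %6d changed, CML = %.2f", iter, changed, cml))
    prev <- a
    assignment <- a
    models <- mp$models
    priors <- mp$priors
    if (changed / n < converge_frac) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf("halting rule did not fire within %d iterations", max_iters))
  lev <- sort(unique(as.integer(assignment)))
  # a cluster reseeded on the last iteration has members but no model yet
  for (kk in lev) {
    if (is.null(models[[kk + 1L]])) {
      ids <- names(assignment)[assignment == kk]
      models[[kk + 1L]] <- train_icm(subset_seqs(set, ids), w = w, ...)
      priors[kk + 1L] <- sum(nchar(subset_seqs(set, ids)$seq)) / total_bp(set)
    }
  }
  compacted <- structure(match(as.integer(assignment), lev) - 1L,
                         names = names(assignment))
  structure(list(assignment = compacted,
                 models = models[lev + 1L],
                 priors = priors[lev + 1L] / sum(priors[lev + 1L]),
                 cml = history$cml[nrow(history)],
                 iteration = iter, converged = converged,
                 strand_mode = strand_mode, history = history),
            class = "scimm_state")
}

#' @export
print.scimm_state <- function(x, ...) {
  cat(sprintf(
    "scimm_state: %d sequences in %d clusters after %d iterations%s\n",
    length(x$assignment), length(unique(x$assignment)), x$iteration,
    if (x$converged) " (converged)" else " (iteration cap hit)"))
  cat(sprintf("  CML = %.2f; priors: %s\n", x$cml,
              paste(sprintf("%.3f", x$priors), collapse = " ")))
  invisible(x)
}

#' Read a sequence classification table
#' @param path two-column TSV (sequence id, taxon label), no header.
#' @return data.frame with columns `id`, `label`.
#' @export
read_classifications <- function(path) {
  if (!file.exists(path)) stopf("classification table not found: %s", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = "character", quote = "")
  names(df) <- c("id", "label")
  if (anyDuplicated(df$id))
    stopf("duplicate sequence id in classification table: %s",
          df$id[duplicated(df$id)][1])
  df
}

#' Seed clusters from supervised taxonomic classifications
#'
#' Groups sequences by taxon label and keeps only groups holding more than
#' `20/k_expected` percent of the classified bases (a mixture of `k` genomes
#' in random proportions has a mean abundance of `100/k`%, so the filter
#' keeps groups above a fifth of that -- 1% for 20 genomes).  Everything
#' else -- filtered groups and unclassified sequences -- lands in one extra
#' catch-all cluster, so noisy labels are not forced into the high-quality
#' seeds.  The number of clusters returned is data-driven, not forced to
#' `k_expected`.
#'
#' @param set a [seq_set()].
#' @param table data.frame (`id`, `label`) as from [read_classifications()];
#'   sequences absent from it count as unclassified.
#' @param k_expected expected number of genomes in the mixture.
#' @return named integer assignment covering all of `set`; kept groups get
#'   ids `0..m-1` in decreasing bp order, the catch-all (if non-empty) id
#'   `m`.  Attribute `threshold_frac` records the filter threshold.
#' @export
physcimm_seed <- function(set, table, k_expected) {
  stopifnot(k_expected >= 1)
  thr <- (20 / k_expected) / 100
  bp <- nchar(set$seq)
  names(bp) <- set$id
  a <- structure(rep(NA_integer_, length(set$id)), names = set$id)
  if (!is.null(table) && nrow(table) > 0) {
    table <- table[table$id %in% set$id, , drop = FALSE]
  }
  if (is.null(table) || nrow(table) == 0) {
    a[] <- 0L
    attr(a, "threshold_frac") <- thr
    return(a)
  }
  grp_bp <- tapply(bp[table$id], table$label, sum)
  keep <- names(grp_bp)[grp_bp > thr * sum(grp_bp)]
  keep <- keep[order(-grp_bp[keep])]
  for (ci in seq_along(keep)) {
    ids <- table$id[table$label == keep[ci]]
    a[ids] <- ci - 1L
  }
  a[is.na(a)] <- length(keep)
  # catch-all may be empty, in which case ids are already 0..m-1
  attr(a, "threshold_frac") <- thr
  a
}
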