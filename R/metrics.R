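#' Base-pair weighted cluster-by-genome confusion matrix
#'
#' Entry `(i, j)` is the number of sequenced nucleotides from genome `j`
#' placed in cluster `i`; all evaluation statistics derive from it.
#'
#' @param assignment named integer cluster assignment.
#' @param truth named character vector (or 2-column data.frame) mapping
#'   sequence id to source genome.
#' @param set the evaluated [seq_set()].
#' @return numeric matrix, rows = clusters (named `cluster<i>`), columns =
#'   genome labels.
#' @export
confusion_matrix <- function(assignment, truth, set) {
  assignment <- as_assignment(assignment)
  if (is.data.frame(truth)) {
    t2 <- as.character(truth[[2]])
    names(t2) <- as.character(truth[[1]])
    truth <- t2
  }
  only_a <- setdiff(set$id, names(assignment))
  only_t <- setdiff(set$id, names(truth))
  if (length(only_a) || length(only_t))
    stopf("ids missing from %s: %s",
          if (length(only_a)) "assignment" else "truth",
          paste(utils::head(c(only_a, only_t), 5), collapse = ", "))
  bp <- nchar(set$seq)
  cl <- factor(assignment[set$id])
  gn <- factor(truth[set$id])
  c_ij <- tapply(bp, list(cl, gn), sum, default = 0)
  rownames(c_ij) <- paste0("cluster", rownames(c_ij))
  unclass(c_ij)
}

#' Clustering recall, bp-weighted
#'
#' Per genome `j`, `max_i c_ij / sum_i c_ij`: the fraction of a genome's
#' bases kept together in its best cluster (merging everything gives recall
#' 1).  The global value weights each genome by its sequenced bases.
#'
#' @param c_ij a [confusion_matrix()].
#' @return list with `per_genome` (named vector) and `global` (float in
#'   \[0, 1\]).
#' @export
clustering_recall <- function(c_ij) {
  col_tot <- colSums(c_ij)
  if (any(col_tot == 0)) stopf("genome with zero evaluated bases")
  per <- apply(c_ij, 2, max) / col_tot
  list(per_genome = per, global = sum(col_tot * per) / sum(c_ij))
}

#' Clustering precision, bp-weighted
#'
#' Per cluster `i`, `max_j c_ij / sum_j c_ij`: the fraction of a cluster's
#' bases coming from its dominant genome (all-singleton clustering gives
#' precision 1).  Globally bp-weighted like [clustering_recall()].
#'
#' @param c_ij a [confusion_matrix()].
#' @return list with `per_cluster` and `global`.
#' @export
clustering_precision <- function(c_ij) {
  row_tot <- rowSums(c_ij)
  if (any(row_tot == 0)) stopf("cluster with zero evaluated bases")
  per <- apply(c_ij, 1, max) / row_tot
  list(per_cluster = per, global = sum(row_tot * per) / sum(c_ij))
}

#' Adjusted Rand index between a clustering and the truth partition
#'
#' Chance-corrected pairwise agreement (Hubert-Arabie): the fraction of
#' sequence pairs placed together/apart in both partitions, rescaled so the
#' expectation under random partitions with the same cluster sizes is 0 and
#' identity is 1.  Computed per sequence (unweighted items), the standard
#' definition.
#'
#' @param assignment named integer cluster assignment.
#' @param truth named vector mapping id to genome.
#' @return float <= 1.
#' @export
adjusted_rand <- function(assignment, truth) {
  assignment <- as_assignment(assignment)
  if (is.data.frame(truth)) {
    t2 <- as.character(truth[[2]])
    names(t2) <- as.character(truth[[1]])
    truth <- t2
  }
  ids <- names(assignment)
  if (!setequal(ids, names(truth)))
    stopf("assignment and truth cover different ids")
  if (length(ids) < 2) stopf("adjusted Rand needs at least 2 items")
  tab <- table(assignment, truth[ids])
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n2 <- ch2(length(ids))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1) # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Map truth labels to a higher taxonomic level
#'
#' Applies a strain-to-taxon table (e.g. strain to species or family) to a
#' truth mapping so accuracy can be computed at a coarser level: merging two
#' strains of one species into one cluster then counts as correct.  Labels
#' absent from the map pass through unchanged.
#'
#' @param truth named character vector of labels.
#' @param taxmap data.frame (from label, to label) or named character
#'   vector.
#' @return named character vector of mapped labels.
#' @export
apply_taxmap <- function(truth, taxmap) {
  if (is.data.frame(taxmap)) {
    m <- as.character(taxmap[[2]])
    names(m) <- as.character(taxmap[[1]])
    taxmap <- m
  }
  hit <- truth %in% names(taxmap)
  truth[hit] <- taxmap[truth[hit]]
  truth
}

#' Evaluate a clustering against ground truth
#'
#' Convenience wrapper computing the confusion matrix, bp-weighted recall
#' and precision, and the adjusted Rand index in one call, optionally after
#' mapping truth labels through [apply_taxmap()].
#'
#' @param assignment named integer cluster assignment.
#' @param truth named vector or 2-column data.frame mapping id to genome.
#' @param set the evaluated [seq_set()].
#' @param taxmap optional label map (see [apply_taxmap()]).
#' @return list with `confusion`, `recall`, `precision`, `ari`.
#' @export
eval_clustering <- function(assignment, truth, set, taxmap = NULL) {
  if (is.data.frame(truth)) {
    t2 <- as.character(truth[[2]])
    names(t2) <- as.character(truth[[1]])
    truth <- t2
  }
  if (!is.null(taxmap)) truth <- apply_taxmap(truth, taxmap)
  c_ij <- confusion_matrix(assignment, truth, set)
  list(confusion = c_ij,
       recall = clustering_recall(c_ij),
       precision = clustering_precision(c_ij),
       ari = adjusted_rand(assignment, truth))
}
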