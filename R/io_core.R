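#' Construct a sequence set
#'
#' A `seq_set` is the package's lightweight container for DNA sequences: a
#' list with character vectors `id` and `seq` of equal length.  Sequences are
#' uppercased on construction and every character outside `A`, `C`, `G`, `T`
#' is collapsed to `N` (real reads carry IUPAC ambiguity codes; erroring on
#' them would be hostile).  Ids must be unique, non-empty and free of
#' whitespace; sequences must be non-empty.
#'
#' @param seqs character vector of DNA sequences; names are used as ids when
#'   `ids` is missing.
#' @param ids character vector of sequence identifiers.
#' @return object of class `seq_set`.
#' @export
#' @examples
#' s <- seq_set(c(a = "acgt", b = "ACRT"))
#' s$seq          # "ACGT" "ACNT"
#' total_bp(s)    # 8
seq_set <- function(seqs, ids = names(seqs)) {
  force(ids) # before as.character() strips the names
  seqs <- as.character(seqs)
  if (is.null(ids)) stopf("sequence ids are required (names or `ids`)")
  ids <- as.character(ids)
  if (length(ids) != length(seqs))
    stopf("ids and seqs have different lengths (%d vs %d)",
          length(ids), length(seqs))
  if (anyNA(ids) || any(ids == ""))
    stopf("empty or missing sequence id")
  if (any(grepl("\\s", ids)))
    stopf("sequence ids must not contain whitespace: %s",
          ids[grepl("\\s", ids)][1])
  if (anyDuplicated(ids))
    stopf("duplicate sequence id: %s", ids[duplicated(ids)][1])
  seqs <- toupper(seqs)
  seqs <- gsub("[^ACGT]", "N", seqs)
  if (any(nchar(seqs) == 0)) {
    bad <- ids[nchar(seqs) == 0][1]
    stopf("sequence '%s' is empty", bad)
  }
  structure(list(id = ids, seq = unname(seqs)), class = "seq_set")
}

#' @export
length.seq_set <- function(x) length(x$id)

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("seq_set with %d sequences, %d bp total\n",
              length(x$id), total_bp(x)))
  invisible(x)
}

#' Total number of bases in a sequence set
#' @param set a [seq_set()].
#' @return integer, the summed sequence lengths.
#' @export
total_bp <- function(set) sum(nchar(set$seq))

#' Subset a sequence set by index or id
#' @param set a [seq_set()].
#' @param i integer or character index.
#' @return a `seq_set` with the selected records, input order preserved.
#' @export
subset_seqs <- function(set, i) {
  if (is.character(i)) i <- match(i, set$id)
  if (anyNA(i)) stopf("unknown sequence id in subset")
  seq_set(set$seq[i], set$id[i])
}

#' Read a (multi-)FASTA file
#'
#' The id of each record is the first whitespace-delimited token of its
#' header, so ids stay usable as keys in downstream TSVs.  Sequences are
#' uppercased and non-ACGT characters become `N`.  Gzipped files are handled
#' transparently.
#'
#' @param path path to a FASTA file.
#' @return a [seq_set()], record order preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  dss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(dss))
  if (any(Biostrings::width(dss) == 0)) {
    bad <- names(dss)[Biostrings::width(dss) == 0][1]
    stopf("FASTA entry with empty sequence: '%s'", bad)
  }
  seq_set(as.character(dss), ids)
}

#' Write a sequence set to FASTA
#' @param set a [seq_set()].
#' @param path output file path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(set, path, width = 70L) {
  dss <- Biostrings::DNAStringSet(set$seq)
  names(dss) <- set$id
  Biostrings::writeXStringSet(dss, path, width = width)
  invisible(path)
}

#' Normalise a cluster assignment
#'
#' Assignments map sequence ids to integer cluster ids `0..K-1`.  They are
#' represented as a named integer vector.  `as_assignment()` validates and
#' `compact_assignment()` relabels so the used cluster ids form a contiguous
#' range starting at 0, ordered by first appearance.
#'
#' @param x named integer(ish) vector, or data.frame with columns id and
#'   cluster.
#' @return named integer vector of cluster ids.
#' @export
as_assignment <- function(x) {
  if (is.data.frame(x)) {
    a <- as.integer(x[[2]])
    names(a) <- as.character(x[[1]])
    x <- a
  }
  if (is.null(names(x)) || any(names(x) == ""))
    stopf("assignment must be named by sequence id")
  if (anyDuplicated(names(x)))
    stopf("duplicate id in assignment: %s", names(x)[duplicated(names(x))][1])
  a <- as.integer(x)
  if (anyNA(a) || any(a < 0)) stopf("cluster ids must be integers >= 0")
  names(a) <- names(x)
  a
}

#' @rdname as_assignment
#' @export
compact_assignment <- function(x) {
  x <- as_assignment(x)
  lev <- unique(x)
  out <- match(x, lev) - 1L
  names(out) <- names(x)
  out
}

#' Write clustering results
#'
#' Writes `clusters.tsv` (two tab-separated columns: sequence id, cluster id;
#' no header, LF endings) and one FASTA per non-empty cluster
#' (`cluster-<id>.fa`) containing its members in input order.
#'
#' @param assignment named integer vector (see [as_assignment()]).
#' @param set the [seq_set()] the assignment refers to.
#' @param out_dir output directory, created if needed.
#' @return character vector of written paths, invisibly.
#' @export
write_assignments <- function(assignment, set, out_dir) {
  assignment <- as_assignment(assignment)
  missing <- setdiff(set$id, names(assignment))
  if (length(missing) > 0)
    stopf("sequence id(s) missing from assignment: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cl <- assignment[set$id]
  tsv <- file.path(out_dir, "clusters.tsv")
  con <- file(tsv, open = "wb") # binary: LF endings on every platform
  writeLines(paste(set$id, cl, sep = "\t"), con, sep = "\n")
  close(con)
  paths <- tsv
  for (k in sort(unique(cl))) {
    members <- which(cl == k)
    p <- file.path(out_dir, sprintf("cluster-%d.fa", k))
    write_fasta(subset_seqs(set, members), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a clusters.tsv file
#' @param path two-column TSV (sequence id, cluster id), no header.
#' @return named integer vector of cluster ids.
#' @export
read_clusters_tsv <- function(path) {
  if (!file.exists(path)) stopf("cluster file not found: %s", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = c("character", "integer"))
  as_assignment(df)
}

#' Random whole-sequence subsample reaching a bp target
#'
#' Draws records uniformly at random without replacement until the cumulative
#' length reaches `target_bp` (or the set is exhausted).  Sequences are never
#' split: initial model training tolerates a little overshoot better than
#' truncated reads.  Deterministic for a fixed seed.
#'
#' @param set a [seq_set()].
#' @param target_bp positive integer, the bp budget.
#' @param seed integer RNG seed.
#' @return a `seq_set` whose records are a subset of `set`, in draw order.
#' @export
subsample_bp <- function(set, target_bp, seed = 1L) {
  stopifnot(target_bp >= 1)
  if (total_bp(set) <= target_bp) return(set)
  with_seed(seed, {
    ord <- sample.int(length(set$id))
    cum <- cumsum(nchar(set$seq)[ord])
    take <- ord[seq_len(which(cum >= target_bp)[1])]
    subset_seqs(set, take)
  })
}
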