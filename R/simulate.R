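#' Jensen-Shannon divergence between two discrete distributions
#'
#' In bits; symmetric, bounded by 1 for distributions over any alphabet.
#' Used to guarantee that synthetic genomes carry distinguishable signatures.
#'
#' @param p,q non-negative numeric vectors of equal length; normalised
#'   internally.
#' @return float in \[0, 1\].
#' @export
js_divergence <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

# mean JS divergence between corresponding context rows of two transition
# matrices; the package's notion of distance between Markov parameter sets
markov_param_divergence <- function(t1, t2) {
  mean(vapply(seq_len(nrow(t1)),
              function(r) js_divergence(t1[r, ], t2[r, ]), 0))
}

#' Draw random, mutually divergent Markov chain parameter sets
#'
#' Samples `k` transition tensors with Dirichlet(`alpha`) rows and rejects
#' draws until every pair is at least `min_js` apart (mean per-context
#' Jensen-Shannon divergence, bits).  These parameter sets stand in for the
#' genome signatures of distinct organisms.
#'
#' The defaults (`alpha = 10`, `min_js = 0.01`) give a mean pairwise
#' divergence near 0.03 bits.  That is deliberately modest: real bacterial
#' genome signatures are similar to one another, and mixtures simulated at
#' this level reproduce the difficulty regime reported for mixtures of real
#' genomes (clustering accuracy well below ceiling at short read lengths,
#' improving with longer fragments) instead of a trivially separable
#' caricature.
#'
#' @param k number of parameter sets.
#' @param order chain order (default 3).
#' @param alpha Dirichlet concentration (default 10; smaller values give
#'   more idiosyncratic, easier-to-separate signatures).
#' @param min_js divergence floor between any two sets (default 0.01 bits).
#' @param seed RNG seed.
#' @param max_tries rejection budget.
#' @return list of `k` matrices (`4^order` x 4, rows summing to 1).
#' @export
random_markov_params <- function(k, order = 3L, alpha = 10, min_js = 0.01,
                                 seed = 1L, max_tries = 200L) {
  stopifnot(k >= 1, order >= 0)
  nctx <- 4L^order
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      params <- lapply(seq_len(k), function(i) {
        g <- matrix(stats::rgamma(nctx * 4, shape = alpha), nctx, 4)
        g / rowSums(g)
      })
      ok <- TRUE
      if (k > 1) {
        for (i in seq_len(k - 1)) for (j in (i + 1):k) {
          if (markov_param_divergence(params[[i]], params[[j]]) < min_js) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) return(params)
    }
    stopf("could not draw %d parameter sets with pairwise JS >= %g", k, min_js)
  })
}

#' Sample a synthetic genome from a fixed-order Markov chain
#'
#' @param order chain order.
#' @param transition_params `4^order` x 4 stochastic matrix (contexts in
#'   lexicographic A/C/G/T order, first base most significant).
#' @param length genome length in bp (> order).
#' @param seed RNG seed.
#' @param id record id.
#' @return single-record [seq_set()].
#' @export
generate_markov_genome <- function(order, transition_params, length,
                                   seed = 1L, id = "genome1") {
  transition_params <- as.matrix(transition_params)
  if (nrow(transition_params) != 4^order || ncol(transition_params) != 4)
    stopf("transition_params must be 4^order x 4")
  if (any(transition_params < 0) ||
      any(abs(rowSums(transition_params) - 1) > 1e-8))
    stopf("rows of transition_params must be probabilities summing to 1")
  s <- with_seed(seed,
                 .markov_gen_cpp(as.integer(order), transition_params,
                                 as.integer(length)))
  seq_set(s, ids = id)
}

#' Random abundance profile for a k-genome mixture
#'
#' `k` independent uniform(0, 1) draws, normalised to sum 1 -- so genome
#' abundances vary over an order of magnitude or more, as in environmental
#' mixtures.
#'
#' @param k number of genomes.
#' @param seed RNG seed.
#' @return probability vector of length `k`.
#' @export
sample_abundances <- function(k, seed = 1L) {
  stopifnot(k >= 1)
  with_seed(seed, {
    u <- runif(k)
    u / sum(u)
  })
}

#' Simulate shotgun reads from a genome mixture
#'
#' Each read draws its genome from `abundances`, a uniform start position,
#' and a uniform strand; the read is the (reverse-complemented, for minus
#' strand) substring, error-free.  Use [inject_errors()] for substitution
#' noise.  All provenance is recorded so evaluation has exact ground truth.
#'
#' @param genomes a [seq_set()] of source genomes (each at least `read_len`
#'   long).
#' @param abundances probability vector, one entry per genome.
#' @param n_reads number of reads.
#' @param read_len read length in bp.
#' @param seed RNG seed.
#' @return list with `reads` (a `seq_set`, ids `read000001...`) and `truth`
#'   (data.frame `id`, `genome`, `pos` 0-based, `strand`).
#' @export
simulate_reads <- function(genomes, abundances, n_reads, read_len,
                           seed = 1L) {
  k <- length(genomes$id)
  stopifnot(length(abundances) == k, n_reads >= 1, read_len >= 1)
  if (abs(sum(abundances) - 1) > 1e-6)
    stopf("abundances must sum to 1")
  glen <- nchar(genomes$seq)
  if (any(glen < read_len))
    stopf("genome '%s' is shorter than read_len",
          genomes$id[which(glen < read_len)[1]])
  with_seed(seed, {
    gi <- sample.int(k, n_reads, replace = TRUE, prob = abundances)
    start <- floor(runif(n_reads) * (glen[gi] - read_len + 1)) + 1
    minus <- runif(n_reads) < 0.5
    reads <- substring(genomes$seq[gi], start, start + read_len - 1)
    if (any(minus)) {
      rc <- Biostrings::reverseComplement(
        Biostrings::DNAStringSet(reads[minus]))
      reads[minus] <- as.character(rc)
    }
    ids <- sprintf("read%06d", seq_len(n_reads))
    list(reads = seq_set(reads, ids),
         truth = data.frame(id = ids, genome = genomes$id[gi],
                            pos = as.integer(start - 1),
                            strand = ifelse(minus, "-", "+")))
  })
}

#' Inject uniform substitution errors into reads
#'
#' Every base is independently mis-called with probability `rate`, replaced
#' by one of the three other nucleotides uniformly (substitution-only: no
#' indels).  Truth labels are untouched.
#'
#' @param set a [seq_set()] of reads.
#' @param rate substitution probability per base, in \[0, 1).
#' @param seed RNG seed.
#' @return a `seq_set` with mutated sequences.
#' @export
inject_errors <- function(set, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(set)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    seqs <- set$seq
    lens <- nchar(seqs)
    nerr <- stats::rbinom(length(seqs), lens, rate)
    for (i in which(nerr > 0)) {
      ch <- strsplit(seqs[i], NULL)[[1]]
      pos <- sample.int(lens[i], nerr[i])
      for (p in pos) {
        alt <- bases[bases != ch[p]]
        if (length(alt) == 4) alt <- bases # N stays random ACGT
        ch[p] <- alt[sample.int(length(alt), 1)]
      }
      seqs[i] <- paste(ch, collapse = "")
    }
    seq_set(seqs, set$id)
  })
}

#' Reverse-complement random segments of a sequence
#'
#' Cuts each sequence into segments of roughly `mean_segment` bp and
#' reverse-complements each with probability 1/2.  Real genomes hold
#' protein-coding genes on both strands, which is why their k-mer content is
#' approximately strand-symmetric (Chargaff's second parity rule); a raw
#' Markov-chain sample has no such symmetry, and a forward-strand model
#' could then split reads by strand instead of by genome -- structure that
#' does not exist in real data.  Synthetic genomes are passed through this
#' mosaic step by default.
#'
#' @param set a [seq_set()].
#' @param mean_segment mean segment length in bp (default 10000, a typical
#'   operon-scale strand run).
#' @param seed RNG seed.
#' @return a `seq_set` with the same ids and lengths.
#' @export
strand_mosaic <- function(set, mean_segment = 10000, seed = 1L) {
  with_seed(seed, {
    seqs <- vapply(set$seq, function(s) {
      n <- nchar(s)
      cuts <- unique(pmin(cumsum(
        pmax(500, stats::rexp(ceiling(4 * n / mean_segment), 1 / mean_segment))),
        n))
      starts <- c(1, utils::head(cuts, -1) + 1)
      segs <- substring(s, starts, cuts)
      flip <- runif(length(segs)) < 0.5
      segs[flip] <- revcomp(segs[flip])
      paste(segs, collapse = "")
    }, "", USE.NAMES = FALSE)
    seq_set(seqs, set$id)
  })
}

#' Number of reads giving a fixed sequencing effort
#'
#' For experiments holding total sequenced bp constant while varying read
#' length (halving the length doubles the read count).  Floors the ratio.
#'
#' @param total_bp total sequencing effort in bp.
#' @param read_len read length.
#' @return integer read count.
#' @export
reads_for_total_bp <- function(total_bp, read_len) {
  as.integer(floor(total_bp / read_len))
}

#' Simulate a complete synthetic metagenome
#'
#' End-to-end generator: draws `k` divergent Markov parameter sets, samples
#' one synthetic genome from each, draws random abundances (unless given),
#' simulates reads and injects substitution errors.  With `out_dir` set,
#' writes `reads.fa`, `truth.tsv`, `genomes.fa` and `abundances.tsv`, so a
#' full pipeline run needs no external data.
#'
#' @param k number of genomes.
#' @param n_reads number of reads.
#' @param read_len read length in bp.
#' @param error_rate substitution error rate (default 0).
#' @param seed master RNG seed; all stage seeds derive from it.
#' @param order Markov order of the synthetic genomes (default 3).
#' @param genome_len genome length in bp (default 100000).
#' @param abundances optional fixed abundance vector (sums to 1); random
#'   uniform draws otherwise.
#' @param genomes optional user-supplied [seq_set()] of genomes, replacing
#'   the synthetic ones.
#' @param alpha,min_js signature spread controls for synthetic parameter
#'   sets; see [random_markov_params()].
#' @param mosaic pass synthetic genomes through [strand_mosaic()] so their
#'   k-mer content is approximately strand-symmetric like real genomes
#'   (default `TRUE`); user-supplied genomes are never modified.
#' @param out_dir optional output directory.
#' @return list with `genomes`, `abundances`, `reads` (`seq_set`), `truth`
#'   (data.frame).
#' @export
simulate_metagenome <- function(k, n_reads, read_len, error_rate = 0,
                                seed = 1L, order = 3L, genome_len = 100000L,
                                abundances = NULL, genomes = NULL,
                                alpha = 10, min_js = 0.01, mosaic = TRUE,
                                out_dir = NULL) {
  seed <- as.integer(seed)
  if (is.null(genomes)) {
    params <- random_markov_params(k, order = order, alpha = alpha,
                                   min_js = min_js, seed = seed)
    gs <- lapply(seq_len(k), function(i)
      generate_markov_genome(order, params[[i]], genome_len,
                             seed = seed + i, id = sprintf("genome%d", i)))
    genomes <- seq_set(unlist(lapply(gs, `[[`, "seq")),
                       ids = unlist(lapply(gs, `[[`, "id")))
    if (mosaic)
      genomes <- strand_mosaic(genomes, seed = seed + 500L)
  } else {
    k <- length(genomes$id)
  }
  if (is.null(abundances))
    abundances <- sample_abundances(k, seed = seed + 1000L)
  sim <- simulate_reads(genomes, abundances, n_reads, read_len,
                        seed = seed + 2000L)
  if (error_rate > 0)
    sim$reads <- inject_errors(sim$reads, error_rate, seed = seed + 3000L)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(sim$reads, file.path(out_dir, "reads.fa"))
    write_fasta(genomes, file.path(out_dir, "genomes.fa"))
    write.table(sim$truth[, c("id", "genome")],
                file.path(out_dir, "truth.tsv"), sep = "\t",
                row.names = FALSE, col.names = FALSE, quote = FALSE)
    write.table(data.frame(genomes$id, abundances),
                file.path(out_dir, "abundances.tsv"), sep = "\t",
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  list(genomes = genomes, abundances = abundances,
       reads = sim$reads, truth = sim$truth)
}
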