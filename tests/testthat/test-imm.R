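test_that("build_corpus enumerates windows and drops N overlaps", {
  cc <- build_corpus(seq_set(c(x = "ACGTA")), w = 2)
  expect_equal(cc$context, c("AC", "CG", "GT"))
  expect_equal(cc$outcome, c("G", "T", "A"))
  # sequence shorter than w+1 contributes nothing
  expect_length(build_corpus(seq_set(c(x = "AC")), w = 2)$outcome, 0)
  # windows overlapping an N are excluded
  cc2 <- build_corpus(seq_set(c(x = "ACNGT")), w = 1)
  expect_equal(cc2$context, c("A", "G"))
  expect_equal(cc2$outcome, c("C", "T"))
  # window count over several sequences: sum of max(0, |s| - w)
  set <- seq_set(c(a = "ACGTACGT", b = "ACG", c = "AC"))
  expect_length(build_corpus(set, w = 2)$outcome, 6 + 1 + 0)
})

test_that("mutual_information matches the plug-in entropy oracle", {
  # independence: all 16 pairs equally frequent -> 0 bits
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(ctx = bases, out = bases)
  cc <- structure(list(w = 1L, context = as.character(grid$ctx),
                       outcome = as.character(grid$out)),
                  class = "context_corpus")
  expect_equal(mutual_information(cc, 1), 0)
  # outcome equals the context base, uniform marginal -> 2 bits
  cc2 <- structure(list(w = 1L, context = bases, outcome = bases),
                   class = "context_corpus")
  expect_equal(mutual_information(cc2, 1), 2)
  # skewed joint: check against independent entropy computation
  ctx <- rep(c("A", "A", "C", "C"), c(8, 2, 2, 8))
  out <- rep(c("A", "C", "A", "C"), c(8, 2, 2, 8))
  cc3 <- structure(list(w = 1L, context = ctx, outcome = out),
                   class = "context_corpus")
  expect_equal(mutual_information(cc3, 1), oracle_mi(ctx, out),
               tolerance = 1e-12)
  expect_equal(mutual_information(cc3, 1), 0.2780719, tolerance = 1e-6)
  # position argument is validated
  expect_error(mutual_information(cc3, 2), "position")
})

test_that("interpolate_dist follows the chi-square weighting rule", {
  unif <- rep(0.25, 4)
  # counts exactly proportional to the parent: no evidence, keep parent
  r <- interpolate_dist(c(10, 10, 10, 10), unif)
  expect_equal(r$lambda, 0)
  expect_equal(r$interp_dist, unif)
  # strong divergence with lots of data pushes lambda toward n/(n+n0)
  r2 <- interpolate_dist(c(4000, 0, 0, 0), unif, n0 = 400)
  expect_gt(r2$lambda, 0.89)
  expect_gt(r2$interp_dist[1], 0.9)
  # frozen example: counts (40,0,0,0) vs uniform, N0 = 400.
  # X2 = 90 + 3*10 = 120; lambda = (1 - pchisq(120, 3, upper)) * 40/440
  r3 <- interpolate_dist(c(40, 0, 0, 0), unif, pseudocount = 0.5, n0 = 400)
  lam_oracle <- (1 - pchisq(120, df = 3, lower.tail = FALSE)) * 40 / 440
  expect_equal(r3$lambda, lam_oracle, tolerance = 1e-12)
  emp <- c(40.5, 0.5, 0.5, 0.5) / 42
  expect_equal(r3$interp_dist, lam_oracle * emp + (1 - lam_oracle) * unif,
               tolerance = 1e-12)
  expect_equal(sum(r3$interp_dist), 1, tolerance = 1e-9)
})

test_that("training collapses uninformative context and finds informative positions", {
  set.seed(101)
  # iid uniform sequence: outcome independent of context -> single root leaf
  iid <- seq_set(c(r = rand_dna(5000)))
  m <- train_icm(iid, w = 6)
  expect_length(m$nodes$split_pos, 1)
  expect_equal(m$nodes$split_pos[1], 0)
  # root raw distribution = empirical outcome distribution (positions w+1..n)
  outc <- strsplit(substring(iid$seq, 7, 5000), NULL)[[1]]
  expect_equal(as.vector(m$nodes$raw_dist[1, ]),
               as.vector(table(factor(outc, c("A", "C", "G", "T"))) /
                           length(outc)),
               tolerance = 1e-9)
  # outcome determined by the immediately preceding base -> root splits at w
  doubled <- paste(rep(sample(c("A", "C", "G", "T"), 2000, TRUE), each = 2),
                   collapse = "")
  m2 <- train_icm(seq_set(c(d = doubled)), w = 4, min_split_windows = 10)
  expect_equal(m2$nodes$split_pos[1], 4)
  # MI oracle agrees that position w is the most informative
  cc <- build_corpus(seq_set(c(d = doubled)), w = 4)
  mis <- vapply(1:4, function(p) mutual_information(cc, p), 0)
  expect_equal(which.max(mis), 4L)
  # homopolymer training: matching sequence outscores a divergent one
  m3 <- train_icm(seq_set(c(a = strrep("A", 1000))), w = 3)
  expect_gt(score_sequences(m3, seq_set(c(q = "AAAA"))),
            score_sequences(m3, seq_set(c(q = "ACGT"))))
})

test_that("trained models satisfy structural invariants", {
  set.seed(77)
  set <- seq_set(c(g = rand_dna(20000, prob = c(0.4, 0.25, 0.2, 0.15))))
  m <- train_icm(set, w = 6, min_split_windows = 50)
  nd <- m$nodes
  nn <- length(nd$split_pos)
  expect_true(all(abs(rowSums(nd$interp_dist) - 1) < 1e-9))
  expect_true(all(nd$interp_dist > 0)) # pseudocounts keep everything positive
  expect_true(all(nd$lambda >= 0 & nd$lambda <= 1))
  # walk every root-leaf path: depth <= w, no split position reused,
  # and each node's window count equals the sum over its children
  check <- function(i, depth, used) {
    expect_lte(depth, m$w)
    if (nd$split_pos[i] == 0) return(invisible())
    p <- nd$split_pos[i]
    expect_false(p %in% used)
    kids <- nd$children[i, ]
    expect_equal(sum(nd$n_windows[kids]), nd$n_windows[i])
    for (k in kids) check(k, depth + 1, c(used, p))
  }
  check(1, 0, integer())
})

test_that("scoring follows the tree and handles N and strands", {
  # single-leaf model: score is the sum of leaf probabilities at positions
  # w+1..|s| (iid uniform training data collapses the tree to its root)
  set.seed(5)
  m <- train_icm(seq_set(c(u = rand_dna(4000))), w = 5)
  expect_length(m$nodes$split_pos, 1)
  s10 <- seq_set(c(x = "ACGTACGTAC")) # outcomes 6..10 are C,G,T,A,C
  expect_equal(score_sequences(m, s10),
               sum(log(m$nodes$interp_dist[1, c(2, 3, 4, 1, 2)])),
               tolerance = 1e-9)
  # every window containing an N contributes exactly log(1/4)
  mN <- train_icm(seq_set(c(t = strrep("ACGT", 500))), w = 2)
  expect_equal(score_sequences(mN, seq_set(c(x = strrep("N", 12)))),
               10 * log(0.25), tolerance = 1e-12)
  # sequences no longer than w are rejected
  expect_error(score_sequences(mN, seq_set(c(x = "AC"))), "length")
  # both-max is the max of forward and reverse-complement scores
  set.seed(6)
  gen <- seq_set(c(g = rand_dna(20000, prob = c(0.5, 0.3, 0.1, 0.1))))
  mg <- train_icm(gen, w = 4)
  probe <- seq_set(c(p = substr(gen$seq, 101, 400)))
  probe_rc <- seq_set(revcomp(probe$seq), ids = "prc")
  fwd <- score_sequences(mg, probe)
  rc <- score_sequences(mg, probe_rc)
  expect_equal(score_sequences(mg, probe, strand_mode = "both-max"),
               max(fwd, rc), tolerance = 1e-9)
  expect_equal(score_sequences(mg, probe_rc, strand_mode = "both-max"),
               max(fwd, rc), tolerance = 1e-9)
})

test_that("scores are additive across a split with reconstructed context", {
  set.seed(8)
  m <- train_icm(seq_set(c(g = rand_dna(10000, prob = c(.4, .3, .2, .1)))),
                 w = 5)
  s <- rand_dna(400)
  j <- 250
  whole <- score_sequences(m, seq_set(c(x = s)))
  left <- score_sequences(m, seq_set(c(x = substr(s, 1, j))))
  right <- score_sequences(m, seq_set(c(x = substr(s, j - m$w + 1, 400))))
  expect_equal(whole, left + right, tolerance = 1e-9)
})

test_that("oracle mode reproduces a directly counted fixed-order chain", {
  set.seed(9)
  for (w in c(2, 4)) {
    train <- seq_set(c(t = rand_dna(8000, prob = c(.35, .3, .2, .15))))
    m <- train_icm(train, w = w, min_split_windows = 1, interpolate = FALSE)
    test <- rand_dna(300)
    got <- score_sequences(m, seq_set(c(x = test)))
    expect_equal(got, oracle_chain_score(train$seq, test, w),
                 tolerance = 1e-9)
  }
})

test_that("model serialization round-trips scores exactly", {
  set.seed(10)
  m <- train_icm(seq_set(c(g = rand_dna(5000, prob = c(.4, .1, .4, .1)))),
                 w = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_icm(m, path)
  m2 <- read_icm(path)
  probe <- seq_set(c(p = rand_dna(500)))
  expect_equal(score_sequences(m, probe), score_sequences(m2, probe),
               tolerance = 1e-12)
  expect_equal(m2$w, m$w)
  expect_error(read_icm(write_tmp_fasta(c("{}"))), "not a scimmr ICM")
})

test_that("scores discriminate the training source from a divergent one", {
  # a sequence scores at least as well under its own source's model
  wins <- 0
  for (sd in 1:20) {
    sim <- simulate_metagenome(k = 2, n_reads = 2, read_len = 1000,
                               seed = sd, genome_len = 20000)
    g1 <- subset_seqs(sim$genomes, 1)
    g2 <- subset_seqs(sim$genomes, 2)
    m1 <- train_icm(g1, w = 6)
    m2 <- train_icm(g2, w = 6)
    probe <- seq_set(c(p = substr(g1$seq, 5001, 6000)))
    if (score_sequences(m1, probe) >= score_sequences(m2, probe))
      wins <- wins + 1
  }
  expect_gte(wins, 19)
})
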