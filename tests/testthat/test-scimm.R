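test_that("cml_criterion matches hand-computed sums on fixed leaf models", {
  # two single-leaf models with known distributions, priors (0.5, 0.5)
  leaf_model <- function(dist, w = 0L) {
    structure(list(w = w, pseudocount = 0.5, n0 = 400, stop_alpha = 0.05,
                   interpolate = TRUE, trained_bp = 0, n_windows = 0,
                   nodes = list(split_pos = 0L,
                                children = matrix(0L, 1, 4),
                                n_windows = 0, lambda = 0,
                                raw_dist = matrix(dist, 1, 4),
                                interp_dist = matrix(dist, 1, 4))),
              class = "icm_model")
  }
  m1 <- leaf_model(c(0.7, 0.1, 0.1, 0.1))
  m2 <- leaf_model(c(0.1, 0.1, 0.1, 0.7))
  set <- seq_set(c(s1 = "AAAA", s2 = "TTTT", s3 = "AATT"))
  a <- c(s1 = 0L, s2 = 1L, s3 = 0L)
  # hand sum: w = 0 scores every position
  expected <- (4 * log(0.7) + log(0.5)) + (4 * log(0.7) + log(0.5)) +
    (2 * log(0.7) + 2 * log(0.1) + log(0.5))
  got <- cml_value(set, a, list(m1, m2), c(0.5, 0.5))
  expect_equal(got, expected, tolerance = 1e-12)
  # K = 1: no prior cost
  expect_equal(cml_value(set, c(s1 = 0L, s2 = 0L, s3 = 0L), list(m1), 1),
               sum(score_sequences(m1, set)), tolerance = 1e-12)
  # moving a sequence to its argmax cluster cannot decrease CML
  a_post <- assign_step(set, list(m1, m2), c(0.5, 0.5))
  expect_gte(cml_value(set, a_post, list(m1, m2), c(0.5, 0.5)), got)
})

test_that("assign_step takes the maximum posterior with low-index ties", {
  sim <- small_mixture(51, n_reads = 40)
  mp <- retrain_step(sim$reads, structure(rep(0:1, 20), names = sim$reads$id),
                     w = 4)
  # same model twice, unequal priors: the larger prior must win everywhere
  a <- assign_step(sim$reads, list(mp$models[[1]], mp$models[[1]]),
                   c(0.9, 0.1))
  expect_true(all(a == 0L))
  # equal likelihoods and equal priors: lowest index
  a2 <- assign_step(sim$reads, list(mp$models[[1]], mp$models[[1]]),
                    c(0.5, 0.5))
  expect_true(all(a2 == 0L))
  # K = 1
  a3 <- assign_step(sim$reads, mp$models[1], 1)
  expect_true(all(a3 == 0L))
  # posterior attribute holds the winning score
  expect_length(attr(a, "posterior"), 40)
})

test_that("retrain_step trains per-cluster models with bp-share priors", {
  set <- seq_set(c(a = strrep("AC", 300), b = strrep("A", 400)))
  mp <- retrain_step(set, c(a = 0L, b = 1L), w = 2)
  expect_equal(mp$priors, c(0.6, 0.4))
  expect_length(mp$models, 2)
  # single cluster: prior 1
  mp1 <- retrain_step(set, c(a = 0L, b = 0L), w = 2)
  expect_equal(mp1$priors, 1)
  # assignment covering a subset trains only on that subset
  mps <- retrain_step(set, c(a = 0L), w = 2)
  expect_equal(mps$priors, 1)
  expect_equal(mps$models[[1]]$trained_bp, 600)
})

test_that("the CEM loop halts, reaches a fixed point, and compacts ids", {
  sim <- small_mixture(52, n_reads = 300)
  truth <- truth_vector(sim)
  init <- compostbin_partition(sim$reads, 2, seed = 52)
  st <- run_scimm(sim$reads, 2, init, w = 6, quiet = TRUE)
  expect_s3_class(st, "scimm_state")
  expect_true(st$converged)
  expect_equal(sort(unique(unname(st$assignment))), 0:1)
  expect_equal(sum(st$priors), 1, tolerance = 1e-9)
  expect_true(is.finite(st$cml))
  expect_equal(cml_criterion(st, sim$reads), st$cml, tolerance = 1e-6)
  # restarting from the converged assignment immediately converges again
  st2 <- run_scimm(sim$reads, 2, st$assignment, w = 6, quiet = TRUE)
  expect_lte(st2$history$changed[nrow(st2$history)],
             0.001 * length(sim$reads$id))
  # k = 1 converges in one iteration with everything in cluster 0
  st1 <- run_scimm(sim$reads, 1, structure(rep(0L, 300),
                                           names = sim$reads$id),
                   w = 6, quiet = TRUE)
  expect_equal(st1$iteration, 1L)
  expect_true(all(st1$assignment == 0L))
})

test_that("initial partitions of a subsample still cluster the full set", {
  sim <- small_mixture(53, n_reads = 300)
  sub <- subsample_bp(sim$reads, 30000, seed = 53)
  expect_lt(length(sub$id), 300)
  init <- compostbin_partition(sub, 2, seed = 53)
  st <- run_scimm(sim$reads, 2, init, w = 6, quiet = TRUE)
  expect_setequal(names(st$assignment), sim$reads$id)
  expect_gte(adjusted_rand(st$assignment, truth_vector(sim)), 0.9)
})

test_that("label-permuted initialisation yields the same partition up to labels", {
  sim <- small_mixture(54, n_reads = 200)
  init <- compostbin_partition(sim$reads, 2, seed = 54)
  flipped <- structure(1L - unname(init), names = names(init))
  st_a <- run_scimm(sim$reads, 2, init, w = 6, quiet = TRUE)
  st_b <- run_scimm(sim$reads, 2, flipped, w = 6, quiet = TRUE)
  expect_equal(adjusted_rand(st_a$assignment,
                             structure(st_b$assignment,
                                       names = names(st_b$assignment))), 1)
})

test_that("an emptied cluster is reseeded so k survives", {
  sim <- small_mixture(55, n_reads = 60)
  # deliberately put a single sequence in cluster 2; CEM will usually
  # absorb it, and repair must keep 3 clusters alive through the run
  ids <- sim$reads$id
  init <- structure(c(2L, rep(0:1, length.out = 59)), names = ids)
  st <- run_scimm(sim$reads, 3, init, w = 4, quiet = TRUE)
  expect_equal(sort(unique(unname(st$assignment))), 0:2)
})

test_that("physcimm_seed applies the 20/k% filter with a catch-all cluster", {
  # k = 20 genomes: threshold is 1% of classified bp
  set <- seq_set(c(big1 = strrep("A", 600), big2 = strrep("C", 300),
                   tiny = strrep("G", 5), un = strrep("T", 100)))
  table <- data.frame(id = c("big1", "big2", "tiny"),
                      label = c("famA", "famB", "famC"))
  a <- physcimm_seed(set, table, k_expected = 20)
  expect_equal(attr(a, "threshold_frac"), 0.01)
  # famA and famB pass 1% of 905 bp; famC (5 bp ~ 0.55%) is filtered
  expect_equal(unname(a[c("big1", "big2")]), c(0L, 1L))
  expect_equal(unname(a["tiny"]), unname(a["un"])) # both in catch-all
  expect_equal(unname(a["un"]), 2L)
  # k = 10: threshold 2%
  expect_equal(attr(physcimm_seed(set, table, 10), "threshold_frac"), 0.02)
  # all groups pass, nothing unclassified: no catch-all emitted
  set2 <- seq_set(c(x = strrep("A", 60), y = strrep("C", 40)))
  t2 <- data.frame(id = c("x", "y"), label = c("f1", "f2"))
  a2 <- physcimm_seed(set2, t2, 5) # threshold 4%
  expect_equal(sort(unique(unname(a2))), 0:1)
  # empty table: one catch-all cluster
  a3 <- physcimm_seed(set2, NULL, 5)
  expect_true(all(a3 == 0L))
})

test_that("classification tables parse and reject duplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("r1\tEscherichia", "r2\tBacillus"), path)
  tab <- read_classifications(path)
  expect_equal(tab$label, c("Escherichia", "Bacillus"))
  writeLines(c("r1\ta", "r1\tb"), path)
  expect_error(read_classifications(path), "duplicate")
})
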