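# fixture builders shared across test files

rand_dna <- function(n, prob = NULL) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# small two-source mixture used by several CEM tests
small_mixture <- function(seed, n_reads = 200, read_len = 500, k = 2,
                          genome_len = 40000, error_rate = 0) {
  simulate_metagenome(k = k, n_reads = n_reads, read_len = read_len,
                      error_rate = error_rate, seed = seed,
                      genome_len = genome_len)
}

truth_vector <- function(sim) {
  structure(sim$truth$genome, names = sim$truth$id)
}

write_tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
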