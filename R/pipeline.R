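#' Build and validate a pipeline run configuration
#'
#' @param input path to the input FASTA of reads or contigs.
#' @param k number of clusters.
#' @param out_dir output directory.
#' @param init initialisation mode: `"both"` (default; composition bisection
#'   plus Markov MCMC, winner picked by CML), `"compostbin"`, `"likelybin"`,
#'   `"random"`, or `"file"`.
#' @param init_file `clusters.tsv` providing the initial partition when
#'   `init = "file"`.
#' @param w ICM window width.
#' @param seed master RNG seed.
#' @param subsample_bp bp budget for the initialisation subsample (default
#'   3e6; initialisers are slow on large sets and a few Mb suffices to train
#'   the first round of models).
#' @param converge_frac halting threshold (fraction of sequences changing
#'   cluster, default 0.001).
#' @param max_iters iteration cap.
#' @param strand_mode `"forward"` or `"both-max"`.
#' @param classifications optional TSV (id, taxon label) enabling
#'   classification-seeded mode: the initial partition comes from
#'   [physcimm_seed()] and `k` is taken as the expected number of genomes.
#' @param truth optional TSV (id, genome) triggering evaluation output.
#' @return validated list of class `scimm_config`.
#' @export
scimm_config <- function(input, k, out_dir, init = "both", init_file = NULL,
                         w = 8L, seed = 1L, subsample_bp = 3e6,
                         converge_frac = 0.001, max_iters = 100L,
                         strand_mode = "forward", classifications = NULL,
                         truth = NULL) {
  problems <- character()
  if (!file.exists(input))
    problems <- c(problems, sprintf("input FASTA not found: %s", input))
  if (!is.numeric(k) || k < 1)
    problems <- c(problems, "k must be an integer >= 1")
  if (!(init %in% c("both", "compostbin", "likelybin", "random", "file")))
    problems <- c(problems, sprintf("unknown init mode '%s'", init))
  if (init == "file" && (is.null(init_file) || !file.exists(init_file)))
    problems <- c(problems, "init = 'file' needs an existing init_file")
  if (!is.null(classifications) && !file.exists(classifications))
    problems <- c(problems,
                  sprintf("classification table not found: %s", classifications))
  if (!is.null(truth) && !file.exists(truth))
    problems <- c(problems, sprintf("truth table not found: %s", truth))
  if (converge_frac <= 0 || converge_frac >= 1)
    problems <- c(problems, "converge_frac must be in (0, 1)")
  if (length(problems) > 0)
    stopf("invalid configuration:\n  - %s", paste(problems, collapse = "\n  - "))
  structure(list(input = input, k = as.integer(k), out_dir = out_dir,
                 init = init, init_file = init_file, w = as.integer(w),
                 seed = as.integer(seed), subsample_bp = subsample_bp,
                 converge_frac = converge_frac,
                 max_iters = as.integer(max_iters),
                 strand_mode = strand_mode,
                 classifications = classifications, truth = truth),
            class = "scimm_config")
}

#' Run the full clustering pipeline
#'
#' Reads the input FASTA, initialises a partition on a bp-capped subsample
#' (mode per `cfg$init`, or from supervised classifications when
#' `cfg$classifications` is set), runs the iterative clustering loop on the
#' full set, and writes `clusters.tsv`, one FASTA per cluster, a run log
#' with per-iteration change counts and CML, a config echo, and -- when a
#' truth table is supplied -- an evaluation report.  Fully reproducible from
#' the inputs and the seed.
#'
#' @param cfg a [scimm_config()].
#' @return the final `scimm_state`, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "scimm_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "log.txt")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    writeLines(line, log_con)
    message(line)
  }

  set <- read_fasta(cfg$input)
  logmsg("input: %d sequences, %d bp", length(set$id), total_bp(set))
  sub <- subsample_bp(set, cfg$subsample_bp, seed = cfg$seed)
  logmsg("initialisation subsample: %d sequences, %d bp",
         length(sub$id), total_bp(sub))

  k_run <- cfg$k
  if (!is.null(cfg$classifications)) {
    table <- read_classifications(cfg$classifications)
    init <- physcimm_seed(sub, table, k_expected = cfg$k)
    k_run <- max(init) + 1L
    logmsg("classification seeding: %d clusters (filter > %.2f%% of bp)",
           k_run, attr(init, "threshold_frac") * 100)
  } else {
    init <- switch(cfg$init,
      compostbin = compostbin_partition(sub, cfg$k, seed = cfg$seed),
      likelybin = likelybin_partition(sub, cfg$k, seed = cfg$seed),
      random = with_seed(cfg$seed, structure(
        sample.int(cfg$k, length(sub$id), replace = TRUE) - 1L,
        names = sub$id)),
      file = read_clusters_tsv(cfg$init_file),
      both = {
        cands <- list(
          compostbin = compostbin_partition(sub, cfg$k, seed = cfg$seed),
          likelybin = likelybin_partition(sub, cfg$k, seed = cfg$seed))
        sel <- select_initialization(cands, set, w = cfg$w)
        logmsg("dual initialisation: %s wins (CML %.2f)",
               names(cands)[attr(sel, "which")], attr(sel, "cml"))
        sel
      })
  }

  state <- withCallingHandlers(
    run_scimm(set, k_run, init, w = cfg$w, max_iters = cfg$max_iters,
              converge_frac = cfg$converge_frac,
              strand_mode = cfg$strand_mode, quiet = FALSE),
    message = function(m) writeLines(sub("\n$", "", conditionMessage(m)),
                                     log_con),
    warning = function(w) {
      writeLines(paste("warning:", conditionMessage(w)), log_con)
      invokeRestart("muffleWarning")
    })

  write_assignments(state$assignment, set, cfg$out_dir)
  cfg_echo <- vapply(names(unclass(cfg)), function(nm) {
    v <- cfg[[nm]]
    sprintf("%s=%s", nm, if (is.null(v)) "" else as.character(v))
  }, "")
  writeLines(c(cfg_echo,
               sprintf("package_version=%s",
                       as.character(utils::packageVersion("scimmr"))),
               sprintf("r_version=%s", R.version.string)),
             file.path(cfg$out_dir, "config.txt"))

  if (!is.null(cfg$truth)) {
    truth <- read.table(cfg$truth, sep = "\t", header = FALSE,
                        colClasses = "character")
    ev <- eval_clustering(state$assignment, truth, set)
    rep_path <- file.path(cfg$out_dir, "metrics.txt")
    writeLines(c(
      sprintf("global_recall\t%.6f", ev$recall$global),
      sprintf("global_precision\t%.6f", ev$precision$global),
      sprintf("adjusted_rand\t%.6f", ev$ari)), rep_path)
    logmsg("evaluation: recall %.3f, precision %.3f, ARI %.3f",
           ev$recall$global, ev$precision$global, ev$ari)
  }
  invisible(state)
}
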