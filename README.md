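# scimmr

Unsupervised clustering ("binning") of metagenomic DNA sequences with
interpolated Markov models, in R.

Environmental shotgun sequencing returns reads of unknown origin, and most
of the organisms in a typical sample have no sequenced relative — so the
crucial first analysis step, grouping reads by source organism, often
cannot lean on reference databases. scimmr clusters sequences using only
their own composition: each cluster is modelled by an **interpolated
context model** (ICM), a probabilistic decision tree over the most
informative positions of a `w`-wide context window, and a hard-assignment
**classification EM** loop alternately re-trains the per-cluster models and
reassigns every sequence to the cluster maximising the posterior
`log p_k + log P(s | m_k)`, locally maximising the classification maximum
likelihood (CML) criterion

```
CML(C, p, u) = sum_k sum_{x_i in C_k} log( p_k f(x_i; u_k) ).
```

The loop halts when fewer than 0.1% of sequences change cluster. Because
the likelihood landscape is full of local maxima, the pipeline initialises
from two established composition-based methods — spectral bisection of
5-mer profiles (PCA + normalized cut of a kNN graph) and a Markov-chain
MCMC — and keeps whichever start yields the greater CML after one
iteration. When supervised taxonomic classifications are available,
clusters can instead be seeded from them, keeping only taxon groups holding
more than `20/k`% of the classified bases and pooling the rest into a
catch-all cluster.

The package is self-contained for testing: it simulates mixtures of
synthetic genomes (strand-mosaic order-3 Markov chains) in random
proportions, with configurable read length and substitution error rate, and
evaluates clusterings by bp-weighted recall and precision and the adjusted
Rand index.

Intended users: metagenomics researchers binning reads or contigs from
low-to-moderate complexity communities, and method developers who need a
transparent, fully scriptable reference implementation of ICM-based
clustering.

## Worked example

Simulate a two-genome mixture, cluster it with the default dual
initialisation, and evaluate against the recorded ground truth:

```r
library(scimmr)

sim <- simulate_metagenome(k = 2, n_reads = 500, read_len = 800,
                           seed = 7, genome_len = 60000,
                           out_dir = "demo")
cfg <- scimm_config("demo/reads.fa", k = 2, out_dir = "demo/run",
                    seed = 7, truth = "demo/truth.tsv")
state <- run_pipeline(cfg)
```

which logs (output from this exact script):

```
input: 500 sequences, 400000 bp
initialisation subsample: 500 sequences, 400000 bp
dual initialisation: compostbin wins (CML -532917.82)
iter   1:      0 changed, CML = -532917.82
evaluation: recall 1.000, precision 1.000, ARI 1.000
```

`dual initialisation` reports which initialiser's partition won the CML
comparison; each `iter` line gives the number of sequences that changed
cluster and the CML criterion, and the run stops once fewer than 0.1%
(here: 0) of sequences move. With ground truth supplied, the final line
reports bp-weighted recall and precision and the adjusted Rand index —
1.000 means the two planted genomes were recovered exactly. `demo/run/`
then contains `clusters.tsv` (sequence id, cluster id), one FASTA per
cluster, the run log, a config echo, and `metrics.txt`.

The same run from the shell:

```sh
scimm simulate --k 2 --n-reads 500 --read-len 800 --genome-len 60000 --seed 7 --out demo
scimm cluster --k 2 --seed 7 --truth demo/truth.tsv --out demo/run demo/reads.fa
scimm eval --truth demo/truth.tsv demo/run/clusters.tsv demo/reads.fa
```

(`scimm` is installed to the package's `exec/` directory; call it as
`$(Rscript -e 'cat(system.file("exec/scimm", package="scimmr"))')` or add
that directory to `PATH`.)

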