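---
title: "Methods: model-based clustering of metagenomic sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model-based clustering of metagenomic sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scimmr)
```

## The problem

Environmental shotgun sequencing yields reads of unknown origin. Binning —
grouping reads by their (unknown) source organism — exploits the *genome
signature*: oligonucleotide usage is fairly constant within a genome and
diverse between genomes. scimmr clusters sequences entirely unsupervised by
fitting one probabilistic sequence model per cluster and iterating between
model fitting and reassignment, optionally seeded from supervised taxonomic
classifications when related genomes happen to be available.

## The cluster model: interpolated context models

Each cluster is modelled by an interpolated context model (ICM), a
variable-order relative of a fixed order-$w$ Markov chain. The likelihood of
a sequence $s$ under a model $m$ is

$$\log P(s \mid m) = \sum_{i = w+1}^{|s|} \log P_m(s_i \mid s_{i-w} \ldots s_{i-1}),$$

each conditional read off a decision tree over the $w$ context positions.
Training considers every $(w{+}1)$-wide window of the cluster's sequences.
At the root, the context position with the greatest mutual information with
the predicted base is split into four branches (one per nucleotide); each
child repeats the choice among the remaining positions on the windows that
reach it. A path stops growing when

* fewer than `min_split_windows` windows reach the node (data too sparse),
* all $w$ positions are used, or
* a chi-square test cannot distinguish the node's outcome distribution from
  its parent's at significance `stop_alpha` — further context is
  uninformative.

Every node stores a distribution interpolated with its parent's:
$\lambda\,\hat p_{\text{node}} + (1-\lambda)\,p_{\text{parent}}$ with
$\lambda = (1 - \text{pval}) \cdot n/(n + N_0)$, so sparsely supported or
unsurprising nodes defer to their parent. Scoring a position descends the
tree by the context's nucleotides and uses the leaf's interpolated
distribution; a window containing `N` contributes $\log(1/4)$.

This adaptivity is the point: in a metagenome the amount of training
sequence per cluster varies over orders of magnitude with organism
abundance, and the model order adapts per context path instead of being
fixed globally.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `w` | 8 | context window width (positions available to the tree) |
| `min_split_windows` | 100 | minimum windows to split a node |
| `pseudocount` | 0.5 | per-outcome count added before mixing; keeps scores finite |
| `n0` | 400 | window count at which a maximally significant node reaches $\lambda = 0.5$ |
| `stop_alpha` | 0.05 | chi-square significance of the "similar to parent, stop" rule |
| `strand_mode` | forward | `both-max` scores the reverse complement too and keeps the larger |

The original SCIMM description never fixes its window width, chi-square
level, or strand handling; all three are exposed with the defaults above. `n0 = 400`
follows the Glimmer lineage of ICMs.

### Design choices that were genuinely open

* **Root handling and post-pruning.** The similarity stop compares a node
  with its parent, which leaves the root undefined. The root always splits
  if other rules allow, and after training any split whose four children
  are all leaves indistinguishable from it is collapsed. This makes a
  corpus whose outcome is independent of all context positions yield a
  single root leaf, as it should.
* **Oracle mode.** With `interpolate = FALSE` (forcing $\lambda = 1$ and
  disabling the similarity stop and pruning) and `min_split_windows = 1`,
  the ICM is *exactly* a fixed order-$w$ chain with the same pseudocounts.
  The test suite checks this against an independently implemented chain to
  1e-9, which pins down the scoring path end to end.

## The clustering loop

Sequences $x_1..x_n$ hard-assigned to clusters $C_1..C_K$ with mixture
proportions $p_k$ are scored by the classification maximum likelihood
criterion

$$\mathrm{CML}(C, p, u) = \sum_{k=1}^{K} \sum_{x_i \in C_k}
  \log\left(p_k\, f(x_i; u_k)\right),$$

the hard-assignment analogue of a mixture log-likelihood. Classification EM
alternates: train one ICM per cluster on its members and set
$p_k$ to the cluster's share of bases (M-step), then reassign every
sequence to the cluster maximising
$\log p_k + \log P(s \mid m_k)$ (E-step), ties toward the lowest index. The
loop halts when fewer than 0.1% of sequences change cluster
(`converge_frac = 0.001`) — the closing iterations shuffle a negligible
handful — or at `max_iters = 100`.

Because ICM training is a heuristic rather than an exact M-step, the
classical guarantee that CML never decreases is forfeited; in practice the
halting rule fired in every experiment we ran. The guarantee can be
recovered for testing by using oracle mode with `prior_weight = "count"`
(the exact ML estimate of $p_k$ for the CML prior term counts sequences,
not bases) and a near-zero pseudocount; the acceptance suite verifies
monotonicity there. Default priors remain bp-weighted, consistent with the
bp-weighted view of abundance used in evaluation.

Other decisions: a cluster that loses all members is reseeded with the
worst-scoring sequence so the requested number of clusters survives
(cluster death is otherwise undefined behaviour); the initial partition may
cover only a subsample — it seeds the first round of models, and every
sequence is scored and assigned from iteration 1 onward.

## Initial partitions

CEM inherits k-means' sensitivity to initialisation, and simple random
starts strand the optimisation in poor local maxima. Two established
composition-based strategies are re-implemented as initialisers and run on
a random subsample (default 3 Mbp — both are slow on large sets and a few
Mbp suffices to train the first models):

* **Spectral bisection of k-mer profiles** (`compostbin_partition`):
  strand-symmetric 5-mer frequencies per sequence, PCA to 3 dimensions, a
  symmetrised kNN graph with $f(n) = 2 + \lfloor \tfrac12 \lfloor \ln n
  \rfloor \rfloor$ neighbours and Gaussian weights
  ($\sigma$ = median neighbour distance; CompostBin prescribes only the kNN
  topology), then an approximate minimum normalized cut
  via the Fiedler vector of the normalized Laplacian with a sweep over the
  sorted entries. Bisection recurses on the part holding the most bases (which part to
  split is genuinely open; largest-by-bp favours resolving dominant
  organisms) until $k$ parts exist. The neighbour count $f(n)$ reproduces
  CompostBin's classic six nearest neighbours at typical metagenome sizes
  while thinning the graph for small inputs, and is configurable.
* **Markov-chain MCMC** (`likelybin_partition`): per-cluster fixed-order
  chains (default order 3, 2 restarts) with bp-share priors and a
  Metropolis sampler over single-sequence moves. Counting is
  strand-symmetric: with forward-only counts the sampler reproducibly
  reaches *higher*-likelihood partitions that split reads by strand rather
  than by genome, which no faithful initialiser should do to unoriented
  shotgun reads. This is a light re-implementation of the idea, not a port
  of any particular sampler.

By default both run and each candidate gets one full CEM iteration; the
post-iteration partition with the greater CML wins (`both` mode). The
initialisers succeed on different data, so the CML-based choice is part of
the method.

### Supervised seeding

When a per-sequence taxonomic classification table is available,
`physcimm_seed` groups sequences by label and keeps groups holding more
than $20/k\,\%$ of the classified bases, $k$ the expected number of genomes
(1% for twenty genomes). Classifiers return many small spurious groups;
everything filtered plus everything unclassified forms one extra catch-all
cluster so noise is not forced into the high-quality seeds. The cluster
count is data-driven, not forced to $k$. Group size is measured in bases of *classified* sequences; using all
sequenced bases as the denominator would only loosen the filter and is a
documented alternative. CEM then iterates as usual.

## Evaluation

With ground truth, let $c_{ij}$ be the nucleotides from genome $j$ in
cluster $i$. Recall per genome, $\max_i c_{ij} / \sum_i c_{ij}$, rewards
keeping a genome together; precision per cluster,
$\max_j c_{ij} / \sum_j c_{ij}$, rewards purity; global values weight by
bases. The adjusted Rand index is computed per sequence (the standard
Hubert–Arabie definition; whether the reference weighted it by bp is
unstated). A strain-to-taxon mapping table lets accuracy be computed at
coarser taxonomic levels without hard-coded taxonomy.

## The synthetic world

The simulator emulates the evaluation protocol used in SCIMM's original
experiments without any database downloads: $k$ "genomes" are sampled from random order-3 Markov
chains, abundances are $k$ uniform(0,1) draws normalised to sum 1, reads
take a genome by abundance, a uniform start and a uniform strand, and
substitution errors hit each base independently (no indels — only
mis-calls are modelled; no platform-specific profiles).

Synthetic genomes are additionally passed through a *strand mosaic*
(`strand_mosaic()`): segments of roughly 10 kb are reverse-complemented
with probability 1/2. Real genomes hold genes on both strands and their
k-mer content is therefore approximately strand-symmetric (Chargaff's
second parity rule); a raw Markov-chain sample has no such symmetry, and
against maximally strand-asymmetric "genomes" a forward-strand model family
can legitimately achieve a higher clustering likelihood by splitting reads
by *strand* than by genome — an attractor that simply does not exist in
real data. The mosaic restores the parity property the methods implicitly
rely on.

The one free choice is how *different* the synthetic genomes should be.
Transition rows are Dirichlet($\alpha$) draws with a mean Jensen–Shannon
divergence floor between parameter sets; the defaults
($\alpha = 5$, floor 0.01 bits, giving ≈ 0.05 bits mean pairwise
divergence) were calibrated once so that 5-genome mixtures land in the difficulty
regime reported for mixtures of real genomes — accuracy clearly below
ceiling at 400 bp reads and improving through 1600 bp — and then frozen. Sharper signatures (e.g. $\alpha = 1$) make every mixture trivially
separable at all read lengths and would validate nothing.

What a green test does establish: the pipeline recovers planted structure
of realistic strength from unoriented, error-bearing reads at realistic
read lengths. What it does not: performance on real genomes, whose
signatures carry phylogenetic correlation structure, repeats, HGT and
coding constraints that order-3 chains do not reproduce, nor behaviour on
communities with hundreds of low-abundance members.

## Numerical and engineering notes

* Normalized cuts: dense symmetric eigendecomposition up to 1024 vertices,
  above that a deflated power iteration on $2I - L_{\mathrm{sym}}$ with a
  deterministic start (the trivial eigenvector $\sqrt{d}$ is deflated
  analytically). The sweep then only needs the eigenvector's order, which
  is robust to loose eigen-convergence. Disconnected graphs split along
  components with cut 0 before any eigenproblem.
* PCA axis signs are fixed (largest-magnitude loading positive); distance
  ties in kNN break by input order; MI ties in tree training break toward
  the position nearest the predicted base. All exported functions taking a
  `seed` restore the caller's RNG state.
* All heavy inner loops (window counting, tree construction, scoring,
  k-mer and transition counting, the Metropolis sampler, chain sampling)
  are in C++; they draw randomness through R's RNG so seeding works the
  R way.
* Scores are computed entirely in log space; pseudocounts guarantee every
  interpolated distribution is strictly positive, so any ACGT sequence
  longer than $w$ has a finite score.
* Acceptance-grade simulations are scaled to a 1-CPU, ~25-minute test
  budget: the CEM-monotonicity check uses 50 mixtures of 100 × 400 bp; the
  read-length and error-robustness checks use 640 kb of sequencing effort
  over 5 genomes of 60 kb; the two-genome recovery check keeps its stated
  2000 × 800 bp size.

## Known limitations

The number of clusters $k$ is user-chosen, as in SCIMM itself;
mate-pair constraints, quality values, coverage-biased sampling and
assembly are out of scope. Sequences shorter than ~100 bp carry too little
signature to cluster reliably. The MCMC initialiser is a deliberately
simple stand-in and should not be benchmarked as a faithful LikelyBin.
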