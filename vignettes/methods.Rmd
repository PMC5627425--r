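---
title: "Binning contigs by cross-sample read-count profiles: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binning contigs by cross-sample read-count profiles: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixbin)
```

## The problem and the signal

Shotgun metagenomic studies assemble reads pooled from many samples into
contigs, then must group ("bin") those contigs into putative genomes without
reference sequences. Sequence-composition methods (k-mer spectra) lose power
on short contigs and on genetically similar organisms. mixbin instead uses a
purely quantitative signal: when the same P samples are mapped back against
the shared contig set, every contig from one species should receive reads
from the samples in the *same proportions* — the proportions in which that
species itself is abundant across the samples. We call this normalized
vector the **sample profile**. Two contigs with similar sample profiles are
probably pieces of the same genome, regardless of their sequence content.

The data structure is the contigs-by-samples read-count matrix (`rcmm`):
N rows (contigs), P columns (samples), entry $x_{ij}$ the number of reads
from sample $j$ whose primary alignment lands on contig $i$. Rows are kept
as raw counts, not normalized: the row total $n_i$ carries the information
about how precisely that contig's profile is measured.

## The multinomial mixture model

Let $z_i \in \{1,\dots,K\}$ be the (latent) species of contig $i$, with
$\Pr(z_i = k) = \pi_k$. Given its species, the contig's count vector is
multinomial:

$$\mathbf{x}_i \mid z_i = k \;\sim\; \mathrm{Multinomial}(n_i,\,
\mathbf{a}_k),$$

where $\mathbf{a}_k$, the $k$-th row of the $K \times P$ matrix $A$, is
species $k$'s sample profile (non-negative, summing to one). The parameters
$\theta = (\boldsymbol\pi, A)$ are estimated by maximum likelihood via EM:

* **E-step** — posterior responsibilities
  $q_{ik} \propto \pi_k \prod_j a_{kj}^{x_{ij}}$, normalized over $k$;
* **M-step** — $\pi_k \propto \sum_i q_{ik}$ and
  $a_{kj} \propto \sum_i q_{ik} x_{ij}$.

Hard bin labels are the posterior argmax per contig (ties broken toward the
lowest index). The model ignores sequence content entirely; its key
assumption is **differential abundance**: species must vary appreciably
across samples. Ten or more samples are recommended in practice.

### Numerical conventions

* **Log space.** Responsibilities and the log-likelihood are computed with
  the log-sum-exp trick; the literal products $a_{kj}^{x_{ij}}$ underflow
  already at modest depths.
* **Multinomial coefficient.** The coefficient
  $n_i!/(x_{i1}!\cdots x_{iP}!)$ is constant in $k$ and in $\theta$, so it
  is dropped everywhere — E-step, log-likelihood, and BIC are mutually
  consistent, but absolute log-likelihoods are not comparable with
  implementations that keep it. Differences across iterations or across K,
  which are all the algorithm uses, are unaffected.
* **Profile smoothing.** The M-step adds a pseudo-count (default `1e-10`)
  to every profile numerator, so no $a_{kj}$ is exactly zero and no contig
  can be assigned $-\infty$ under every component mid-fit.
* **Empty components.** A component whose total responsibility falls below
  `1e-12` has its profile re-seeded with the empirical profile of the
  worst-fit contig; its mixing weight keeps the plain M-step value. K is
  never changed inside a fit — the selection loop owns K. With the
  hierarchical initialization this path is rarely taken.
* **Convergence.** Relative log-likelihood change below `1e-6`, capped at
  500 iterations. Every iteration is checked to be non-decreasing (slack
  `1e-8`).

## Initialization

EM only finds local optima, so the start matters. `hclust_init()` takes the
20% of contigs with the most mapped reads (any value in 10–30% is
reasonable; deep contigs have the least noisy profiles — the default sits
mid-range), clusters them by average-linkage agglomeration under the cosine
distance

$$d(\mathbf{x}_1, \mathbf{x}_2) = 1 -
\frac{\sum_j x_{1j} x_{2j}}{\sqrt{\sum_j x_{1j}^2 \sum_j x_{2j}^2}},$$

which is scale-invariant — exactly the right invariance, since two contigs
of one species differ in depth but not in direction — and cuts the tree at
K. Starting profiles are means of the *row-normalized* selected vectors
(raw-count means would let the deepest contigs dominate), and starting
weights are the cluster shares. The procedure is fully deterministic;
`fit_best()` optionally adds random-restart inits by resampling the
selected subset and keeps the best log-likelihood. Average linkage is a
choice, not a necessity; complete and Ward linkage are accepted.

## Choosing the number of species

`select_k()` scores each candidate fit with

$$\mathrm{BIC}(K) = -2\log L(\hat\theta) + (KP + K)\log N,$$

fits K = 1, 2, ... and stops at the first candidate whose BIC exceeds its
predecessor's, returning the BIC minimizer. Two deliberate choices:

* The parameter count $KP + K$ counts every entry of $A$ and $\pi$ without
  subtracting the simplex constraints (which would give $K(P-1) + (K-1)$).
  The surplus $K + 1$ is linear in K, so it only steepens the penalty
  slightly and in our simulations never moves the argmin.
* Each candidate is initialized independently rather than warm-started from
  the previous K; warm starts would couple the candidates and make the
  first-increase stopping rule order-dependent.

For communities with thousands of species a step-1 scan from 1 is
impractical; `strategy = "geometric"` doubles K until BIC turns, then
refines linearly inside the bracket, with the same stopping rule on the
linear pass.

## NMF cross-check

Ignoring noise, the count matrix factors as $X \approx ME$ with $M \ge 0$
the contig-by-species signature matrix and $E \ge 0$ the species-by-sample
total abundances; row-normalizing $E$ recovers $A$. `nmf_factorize()`
minimizes $\|X - ME\|_F$ by the classical multiplicative updates (which
never increase the residual) from a seeded random start, and
`nmf_labels()` assigns each contig to its dominant signature column. On
well-separated communities the NMF and EM labelings agree almost
perfectly (adjusted Rand $\ge 0.9$ in the acceptance checks), which is the
point: NMF is kept as a diagnostic. It offers no likelihood, no
uncertainty, and no principled way to choose K, so it is never the primary
fit path.

## Relative abundance

To compare species across samples the fitted profiles are normalized
RPKM-style:

$$\hat b_{kj} = 10^9 \times \frac{\hat a_{kj} \sum_{i:\hat z_i = k} n_i}
{L_k\, T_j},$$

with $L_k$ the summed contig length of bin $k$ (a genome-length proxy) and
$T_j$ the library size of sample $j$. When counting from alignment files,
$T_j$ is the total read records per file (mapped plus unmapped) — a bare
count table cannot know the unmapped fraction, so there $T_j$ defaults to
the column sum. A species is called **significant** in a sample when
$\hat b_{kj} \ge 0.1\%$ of $\sum_l \hat b_{lj}$ (inclusive); below that the
estimate is dominated by noise. GC-bias correction is out of scope: supply
externally corrected counts if needed — the profile signal itself is robust
to positional bias, since a bias shared by all samples cancels in the
ratios.

## Evaluation metrics

`evaluate_binning()` reports the adjusted Rand index, precision
($\sum_i \max_j n_{ij}/N$ over the contingency table: are bins pure?) and
recall ($\sum_j \max_i n_{ij}/N$: are species kept together?). The ARI uses
exact integer arithmetic for its binomial sums (doubles represent these
integers exactly far beyond any realistic N), and the degenerate 0/0 case —
both partitions trivial, hence necessarily identical — is defined as 1. The
test suite checks the formula against brute-force enumeration of all item
pairs and against an independent implementation.

## What the simulator does and does not emulate

`simulate_community()` draws profiles from a symmetric Dirichlet
(concentration 1 by default: uniformly random profiles), labels from $\pi$,
log-normal contig lengths (median 2 kb, log-sd 0.5 — comfortably above the
conventional 1 kb screening floor), Poisson contig totals proportional to
length times a pooled depth (default calibrated to a mean of 200 reads per
contig, a moderate-coverage regime), and multinomial counts — i.e. exactly
the model, read forward, plus the length–depth coupling that pooled
assembly induces. The `missing_fraction` option zeroes random
(species, sample) cells and renormalizes, emulating species absent from
some samples; `A` can be supplied directly, e.g. to build the
identical-profile negative control. Contigs that draw zero reads are
dropped and reported, as they would never be observed.

What it deliberately does **not** emulate: read-level sequencing error,
assembly chimerism and fragmentation, mapping ambiguity between similar
genomes, and GC/positional coverage bias. Passing the simulation-based
checks therefore demonstrates correctness of the statistical machinery
under the model's own assumptions, not robustness to upstream artifacts —
those enter real analyses through the quality of the count matrix.

The packaged checks run at sizes chosen to exercise the estimator
meaningfully while staying quick on a laptop: recovery and selection at
N = 2000 contigs, P = 20 samples, K up to 10, ten replicate seeds; trend
checks (accuracy versus depth, sample count, species count) at N = 500 and
five seeds per grid point. The identical-profile control uses K = 4 with
one duplicated row and expects the BIC scan to return 3 — species with
proportional abundances across all samples are indistinguishable to this
model by construction; deeper sequencing separates *nearly* proportional
profiles, but exactly proportional ones merge, and that behavior is
asserted rather than hidden.

## Known limitations

* Species with (nearly) proportional abundance patterns across all samples
  merge into one bin; this is intrinsic to the profile signal.
* The method needs multiple samples (preferably more than ten) with genuine
  abundance variation; a single sample carries no profile information.
* Very low-coverage contigs carry almost no signal and should be screened
  out (`filter_contigs()`, default 1 kb and configurable minimum depth).
* Counts are taken at face value: one primary alignment per read, no
  multi-mapping reassignment, no bias correction.

## A worked example

```{r example}
sim <- simulate_community(K = 3, P = 10, N = 500, seed = 7)
sel <- select_k(sim$rcmm, k_min = 1, k_max = 6)
sel$trace
fit <- sel$best_fit
evaluate_binning(fit$labels, sim$truth$labels)
head(tidy(fit), 3)
significant_species(relative_abundance(fit, sim$rcmm))[1:3, ]
```
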