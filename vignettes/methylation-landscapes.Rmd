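---
title: "Potential energy landscapes of DNA methylation: model, estimation, and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Potential energy landscapes of DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methpel)
```

## The model

Whole-genome bisulfite sequencing reports, per read, the methylation state
of each CpG the read covers. Most analysis methods average these calls into
per-site methylation fractions and lose the pattern information within
reads. `methpel` instead models the joint distribution of methylation
patterns in a genomic region with a one-dimensional Ising model: a region
of $N$ CpG sites assigns each binary pattern $x \in \{0,1\}^N$ (1 =
methylated) a potential

$$V(x) = -\sum_{n=1}^{N} \alpha_n \tilde x_n
         \;-\; \sum_{n=1}^{N-1} \beta_n \tilde x_n \tilde x_{n+1},
  \qquad \tilde x = 2x - 1,$$

and probability $P(x) = e^{-V(x)}/Z$. Deep, narrow potential wells mean few
patterns dominate (low methylation stochasticity); flat landscapes mean
many patterns are nearly equiprobable (high stochasticity). Positive
$\alpha_n$ favours methylation at site $n$; positive $\beta_n$ makes
neighbouring sites agree.

The per-site fields and couplings are driven by two genomic covariates:

$$\alpha_n = a + b\,\rho_n, \qquad \beta_n = c / d_n,$$

where $\rho_n \in [0,1]$ is the local CpG density — the CpG count within
$\pm 500$ bp divided by 50, the count at island-typical 20 bp spacing, so
islands sit near 1 and open sea near 0.15 — and $d_n$ is the bp gap
between adjacent CpGs, capped at 1000 bp so that isolated site pairs
decouple rather than dominate. Each estimation region is therefore
summarised by three parameters $(a, b, c)$, box-constrained to
$|a|, |b| \le 10$, $|c| \le 20$. The density normalisation matters: it
keeps $\mathrm{Var}(\rho_n)$ within a region of order $10^{-2}$ rather
than $10^{-5}$, which is what makes $b$ estimable at all from region-scale
data.

## Exact computation and estimation

All probabilities are computed exactly by $2\times2$ transfer-matrix
dynamic programming with per-step rescaling, so arbitrarily strong fields
never overflow: the partition function in $O(N)$, the marginal probability
of a read's calls (unobserved `.` sites and all uncovered sites summed out
by forward–backward messages), and the methylation-level distribution
$P(L = k/K)$ of a $K$-CpG analysis subregion by a counter-augmented pass
in $O(NK)$. For $N \le 10$ these agree with full $2^N$ enumeration to
$10^{-10}$ relative error (property-tested over random parameter draws).

Parameters are fit per estimation region by maximising the sum of read
log-likelihoods. The optimiser is Nelder–Mead restarted from a fixed
$3\times3\times3$ grid over the box ($a, b \in \{-5, 0, 5\}$,
$c \in \{-10, 0, 10\}$), function tolerance $10^{-6}$, ties between starts
broken by the earliest start, with the box enforced by clamping — so a
region of fully methylated reads drives $\hat a$ to the $+10$ bound
instead of diverging. The Nelder–Mead loop itself is compiled (Rcpp)
because the permutation test below refits tens of thousands of regions.
The compiled optimum is cross-checked against `stats::optim` in the test
suite.

Identifiability note: $a$ and $b$ separate only through variation in
$\rho_n$. The bundled `recovery_region_map()` therefore builds a 20-CpG
region with a dense cluster next to sparse sites; with uniform spacing
$\rho_n$ is constant and $(a, b)$ are confounded, and any recovery claim
would be vacuous. On that fixture, 50 replicates of 2,000 complete reads
at $(a, b, c) = (1, 0, 2)$ recover each parameter with median absolute
error well under 0.3 (computed in `tests/testthat/test-acceptance.R`).

## Summary statistics

Per analysis subregion ($K$ CpGs, default 150 bp nested in 3000 bp
estimation regions), the fitted model's level distribution $p_k$ yields

* **MML** $= \sum_k (k/K)\, p_k \in [0,1]$ — mean methylation level;
* **NME** $= H(p) / \log_2(K+1) \in [0,1]$ — Shannon entropy in bits,
  normalised, with $0 \log 0 := 0$; 0 is deterministic, 1 maximally
  stochastic;
* **JSD** $= \sqrt{\tfrac12 KL(p\|m) + \tfrac12 KL(q\|m)}$,
  $m = (p+q)/2$, between the test and reference distributions of the same
  subregion — a metric in $[0,1]$, 0 for identical distributions and 1
  for disjoint support.

All entropies and divergences use base-2 logarithms; that is what places
NME and JSD exactly in $[0,1]$. Statistics come from the fitted model, not
the empirical read histogram: the landscape pools information across the
estimation region and interpolates over sparsely covered subregions, which
is the point of the model. Subregions are scored only with $\ge 5$
supporting read fragments (and regions fit only with $\ge 20$ informative
fragments); these thresholds are configurable defaults, not claims about
optimal filtering.

Between-sample comparison reports per-subregion dMML, dNME (test minus
reference) and JSD, genome-wide medians with a paired two-sided Wilcoxon
signed-rank test over jointly scored subregions (all-zero differences are
reported as $p = 1$; fewer than 10 shared subregions as undefined),
per-feature summaries by the annotation label covering each subregion
midpoint, and strand-aware TSS meta-profiles.

## Gene ranking and significance

Genes are ranked by the *maximum* subregion JSD (or dNME) within 2 kb of
any of their TSSs — a max, not a mean, because the target of inference is
focal discordance; gene-body mode instead averages JSD weighted by CpG
count. Ties break by genomic position, never input order, and multiple
TSSs of one symbol score as the union of their windows.

Significance uses a read-label permutation null: pool the two samples'
fragments in the region, reassign labels preserving group sizes, refit
both groups, recompute the region JSD; $p = (1 + \#\{\text{null} \ge
\text{obs}\})/(1 + n_{\text{perm}})$ with 199 permutations and BH
adjustment across tested genes. Two deliberate economies: refits use a
coarse 4-point start grid (valid because the identical statistic is
applied to observed and permuted data), and p-values are computed for the
top-ranked genes only (default 10–20) — exchangeability makes the test
valid per region, and the scientific claim concerns the top of the
ranking. A 200-region null calibration suite in the test suite checks
$P(p \le \alpha) \le \alpha + 0.05$.

## The synthetic data generator

The generator emulates the statistical structure of a tumor/normal WGBS
comparison, not any real genome. `generate_cpg_map()` lays CpGs with
geometric gaps (mean 20 bp in islands, 120 bp in open sea; all gaps
$\ge 2$ bp), islands of 600–1500 bp covering 6% of each 700 kb chromosome
by default, 2 kb shores and 2 kb shelves, a quarter of islands marked as
bivalent promoters, and 5 kb heterochromatin blocks over 10% of the
sea. `simulate_reads()` draws reads *exactly* from each region's Ising
distribution (forward-filter backward-sample over contiguous windows, a
fixed number of CpGs per read), then masks each covered site independently
at the missing-call rate — i.i.d. masking, since read ends already create
structured missingness. Exact per-subregion MML/NME from the generating
parameters are returned as ground truth.

`make_tumor_normal_pair()` fixes the generative profiles: normal tissue
has $a = +2.5$ over open sea and heterochromatin, $+2.0$ shelves, $+1.5$
shores, $-3.0$ islands and bivalent promoters, $b = 0$, $c = +4$ (strong
cooperativity, concordant reads); the tumor multiplies every field by 0.4
and drops $c$ to $+1$ — global hypomethylation with elevated entropy —
except bivalent promoters, which flip to $a = +2$ (focal
hypermethylation). A region takes the profile of its dominant feature
class, with island-core classes winning whenever the region holds at
least 10 core CpGs so that islands straddling region boundaries keep
their profile in both halves. Default read depth is 10 per CpG with
8-CpG reads and a 5% missing-call rate.

What the generator does *not* emulate: bisulfite conversion errors,
sequencing quality, alignment artefacts, copy-number structure,
cell-type mixtures, or real hg19 coordinates. Passing tests therefore
demonstrate correctness of the estimator and pipeline under the model's
own assumptions plus the planted effect structure — not robustness to the
full messiness of real WGBS data.

## Problem sizes and numerical choices

The bundled study conditions are sized for a desk-scale machine: two
700 kb chromosomes (about 18,000 CpGs, roughly 470 estimation regions and
5,400–5,800 jointly scored subregions per comparison), about 19,000 reads
per sample, 500 genes of which 10 are planted on bivalent promoters. The full
simulate–fit–compare–rank cycle runs in a few minutes on one core; the
50-replicate recovery study and the 200-region permutation calibration
each take a couple of minutes more.

Numerical conventions collected in one place: methylated calls code as
$+1$ spins and positive $a$ favours methylation; level distributions are
normalised exactly (checked to $10^{-9}$); $0 \log 0 = 0$ throughout;
zero cells contribute nothing to their own KL term and $m$ is positive
wherever $p$ or $q$ is, so no division by zero arises; JSD values are
clamped to $[0,1]$ against $10^{-16}$-scale rounding; degenerate inputs
(empty files, CpG-free subregions, regions below the depth filter,
all-`.` reads) are skipped with warnings rather than propagated as NaN;
reads spanning an estimation-region boundary are split at the boundary
and treated as independent fragments, which keeps each region's
likelihood self-contained at the cost of ignoring cross-boundary
coupling for those reads.

## A worked example

```{r example, eval = FALSE}
map <- generate_cpg_map(seed = 101)
pair <- make_tumor_normal_pair(map, seed = 202)
part <- pair$partition

fit_n <- fit_sample(pair$normal, map, part)
fit_t <- fit_sample(pair$tumor, map, part)
track_n <- landscape_track(fit_n, map, part)
track_t <- landscape_track(fit_t, map, part)

diff <- differential_track(track_t, track_n)
genome_summary(track_t, track_n)
feature_summary(diff, map$segments)

genes <- synthesize_genes(map, seed = 303)
rank_genes(diff, genes, mode = "promoter_jsd")
```

The same analysis, staged with all intermediates on disk, is scripted in
`analysis/01_simulate.R` through `analysis/04_rank.R`; `run_pipeline()`
performs it end to end into a single output directory with a MANIFEST and
resolved configuration. The interface of this package is its functions
and these scripts — there is no separate command-line binary, which for an
analysis artifact of this shape would only wrap the same calls.

## Known limitations

The nearest-neighbour Ising form cannot represent longer-range pattern
correlation; $b$ is weakly identified in regions of homogeneous CpG
density (by design of the covariate, not a bug); permutation p-values are
computed for top-ranked genes only, so the reported q-values condition on
the selection; and the synthetic normal sample is a stand-in constructed
from the stated profiles, not a re-analysis of any real reference tissue.
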