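---
title: "Estimating tumor purity and differential methylation from a single bisulfite methylome"
author: "methDeconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tumor purity and differential methylation from a single bisulfite methylome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methDeconv)
```

## The problem

A resected tumor is never pure: a fraction of the cells in the sample are
stromal, immune or other normal cells. Bulk bisulfite sequencing of such a
sample therefore measures a *mixture* methylome, and naive per-site
methylation fractions blur the tumor's signal with the contamination.
methDeconv estimates, from one bisulfite-sequencing sample alone,

1. the mixing ratio of the two dominant cell populations (the *minor
   fraction* $\alpha_1 \le 0.5$; its complement is the major fraction), and
2. the methylation level of each population in every analyzable 300 bp
   bin, from which differentially methylated bins (DMBs) and regions
   (DMRs) are called,

with no matched normal sample, no reference methylomes and no SNP
information.

## The read-level mixture model

Bisulfite sequencing converts unmethylated cytosine to thymine while
methylated cytosine is protected, so an aligned read reports a binary
methylation call at every CpG it covers. Within a short genomic interval
(about 300 bp), CpGs in a pure cell population are strongly co-methylated:
reads are mostly all-methylated or all-unmethylated. A mixture of two
populations with *different* methylation levels in an interval therefore
produces a tell-tale bimodal read pattern whose component weights reflect
the mixing ratio.

Formally, a read $x$ covering $l_x$ CpGs with $M_x$ methylated and $U_x$
unmethylated calls has, under population $j$ with methylation level
$m_j$,

$$p_{x,j} = m_j^{M_x} (1 - m_j)^{U_x},$$

treating CpG states within a read as independent given $m_j$. With minor
fraction $\alpha_1$ (and $\alpha_2 = 1 - \alpha_1$), a bin's read set $X$
has log-likelihood

$$\ell(X) = \sum_{x \in X} \log\left(\alpha_1 p_{x,1} + \alpha_2
p_{x,2}\right),$$

maximized over $\Theta = (m_1, m_2, \alpha_1)$ by
expectation-maximization. The E-step computes membership posteriors
$Q_x(j) \propto \alpha_j p_{x,j}$; the M-step has the closed forms
$m_j = \sum_x Q_x(j) M_x / \sum_x Q_x(j) l_x$ and
$\alpha_1 = \frac{1}{|X|}\sum_x Q_x(1)$. Both are implemented in C++
(reads aggregated by their sufficient statistic $(M_x, l_x)$), with the
reference R implementations (`eStep()`, `mStep()`, `mixtureLogLik()`)
exported and tested against enumeration and numeric-optimization oracles.

Only reads for a single bin enter one fit; bins are treated as
independent. A fixed-$\alpha$ variant updates only $(m_1, m_2)$ and is
used genome-wide once the sample's mixing ratio is known.

## Numerical choices

* **Clamping.** Methylation levels are clamped to $[10^{-6}, 1-10^{-6}]$
  inside log densities so that a read impossible under $m \in \{0, 1\}$
  (e.g. a stray unconverted call) contributes a large but finite penalty.
  Reported estimates are the raw M-step ratios, so fully methylated bins
  still report $m = 1$.
* **Convergence.** Iteration stops when the log-likelihood improves by
  less than $10^{-6}$ (before the parameter update, so the returned
  parameters and likelihood are consistent), or after 500 iterations. The
  log-likelihood trace is retained and is non-decreasing up to $10^{-8}$.
* **Initialization.** Every free-$\alpha$ fit starts from the two
  deterministic points $(m_1, m_2) = (0.2, 0.8)$ and $(0.8, 0.2)$ with
  $\alpha_1 = 0.3$, and the higher-likelihood convergence point is kept
  (ties resolve to $m_1 \le m_2$). The same dual start is used for the
  fixed-$\alpha$ fits, where the two basins correspond to the minor
  component being hypo- vs hyper-methylated. A symmetric "random
  bipartition" start was rejected by design: it begins next to the saddle
  $m_1 = m_2$, where the likelihood surface is so flat that the
  tolerance rule can stop the fit before the components separate.
* **Labels.** After a free-$\alpha$ fit, components are relabelled so
  that $\alpha_1 \le 0.5$; in fixed-$\alpha$ mode components keep their
  initialization identity.
* **Degenerate input.** A bin with a single read, or whose reads are all
  identical, is fitted (the fit collapses to one component) but flagged
  unidentifiable.

## Finding the sample's mixing ratio

Most bins have equal methylation in both populations and carry no
information about $\alpha_1$. The pipeline
(`estimatePurity()`) finds the informative minority:

1. **Qualifying bins**: more than 10 CpGs (strict) and at least 10
   reads, on a non-overlapping 300 bp tiling. "Coverage" here is a read
   count — the model consumes whole reads, not per-base depth.
2. **CNA filter**: bins overlapping known recurrently amplified/deleted
   regions, extended by 1000 bp flanks, are removed; amplification
   inflates the local tumor read share and would bias the local mixing
   ratio.
3. **Bootstrap stability**: each remaining bin's reads are resampled
   with replacement 50 times and refit with the free-$\alpha$ EM. Bins
   whose minor-level estimate $m_1$ is stable (sd $< 0.1$ across
   resamples) behave like genuine two-population mixtures. $m_1$ is the
   most variable of the three parameters and is the ranking statistic;
   the sds of $m_2$ and $\alpha_1$ are reported but unused.
4. **Island de-duplication**: at most one bin per CpG island (the one
   with the smallest sd), so a single island — or a private copy-number
   event covering it — cannot vote more than once.
5. **Vote**: the top 500 stable bins each vote their mean bootstrap
   $\alpha_1$; the sample estimate is the mode of a Gaussian kernel
   density (bandwidth 0.02) over the votes, evaluated on a 0.001 grid
   over $(0, 0.5]$.

Two eligibility guards accompany the sd ranking, both needed because a
*collapsed* fit ($m_1 \approx m_2$) has a perfectly stable — and
meaningless — $m_1$: a bin only votes if its bootstrap fits keep a mean
component separation $|m_1 - m_2| > 0.2$ and a mean minor fraction of at
least 0.05. The second guard encodes the method's detection floor:
contamination below about 5% cannot be distinguished from a pure sample.
If fewer than `minInformative` (default 500) bins survive, estimation
stops with an error of class `"insufficientInformativeBins"` — the
correct behavior for a pure sample, where "deconvolution" would be
noise.

### Behavior near balanced mixing

When the true minor fraction approaches 0.5, bootstrap resamples of a
differential bin frequently flip which component is the minor one; after
relabelling, $m_1$ then alternates between the two levels and its sd
explodes. Such bins fail the stability filter, and the surviving bins are
exactly those whose *empirical* minor fraction sits comfortably below
0.5 — a selection that truncates the vote distribution from above. In our
simulations at 20-fold coverage this is negligible for true fractions up
to 0.3 (recovery within $\pm 0.02$), but at 0.40 the vote settles near
0.35, and at 0.50 the sample is often reported as lacking informative
bins altogether. Users should read estimates above ~0.35 as "close to
balanced, possibly underestimated", and treat a near-balanced sample's
hyper/hypo direction calls with caution (genome-wide phasing of the two
components is deliberately not attempted).

## Differential methylation

With the voted $\hat\alpha_1$ fixed, every qualifying bin is refit with
the dual-start fixed-$\alpha$ EM (`fitAllBins()`), giving per-component
levels $(\hat m_1, \hat m_2)$. A bin is differentially methylated when
$|\hat m_1 - \hat m_2|$ *strictly exceeds* the threshold (default 0.5),
and book-ended DMBs with the same direction (minor hyper- vs
hypo-methylated) merge into DMRs; a hyper/hypo pair is two biological
events and never merges. Bins whose per-read methylation fractions are
highly variable (population variance $> 0.1$) are flagged — they
typically contain more than two read populations (subclones, allele-
specific methylation) — but are not removed from calling.

## What the simulator emulates — and what it does not

`simConfig()`/`simulateMixture()` generate mixtures with known truth,
emulating a two-cell-line read-mixing experiment at desk scale. Defaults
are the study conditions used throughout the tests: 2000 bins of 300 bp;
20-fold coverage with 70–100 bp reads (about 70 reads per bin, Poisson);
15–25 CpGs per bin; 20% of bins truly differential; *dichotomous* levels
(0 vs 1, the dominant pattern in real pure populations); *concordant*
reads (all-or-none per read, probability $m$); and a 0.005 rate of
methylated calls read as unmethylated, a token for imperfect bisulfite
chemistry. The alternative per-CpG Bernoulli read model matches the EM's
own assumption and is used in oracle tests; intermediate-level truth
(levels off the \{0,1\} lattice) reproduces the situation where a
component is called in the wrong direction yet the bin is still correctly
differential. Optional confounders: allele-specific methylation (ASM)
bins whose minor-population reads are 50/50 fully methylated/unmethylated
— a bin-level mimic of a mixture — and tumor-amplified bins whose major-
population read counts are multiplied (default 3x).

Real data differ in ways the simulator deliberately omits: per-bin
coverage is homogeneous (no GC/mappability bias, no RRBS enrichment),
reads lie wholly within bins, CpG spacing is uniform-random, there are no
sequencing errors, quality scores, PCR duplicates or subclonal structure.
Passing tests therefore demonstrate correctness of the *algorithm* under
its own assumptions, not performance on any particular real dataset; in
particular, homogeneous coverage makes the near-balanced truncation above
*more* visible than in real data, where deep bins stabilize the vote.

## Problem sizes and defaults

| parameter | default | meaning |
|---|---|---|
| `binSize` | 300 bp | tiling width; co-methylation is coherent at this scale |
| `minCpG` | >10 | CpGs a qualifying bin must exceed |
| `minCov` | 10 | minimum reads per qualifying bin |
| `nBoot` | 50 | bootstrap resamples per bin |
| `sdThreshold` | 0.1 | max sd of $m_1$ for an informative bin |
| `topN` | 500 | informative bins that vote |
| `minInformative` | 500 | below this, the sample is reported as (near-)pure |
| `cnaFlank` | 1000 bp | flank added to CNA regions before filtering |
| `bandwidth` | 0.02 | Gaussian KDE bandwidth for the vote mode |
| `dmbThreshold` | 0.5 | strict lower bound on $|\hat m_1 - \hat m_2|$ |
| `minComponentSep` | 0.2 | collapsed-fit guard for voting eligibility |
| `minAlphaVote` | 0.05 | detection floor on the per-bin minor fraction |
| `tol`, `maxIter` | $10^{-6}$, 500 | EM stopping rule |

Tests and the acceptance script run at 2000 bins with `minInformative`
lowered to 50, matching the reduced genome; a full run on one CPU takes
about half a minute per sample at this size.

## Known limitations

* Exactly two components; more require deeper data and a model-selection
  step this package does not attempt.
* The minor component is not labelled "tumor" or "normal" — that needs
  pathology or marker genes.
* Contamination under ~5% is indistinguishable from purity (by design,
  reported as an error).
* Estimates near 0.5 are biased low and may fail with the
  insufficient-bins error (see above).
* Sensitivity depends on CpG density: sparse-CpG regions rarely qualify
  at default thresholds.
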