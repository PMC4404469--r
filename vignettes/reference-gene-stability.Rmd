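---
title: "Validating RT-qPCR reference genes with refstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating RT-qPCR reference genes with refstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Relative quantification by RT-qPCR reports a gene's expression against one
or more *reference genes* assumed to be stably expressed across all samples.
That assumption fails often enough — classic housekeeping genes such as
actins or ribosomal RNAs can vary severalfold between tissues, treatments or
temperatures — that candidate references must be validated on the actual
experimental system before use. `refstab` implements the two standard
validation algorithms, geNorm and NormFinder, plus the geometric-mean
consensus that combines their rankings, together with the plumbing around
them: sample QC, technical-replicate aggregation, standard-curve efficiency
estimation, and the transform from quantification cycles (Cq) to relative
quantities.

## From Cq to relative quantities

A transcript detected one cycle earlier is (to amplification efficiency)
twice as abundant. For gene $g$ with per-cycle amplification factor $A_g$
(default 2, i.e. 100% efficiency), the relative quantity in sample $s$ is

$$q_{gs} = A_g^{\min_{s'} Cq_{gs'} - Cq_{gs}},$$

so every gene's highest-expressing sample is the calibrator with $q = 1$.
$A_g$ can come from a fitted standard curve: regressing Cq on
$\log_{10}$(template amount) over a serial dilution gives a slope $m$, and
$E(\%) = (10^{-1/m} - 1) \times 100$, with $A = 1 + E/100$. Efficiencies
materially outside 90–110% usually indicate assay problems rather than
something a correction should absorb.

Before the transform, samples are screened on RNA quality — kept only if
the RNA Quality Indicator exceeds 7 and the A260/A280 ratio lies in
[1.9, 2.1] — and qPCR technical replicates are averaged (arithmetic mean of
the present Cq values; replicates disagreeing by more than 1 cycle trigger
a warning, since no firm rejection rule is standard).

### Missing Cq values

A reaction that never crosses the threshold within `max_cycles` (default
40) is *missing*, not zero. Both stability algorithms need complete
matrices, so two policies are offered: `"drop"` (default) removes any
sample missing any gene; `"impute"` sets missing Cq to `max_cycles`,
treating the value as right-censored. Dropping is the safer default
because imputing at the cycle limit fabricates a quantity for a reaction
that gave no signal; imputation is appropriate when missingness is rare
and concentrated in genuinely low-abundance genes.

## geNorm

For genes $j, k$ the pairwise variation is the sample standard deviation
(denominator $n - 1$) across samples of $\log_2(q_j / q_k)$, and gene $j$'s
stability is

$$M_j = \frac{1}{G - 1} \sum_{k \ne j} V_{jk}.$$

Two ideal references hold a constant ratio in every sample, so low $M$
means stable. The panel is ranked by repeatedly removing the gene with the
highest $M$; the last two genes cannot be ranked against each other and are
reported as a tied pair with their shared $M$. By convention, $M \le 0.5$
indicates a stable gene in a homogeneous sample panel; up to 1 is still
acceptable for heterogeneous panels.

To decide *how many* references to use, the normalization factor
$NF_n$ (geometric mean of the $n$ most stable genes' quantities, per
sample) is compared with $NF_{n+1}$: $V_{n/n+1}$ is the SD across samples
of $\log_2(NF_n / NF_{n+1})$. The first $n$ with $V_{n/n+1} \le 0.15$
suffices; `recommend_gene_count()` also reports the largest panel size
reachable while every preceding $V$ stays under the cutoff, since a value
just under the threshold is usually read as licensing an optional extra
gene rather than requiring one.

Numerical conventions, chosen once: all logs base 2; SDs with the $n-1$
denominator; exact ties in the maximal $M$ (within $10^{-12}$, e.g.
duplicated assays) are broken by excluding the gene latest in input order,
so the trace is deterministic.

## NormFinder

NormFinder fits, within each sample group $g$ (tissue, treatment, ...), a
two-way model of the log2 quantities:

$$y_{igj} = \alpha_i + b_{gj} + d_{ig} + \varepsilon_{igj},
\qquad \varepsilon_{igj} \sim N(0, \sigma^2_{ig}),$$

with gene effects $\alpha$, per-sample effects $b$ (overall template
amount), and group-differential effects $d_{ig}$ that sum to zero over
genes within each group (only relative expression is observable). The
naive per-gene residual variance $z_{ig}$ after two-way centering is
contaminated by every other gene's noise; the unbiased estimator

$$\hat\sigma^2_{ig} = \frac{G}{G-2}
  \left(z_{ig} - \frac{\sum_i z_{ig}}{G (G - 1)}\right)$$

removes it (verified in this package by simulation: over 10,000 synthetic
datasets with $G = 6$, $n = 8$, the un-floored estimator's mean matches
each true $\sigma^2_i$ within 3 Monte-Carlo standard errors). Negative
estimates are floored at zero for reporting; the un-floored values are
available behind `floor_variance = FALSE` because the unbiasedness check
must run without the floor.

Group effects are estimated by double-centering the gene-by-group mean
matrix and shrunk toward zero by $\hat\tau^2 / (\hat\tau^2 +
\hat\sigma^2_{ig}/n_g)$, where $\hat\tau^2$ is the variance of the $d$'s
across genes net of their sampling variance. The per-gene stability
averages, over groups, $|\tilde d_{ig}|$ plus the shrunken sampling SD;
lower is better, and genes are ranked ascending with mean ranks on ties.

**Boundary:** when $\hat\tau^2 = 0$ the shrinkage annihilates every group
effect and the grouped stability degenerates to 0 for all genes — no
ranking. Rather than return that, `normfinder()` falls back to the
ungrouped estimator and flags the result (`tau2_zero_fallback`). This
preserves a usable ordering at the cost of ignoring group structure the
data showed no evidence for. With a single group (or `groups = NULL`) the
ungrouped estimator — stability $\sqrt{\max(0, \hat\sigma^2_i)}$ — is used
directly.

## Consensus ranking

Each algorithm's ordering is converted to integer weights 1..G (most to
least stable; the tied geNorm final pair takes 1.5 each, and tied
NormFinder values share mean ranks), and each gene's weights are combined
by geometric mean; the gene with the lowest GM is the consensus best.
Remaining GM ties are broken by the mean per-method weight, then input
order — a documented house rule, since published tables are not always
reconstructible on this point.

## The synthetic generator

Reference-gene validation studies rarely deposit raw Cq tables, so the
generator is first-class, tested code rather than a fixture: it draws from
exactly the NormFinder generative model above and maps to cycles via
$Cq = \mathrm{baseline}_i - y / \log_2 A_i$. Its defaults are the study's
conditions: 10 candidate genes; a factorial design of 24 condition cells
(leaves and stems, ±PGPR inoculation, weeks 4/6/8 at 20 °C; flowers and
seeds from week 6; uninoculated leaves at 15 and 25 °C, weeks 4/6); 3
biological replicates per cell (destructive sampling, so samples are
independent); 2 technical replicates with 0.1-cycle instrument noise
(typical plate repeatability; the design itself states none); censoring at
40 cycles; baseline Cq values spanning a hyper-abundant ribosomal RNA
(~11.6 cycles) to a rare transcript (~35). Per-gene log2 noise SDs default
to 0.05, 0.1, 0.3, 0.5, ... so that ground truth orders the panel; the
shared per-sample effect SD defaults to 1 log2 unit, a realistic spread of
total template between independently extracted samples. QC metadata is
drawn to pass the filter (RQI uniform 7–10, ratio uniform 1.9–2.1) so that
stability tests are unconfounded; QC behaviour is exercised by corrupting
it explicitly.

What the generator does *not* emulate: amplification-efficiency variation
within a gene, inhibitor-driven Cq shifts, correlated noise between genes
on one plate, or batch/plate effects. Passing recovery tests on synthetic
data therefore shows the algorithms identify planted stability structure
under the model's assumptions — not that any particular real gene is
stable.

## Problem sizes and verification

The test suite cross-checks the vectorized implementations against naive
brute-force oracles (double-loop M values, explicit normalization-factor
vectors, four-loop residual centering) to 1e-10 on random matrices up to
6 genes × 12 samples; runs the 10,000-replicate unbiasedness simulation at
G = 6, n = 8; and verifies, over 200 simulated studies of the full
factorial design, that geNorm, NormFinder and the consensus all place the
two lowest-noise genes on top in at least 95% of runs. These sizes give
Monte-Carlo error comfortably below the margins being asserted while
keeping a full run in the order of seconds.

## Worked example

```{r example}
fx <- make_fixture("paper_design", seed = 7)
cfg <- pipeline_config(cq = fx$cq, meta = fx$meta,
                       subsets = list(leaves = list(tissue = "leaves")))
report <- run_pipeline(cfg)
report
report$panels$all$genorm
report$panels$all$normfinder
report$panels$all$consensus
```

## Known limitations

- geNorm's M is blind to co-regulation: two co-regulated genes keep a
  constant ratio and look perfectly stable. Pair it with NormFinder (which
  is less susceptible) — that is the point of the consensus.
- The grouped NormFinder estimate needs at least 2 samples per group and
  at least 3 genes; small groups make $\hat\tau^2$ noisy.
- Efficiency correction assumes a single per-gene amplification factor
  across all samples.
- The exporter writes tidy CSV/JSON; no publication figures are produced.
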