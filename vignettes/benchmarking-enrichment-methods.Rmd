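---
title: "Benchmarking gene set enrichment methods with eabench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking gene set enrichment methods with eabench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eabench)
```

## The problem

Dozens of gene set enrichment analysis (EA) methods rank gene sets
(pathways, GO terms) for association with a phenotype contrast in an
expression dataset, and they disagree — often drastically — about which
sets are significant and which rank high. Comparing methods is hard
because no experimental gold standard says which sets *should* rank
high. `eabench` provides a self-contained harness for this comparison:
it re-implements a representative panel of methods behind one
interface, generates synthetic benchmark inputs with known ground
truth, and evaluates each method along four axes:

1. **Significance behaviour**: what fraction of sets does a method call
   significant, nominally and after Benjamini–Hochberg (BH) correction?
2. **Type I error**: with group labels shuffled, does the fraction of
   sets with nominal $p < 0.05$ stay near 5%?
3. **Set-size dependency**: are random gene sets — which carry no
   coherent biology — more likely to be called significant merely
   because they are large?
4. **Phenotype relevance**: does the method's ranking accumulate
   a-priori phenotype-relevant sets near its top?

The first three are classical calibration checks. The fourth is the
distinctive one: it scores a ranking against an external relevance
ranking without requiring a binary gold standard.

## The method panel

| method | null hypothesis | gene statistic | set statistic | significance |
|--------|-----------------|----------------|---------------|--------------|
| ORA    | competitive | user DE call | DE/set overlap | hypergeometric tail |
| GSEA   | competitive | signal-to-noise | weighted KS running sum (ES) | sample permutation |
| SAFE   | competitive | Student t | Wilcoxon rank sum of \|t\| | sample permutation |
| PADOG  | competitive | \|moderated t\| | frequency-weighted mean | sample permutation |
| CAMERA | competitive | moderated t → z | variance-inflated two-sample t | t distribution |
| SAMGS  | self-contained | SAM t | sum of squared SAM t | sample permutation |

*Competitive* methods ask whether set genes are more differentially
expressed (DE) than background genes; *self-contained* methods ask
whether the set contains any DE signal at all, background ignored. The
registry ([`ea_methods()`]) also reserves names (GLOBALTEST, GSA,
ROAST, GSVA) as explicit not-implemented stubs so plugin
implementations can slot in without the harness pretending to provide
them.

These are re-implementations sharing one permutation engine, not
wrappers around the original packages; exact score parity with the
originals is a non-goal. Where an established package implements a
standard sub-step, we call it: `edgeR::cpm` for the log-CPM transform,
`limma::squeezeVar` for empirical-Bayes variance shrinkage,
`stats::phyper`, `stats::p.adjust`, `stats::wilcox.test`. The
benchmark machinery itself — rank weights, relevance scores, nulls,
assays — is authored here.

## Gene-level statistics and the RNA-seq bridge

All t-like statistics operate on a log-intensity scale. RNA-seq counts
are bridged to that scale by a variance-stabilizing moderated log2
counts-per-million transform (`log_cpm_transform()`): with a common
negative-binomial dispersion $\hat\varphi$ (method-of-moments,
`estimate_common_dispersion()`), the prior count is set to
$0.5/\hat\varphi$. The prior grows as counts approach Poisson,
damping the low-count variance blow-up of the log. Because
$0.5/\hat\varphi$ diverges as $\hat\varphi \to 0$, the estimate is
floored at 0.01 (prior capped at 50). TPM inputs are
$\log_2(\mathrm{TPM}+1)$-transformed; on the simulated data both routes
make the per-gene t-test type-I error nominal (checked in the test
suite at 2000 genes: fraction of $p<0.05$ within 3 binomial SDs of
0.05).

Statistic conventions: differences are first group level minus second;
the SAM fudge constant $s_0$ is the median per-gene standard error (the
original SAM percentile search is out of scope and a fixed quantile is
the common simplification); moderated-t prior moments come from
`limma::squeezeVar`, the field's reference implementation of exactly
this shrinkage. Zero-variance genes are flagged, excluded from
rankings, and carry zero evidence (statistic zeroed) inside method
permutation loops. When a dataset has `blocks`, gene statistics can use
within-block paired differences, and all permutation engines shuffle
labels within blocks only.

ORA needs a discrete DE list. The benchmark wrapper uses the customary
dual criterion (BH-adjusted $p<0.05$ and $|\log_2 FC|>1$); on data
where that list is empty — notably label-shuffled null data — it falls
back to nominal $p<0.05$ with a warning, since an empty list would make
the hypergeometric test undefined rather than conservative.

## The relevance score

An EA ranking of $N$ sets assigns each set an absolute rank $r_A$, a
relative rank $r_R = r_A/N$ and a weight

$$ w = 1 - r_R \in [0, 1], $$

so weights decay linearly from the top of the ranking. With ties, the
relative rank generalizes to the fraction of sets whose ranking
statistic is at least as extreme, so tied sets share one weight and the
tie-free formula is recovered when all values differ
(`ranks_to_weights()`; orientation — smaller-is-extreme for p-values,
larger-is-extreme for scores — is declared per statistic). Given an
a-priori relevance ranking with non-negative scores $S_p(i)$, the
relevance score of the EA ranking is

$$ X = \sum_{i=1}^{N} w(i)\, S_p(i), $$

and the relative score $\bar X = X / O_p$ normalizes by the
theoretically optimal score $O_p$ obtained when the EA ranking orders
sets by $S_p$ itself. $\bar X \in [0,1]$ for tie-free rankings (a
rearrangement-inequality consequence, property-tested), and
$\bar X = 1$ exactly when the orders match (modulo ties). The
normalization makes scores comparable across datasets whose relevance
scales differ; raw $X$ is deliberately not comparable across
phenotypes, and no cross-phenotype use of raw scores is supported.

Two empirical nulls qualify an observed $X$:

- **Random-ranking null** (`random_ranking_pvalue()`): scores of
  uniformly random orderings. For $N! \le 10^4$ all orderings are
  enumerated and the p-value is exact ($b/N!$); otherwise sampled with
  the add-one convention $(b+1)/(B+1)$, which never returns 0. The
  enumerated null mean obeys the identity
  $\mathbb{E}[X] = \frac{N-1}{2N}\sum_i S_p(i)$, used as a test oracle.
- **Label-permutation null** (`label_permutation_pvalue()`): the method
  is re-run under label shuffles and each resulting ranking scored.
  This null preserves rank dependencies induced by overlapping sets,
  which random orderings destroy.

When the EA ranking and the relevance ranking cover different set
universes, scoring drops the symmetric difference and recomputes
weights on the intersection — the score is defined over one shared
index, and this is the least-surprising reconciliation. An optional
`top_fraction` restricts the evaluation to the top of the ranking by
zeroing every weight below $1 - \text{top\_fraction}$ (rather than
recomputing weights on the truncated subset): the untruncated weights
already encode where each set sits in the full ranking, and zeroing
simply silences the tail's contribution.

## Synthetic data: what it emulates, what it does not

`simulate_expression()` produces two-group data with a controlled DE
fraction and effect size: Gaussian log-intensities (baseline
$N(7,1)$, unit noise, mean shift $\pm$`effect_size` with random sign),
negative-binomial counts (log-normal gene means with meanlog 4 and
sdlog 1, mild library-size variation, common dispersion $\varphi$,
fold-change effects), or TPMs. Defaults are chosen to resemble a
moderately powered two-condition comparison; the benchmark assays
state their own sizes below. Inter-gene correlation is induced by
latent factors over consecutive gene blocks (pairwise correlation
`within_set_cor` inside a block); blocks are recorded in the
`SimulationTruth` so correlated gene sets can be constructed on top of
them — correlation must exist at matrix-generation time, before any
gene set collection does, which is why it attaches to gene blocks
rather than to sets.

`make_scenario()` adds a set collection with a fraction of truly
enriched sets (oversampling DE genes at proportion `enrich_prop`) and a
relevance ranking $S_p = 10\cdot(\text{true DE fraction}) +
|N(0,\sigma)|$. The half-normal noise keeps $S_p \ge 0$, mirroring
non-negative literature-derived composite scores; with $\sigma = 0$
the relevance ranking orders sets exactly by true DE content. This
generator emulates the *structure* of real benchmark inputs — an
informative but imperfect external ranking — not the noise
characteristics of any particular literature mining pipeline, nor
microarray probe effects, GC/length biases, or single-cell structure.
Passing the assays here therefore demonstrates internal correctness
and qualitative behaviour, not performance on any real compendium.

Every generator is a deterministic function of its parameters and
seed (bitwise-reproducible, tested).

## Assay design and problem sizes

The packaged assays run at sizes that reproduce the qualitative
phenomena crisply on a single CPU:

- **Type I error** (`type_one_error_assay()`): null Gaussian data with
  2000 genes × 30 samples, 100 random sets of size 20, 200 label
  shuffles, permutation methods at 100 internal permutations. All six
  methods keep the mean fraction of nominally significant sets at or
  below 0.05 plus three Monte-Carlo standard errors; this is also what
  `scripts/acceptance.R` recomputes.
- **Set-size dependency** (`random_set_size_assay()`): sizes
  $\{5, 10, 25, 50, 100, 250, 500\}$, 100 random sets per size. On
  data with 30% DE genes, SAMGS's significant fraction rises
  monotonically to 1 while competitive methods stay flat — random sets
  inherit the background DE rate, which violates the self-contained
  null but not the competitive one. On null data competitive fractions
  show no size trend. One caveat discovered in testing: CAMERA's
  *default* fixed inter-gene correlation of 0.01 inflates the set-side
  variance by $1+(m-1)\cdot 0.01$, so its rejection rate on
  uncorrelated null data genuinely *declines* with set size (a
  deliberate power trade-off in its default, not a miscalibration);
  the flatness check therefore runs CAMERA with $\rho = 0$, its
  unadjusted core.
- **Relevance discrimination**: across 20 seeded scenarios (1000 genes
  × 16 samples, 25% DE, 40 sets, relevance noise 0.5), the median
  $\bar X$ of the competitive methods exceeds SAMGS's in every seed,
  and an oracle ranking by true DE fraction beats the random-ranking
  mean in every seed. SAMGS loses relevance not because its statistic
  ignores signal but because, with background DE present, its ranking
  is driven by set size as much as by set-specific relevance.

## Numerical choices and edge cases

- Empirical p-values use $(b+1)/(B+1)$ everywhere except complete
  enumerations, which are exact.
- GSEA's ES is computed from the sorted hit positions only (the
  running-sum extrema can occur only at or just before hits), checked
  against a full running-sum oracle; its significance is the two-sided
  permutation p of $|ES|$, giving one consistent p-value per set for
  the ranking machinery rather than the original split
  positive/negative estimation. The weight exponent defaults to 1 and
  is exposed.
- PADOG standardizes set statistics across sets (mean 0, SD 1) within
  the observed data and within each permutation before computing
  p-values; with fewer than ~20 permutations that standardization is
  noisy and a warning is raised.
- SAMGS uses the sum of squared SAM t statistics over set genes — the
  original statistic despite sometimes being described as a Hotelling
  $T^2$; a genuine $T^2$ would need an inverse covariance that is
  singular for sets larger than the sample count.
- Ranking order is deterministic: p ascending, ties by $|statistic|$
  descending, then set id. Weights, however, follow the tie-aware
  formula, so fully tied sets share weight regardless of the printed
  rank order.
- Degenerate inputs: constant matrices give all-zero statistics and
  p-values of 1 in permutation methods; a set equal to the whole
  universe errors for SAFE and CAMERA (no background exists);
  singleton sets are defined for CAMERA with VIF 1.

## Limitations

The re-implementations are faithful to each method's published core
but not line-by-line ports; absolute p-values can differ from the
original software even where rankings agree. The adapted RNA-seq mode
in which a count-model statistic is refit in every permutation is
intentionally not implemented — the VST route is the supported path.
Real-data loaders (GEO/TCGA), identifier mapping, and network-based
methods are out of scope; gene identifiers are matched as exact
strings.
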