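---
title: "Methods: signature reversal, overlap and prognostic stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature reversal, overlap and prognostic stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigreverse)
```

# Overview

`sigreverse` implements a transcriptome-based drug-repurposing workflow for
anti-fibrotic discovery. The scientific idea is signature reversal: if a
disease state (here, hepatic stellate cell activation, the central event of
liver fibrogenesis) is characterized by a reproducible gene-expression
signature, then a compound whose perturbational profile displaces that
signature in the *opposite* direction is a candidate therapeutic. The
pipeline has four statistical stages, each usable on its own:

1. **Signature construction** — permutation t-tests with FDR control on a
   two-group expression matrix, split by sign into directional tag lists,
   mapped to human ortholog symbols.
2. **Connectivity screen** — Kolmogorov–Smirnov tag-enrichment scoring of
   the signature against a rank-transformed compound-perturbation database,
   aggregated from instances (one treatment experiment) to compounds, with
   permutation p-values; compounds with significantly negative enrichment
   are the reversal candidates.
3. **Target overlap** — exact hypergeometric quantification of the
   intersection between a cell-type-specific gene set and a drug-interactor
   gene set against a protein-coding background.
4. **Prognostic validation** — mean+1SD biomarker stratification of a
   clinical cohort, Kaplan–Meier estimation and the log-rank test.

A synthetic-data module generates all inputs with planted ground truth, so
the full pipeline is exercised and calibrated without any external data.

# Signature construction

For each gene, the two-group comparison uses the Welch (unequal-variance)
t statistic, case minus control. The reference distribution is obtained by
permuting group labels over samples: with `B` permutations,

$$p = \frac{1 + \#\{\,|t^\*| \ge |t_{\mathrm{obs}}|\,\}}{1 + B},$$

the add-one form guaranteeing $p \ge 1/(B+1) > 0$, a standard validity
requirement for sampled permutation tests. We chose the Welch statistic
because the permutation null makes the reference distribution exact either
way, while the unequal-variance form is more robust when it is used as a
plain ranking statistic. A gene with identical values in every sample gets
$t = 0$ and $p = 1$ and is flagged, not dropped. Multiplicity is controlled
by Benjamini–Hochberg adjustment of the permutation p-values (`q` values);
genes with `q` below the threshold (default 0.05) form the signature, split
by the sign of `t` into up- and down-regulated tag lists.

Cross-species translation drops genes with zero or more than one human
partner in the ortholog table. Expanding many-to-many orthologs would let a
single source gene contribute several tags to the enrichment statistic,
which double-counts evidence; dropping is the conservative choice, and the
mapping report (mapped / unmapped / ambiguous counts) makes the loss
visible. Gene symbols are matched case-insensitively throughout, because
rodent (`Col1a1`) and human (`COL1A1`) conventions coexist in any
cross-species analysis; original spellings are preserved on output.

**Interaction of `B` with the FDR threshold.** The permutation floor
$1/(B+1)$ bounds how small a q-value can get: with `m` genes tested, the
smallest achievable BH-adjusted value is roughly $m/(k(B+1))$ for $k$
discoveries. At the default `B = 1000`, discovery at FDR 0.05 therefore
requires the true-signal fraction to be substantial, or `B` to be raised in
proportion to `m`. This is a property of sampled permutation tests in
general, not of this implementation; it is why the planted-recovery
calibration below uses a matrix where planted genes are 20% of the
universe, and why users testing 10,000+ genes at `B = 1000` should expect
conservative signatures.

# Connectivity scoring

The rank database stores, per instance, a complete ranking of the gene
universe with rank 1 the most up-regulated gene under treatment. For a tag
list of size $t$ whose sorted ranks in a list of length $n$ are
$V(1) < \dots < V(t)$, the enrichment score is

$$a = \max_{j} \left[ \tfrac{j}{t} - \tfrac{V(j)}{n} \right], \quad
  b = \max_{j} \left[ \tfrac{V(j)}{n} - \tfrac{j-1}{t} \right], \quad
  \mathrm{ES} = \begin{cases} a & a \ge b \\ -b & \text{otherwise,} \end{cases}$$

a signed Kolmogorov–Smirnov statistic in $[-1, 1]$: positive when tags
concentrate at the top of the ranking, negative at the bottom. Two
numerical conventions are worth stating. First, a tag list that covers the
entire universe ($t = n$) carries no positional information and is defined
to score 0 (the raw formulas would give the uninformative $-1/n$). Second,
the statistic is not exactly antisymmetric under list reversal: because the
hit-side maximum uses $j/t$ while the miss side uses $(j-1)/t$, a single
tag at rank $k$ and one at rank $n+1-k$ satisfy
$\mathrm{ES}(k) + \mathrm{ES}(n{+}1{-}k) = -1/n$ exactly, not
$\mathrm{ES}(k) = -\mathrm{ES}(n{+}1{-}k)$.

Per instance, the up and down tag lists are scored separately and combined
as $\mathrm{raw} = \mathrm{es}_{up} - \mathrm{es}_{down} \in [-2, 2]$ when
the two scores have opposite signs (a zero score counts as opposite to
either), and 0 when they share a sign: concordant displacement of both
lists is no evidence of connection. Raw scores are then scaled per side
(positives by the maximum positive, negatives by the absolute minimum
negative) into $[-1, 1]$.

Compound-level aggregation orders all $N$ instances by raw score
(descending, ties broken by instance id for bit-reproducibility) and
applies the same KS statistic with the compound's instances as tags. The
permutation p-value draws random same-size instance subsets; it is
two-sided on $|\mathrm{ES}|$ by default (`sided = "one"` is available),
with the directional selection rule — enrichment < 0 and $p \le \alpha$ —
applied *after* the p-value, so a compound is selected only when it reverses
the signature and does so more extremely than random instance subsets.

# Target overlap

The intersection of a $K$-gene and an $n$-gene set in an $N$-gene
background is modelled as hypergeometric: expected overlap $Kn/N$, point
probability $\binom{K}{k}\binom{N-K}{n-k}/\binom{N}{n}$ evaluated in log
space, and upper tail $P(X \ge k)$ by summation. Both the point and the
tail probability are always reported, explicitly labelled. They answer
different questions (exactly this overlap vs. at least this overlap) and
differ materially near $k = 1$ — for the package's canonical configuration
($K = 160$, $n = 122$, $N = 20354$, $k = 1$) the point probability is 0.37
while the tail is 0.62 — so silently choosing one invites
misinterpretation. The default background of 20,354 protein-coding genes
(NCBI CCDS release 21) is shipped for headless runs; an explicit background
universe, when supplied, both filters set membership and sets $N$.

# Survival stratification

The biomarker rule labels a sample "high" when expression strictly exceeds
the cohort mean plus one sample standard deviation ($n-1$ denominator);
with zero variance every sample is "low" and a warning is emitted. Strict
inequality and the sample SD are deliberate, documented choices (the rule
is stated in the output metadata) — the grouping is invariant to additive
shifts of the biomarker scale. Curves are the standard product-limit
estimator; the two-group comparison is the log-rank test with tied event
times pooled at a single risk-set update. Estimation delegates to the
`survival` package; the test suite verifies the results against an
independent hand-iterated 2×2-table oracle to $10^{-9}$, and verifies that
the Kaplan–Meier curve equals the empirical survival function whenever
there is no censoring. The module is agnostic to event semantics and time
units: it consumes a generic (time, event) table, with the unit declared in
the run config.

# Synthetic data: what it emulates, and what it does not

`simulate_expression` draws null genes i.i.d. $\mathcal N(0, \sigma^2)$ in
both groups and shifts planted genes by $\pm\,\mathrm{effect}\cdot\sigma$
in cases (defaults: 1,000 genes, 10 vs 10 samples, 50 planted at 2 SD —
a scaled-down two-group microarray comparison with a strong activation
program). `simulate_rank_database` builds null instances as uniform random
permutations; planted antagonists start from a uniform permutation and move
signature up-genes toward the bottom and down-genes toward the top by
geometric interpolation at the configured strength, then re-rank (stable
ties) to restore a valid permutation — agonists are the mirror image
(defaults: 200 instances, 40 compounds round-robin, one strength-1
antagonist). Displacement happens in rank space because the connectivity
engine consumes ranks only. `simulate_survival` gives every subject a
standard-normal biomarker; subjects above mean+1SD progress at the baseline
hazard (0.02 per month by default) and the rest at hazard-ratio times that
(default 2.5), so high expression is protective; censoring times are
uniform on $(0, \tau)$ with $\tau$ solved numerically so the expected
censored fraction over the two-group mixture matches the configured value
(default 30%). Each generator draws from its own stream (master seed plus a
fixed offset), so generators are individually reproducible and mutually
independent.

What the generators do **not** emulate: probe-level microarray noise,
batch and platform effects, correlated gene modules, the real dose/cell-line
design of perturbation databases, non-exponential hazards, or informative
censoring. Passing the calibration suite therefore demonstrates that the
statistics are implemented correctly and are well calibrated under their
own assumptions — it does not demonstrate robustness to the failure modes
of real microarray or clinical data.

# Calibration results computed by the test suite

The acceptance tests recompute, at fixed seeds: uniformity of permutation
p-values on a fully null 2,000-gene 10v10 matrix (Kolmogorov–Smirnov test
against $U(0,1)$, plus type-I control at $\alpha \in \{0.01, 0.05\}$);
planted-gene recovery at FDR 0.05 averaged over 20 seeds on 250-gene
matrices with 50 planted up-regulated genes at effect 2 SD and `B = 1000`
(the 20%-planted design follows from the floor analysis above); screen null
calibration over 200 null compounds at `B = 1000` and antagonist recovery
over 20 seeds (5 of 200 instances planted at strength 1); exact agreement
of the KS statistic with a position-walking brute-force oracle for every
configuration with $n \le 8$, $t \le 3$; log-rank null rejection and power
at hazard ratio 2.5 with 200 subjects per group and ~30% uniform censoring
over 500 replicates; and the hypergeometric worked example (point 0.37,
tail 0.62, expected overlap 0.959). These problem sizes were chosen so the
whole suite runs in about a minute on one CPU while keeping Monte-Carlo
error within the stated tolerance bands.

# Known limitations

* The permutation-floor/BH interaction above: large gene universes need
  `B` scaled up with `m`, or a less conservative error criterion.
* Compound p-values treat instances as exchangeable; dose and cell line are
  carried as metadata but not modelled.
* The enrichment statistic is unweighted (classic KS); no gene-level
  weighting is implemented.
* The overlap test assumes both gene sets are drawn from the same
  well-defined background; with sets from different platforms the
  background choice dominates the answer, which is why the background size
  is an explicit, reported parameter.
* One-sided signatures are supported (the missing side scores 0) but
  flagged, since a single-list query halves the information available to
  the reversal statistic.
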