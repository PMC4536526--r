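---
title: "Conserved co-expression modules and cross-cancer risk panels: methods"
author: "panConserve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conserved co-expression modules and cross-cancer risk panels: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panConserve)
```

# The problem

Across tumor types, some transcriptional programs — immune infiltration,
extracellular-matrix remodelling, proliferation — recur as blocks of
co-expressed genes. When the same block is detectable as a module in
several cancers' co-expression networks, its genes are candidates for a
*universal* classifier and, if their expression tracks survival, for a
compact pan-cancer prognostic panel. panConserve implements that chain of
inference as a tested pipeline: per-cohort network and modules → pairwise
module preservation → conserved gene sets → classifiers and sample
stratification → risk genes → panel → resampling revalidation — plus a
synthetic data generator that makes every stage falsifiable against a
known ground truth.

# Per-cohort networks and modules

Expression is taken gene-wise (rows) on a log-intensity-like scale. The
unsigned adjacency is $a_{ij} = |\mathrm{cor}(x_i, x_j)|^{\beta}$ (a signed
variant $((1+\mathrm{cor})/2)^{\beta}$ is available; unsigned is the
default because "modules of highly correlated genes" does not distinguish
correlation sign and unsigned is the historical default of the field).
$\beta$ defaults to 6 or can be chosen by `pickSoftThreshold()`: the
smallest candidate whose scale-free fit index reaches 0.8. The fit index
bins whole-network connectivity $k$ into `nBreaks = 10` equal-width bins
and regresses $\log_{10}$ bin frequency on $\log_{10}$ mean bin
connectivity; empty bins are retained at a pseudo-frequency of $10^{-9}$
at the bin midpoint, and the $R^2$ carries the sign opposite to the slope
so that only a *decaying* degree distribution can qualify. If no candidate
qualifies the best-fitting one is used (with a warning); if the fit is
undefined (too few genes) the conventional fallback 6 is returned.

Topological overlap is
$\mathrm{TOM}_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 -
a_{ij})$, whose denominator is $\ge 1$ whenever $a \in [0,1]$, and modules
are branches of average-linkage clustering of $1-\mathrm{TOM}$.

**Static cut instead of dynamic tree cut.** `detectModules()` cuts the
dendrogram at a fixed dissimilarity height (default 0.99) rather than
re-implementing the dynamic hybrid branch-cutting algorithm. The choice is
deliberate: under soft thresholding, unrelated genes have topological
overlap within rounding of zero, so their dissimilarity sits essentially
at 1 — *above* the cut — and they fall out of the tree as singletons that
collect under the unassigned ("grey") label, while genuinely co-expressed
branches merge far below it. We considered cutting at a quantile of the
merge heights instead, but in realistic geometries the height distribution
is dominated by the background-gene merges just below 1, so a quantile cut
lands above them and sweeps all background genes into one giant spurious
module; a fixed cut does not have this failure mode. The trade-off,
documented rather than hidden, is that weakly correlated modules (pairwise
correlation below roughly 0.5, where $1-\mathrm{TOM}$ crosses the cut) go
unassigned; the package's planted-recovery guarantees are stated for
within-module correlation $\ge 0.6$. Modules are labelled `M1, M2, ...` by
decreasing size with ties broken by smallest member gene id, which makes
the labelling invariant to gene order. `minModuleSize` defaults to 30.

# Module preservation

`modulePreservation()` asks whether a reference module is still dense and
internally organized in a *test* cohort. Four observed statistics are
computed on the module's genes in the test data: mean within-module
$|\mathrm{cor}|$, mean within-module adjacency (density), and the
cross-cohort correlations of intramodular connectivity and of the
off-diagonal correlation entries (connectivity). Their null distribution
comes from `nPerm` random gene sets of the module's size drawn from the
shared gene universe — random *gene* sampling rather than sample
permutation, because it preserves the test cohort's correlation structure
and is the standard null for these statistics. Each statistic is
standardized ($Z = (\mathrm{obs} - \mu_0)/\sigma_0$; a degenerate null sd
yields $+\infty$ with a warning), averaged in pairs into $Z_{density}$ and
$Z_{connectivity}$, and $Z_{summary}$ is their mean. `medianRank` is the
median of the module's ranks (1 = best) on the four observed statistics
across all evaluated modules; with a single module it is 1 by
construction.

Classification: **strong** iff $Z_{summary} > 10$ and `medianRank` < 10;
**moderate** iff $2 < Z_{summary} \le 10$ and `medianRank` < 10; otherwise
**none**. The boundaries are assigned to the lower class because the
defining inequalities are strict. `percentPreservation()` is
`preserved / total * 100` to two decimals, and `preservationMatrix()`
fills the directed grid — asymmetric by construction since the two
directions normalize by different module counts. "Preserved" counts
strong *and* moderate classes by default (configurable), and the diagonal
is 100 by definition (every module is self-preserved). Null calibration
(mean $Z_{summary}$ within $\pm 0.3$ of 0, sd in $[0.7, 1.4]$ at 200
permutations) is enforced in the test suite; note the sd of $Z_{summary}$
sits naturally below 1 because it averages four positively correlated
Z-scores.

# Conserved sets, hubs, classifiers

`extractConservedSets()` searches for one module per cohort of a group
such that every directed pair is preserved at the required class (default
strong) *and* every module pair overlaps more than chance (one-sided
Fisher exact on the shared-universe cross-tabulation, default
$p \le 0.05$, uncorrected — the cross-tabulation is used as a matching
device, not an inference). The conserved set is the intersection of the
chain's member genes; a group of one cohort degenerates to one set per
module. `refineConservedSet()` intersects a set with the best-overlapping
modules of additional cohorts — the mechanism that derives a narrower
subset signature conserved in a wider cancer group.

Interaction networks keep TOM edges at or above `edgeThreshold`
(default 0.02 absolute; the percentile alternative is a one-liner via
`quantile` on the TOM values). Hubs are genes with at least
`minDegree = 10` interactions — the source material states the cutoff
both as "more than 10" and "at least ten"; we adopt $\ge 10$ and expose
the parameter. Classifiers are the hub genes common to every cohort of the
group, partitioned by source conserved set.

# Stratification and survival

`setScore()` is the mean per-gene z-score over a classifier set — a
deliberate, deterministic operationalization of "up/down-regulated
classifiers" (the original analysis partitioned a heat map without stating
a rule). With two sets, the score-sign pair maps to classes 1 (both up),
2 (Set 1 up), 3 (Set 2 up), 4 (neither); a score of exactly 0 counts as
down, which keeps the rule deterministic and conservative. One set gives
two classes. `classSurvival()` attaches Kaplan-Meier curves per class and
overall plus pairwise log-rank tests.

The statistical primitives are self-contained: product-limit
Kaplan-Meier; log-rank with the multi-death hypergeometric variance and
$\chi^2_{k-1}$; Fisher exact 2×2 by hypergeometric tail; McNemar with the
continuity-corrected $\chi^2 = (|b-c|-1)^2/(b+c)$ for $b+c \ge 25$ and the
exact two-sided binomial below that (the switch point is our documented
choice); centered SVD PCA with largest-|loading|-positive sign convention
and no scaling by default (expression is assumed normalized). Each is
cross-validated in the tests against an independent oracle (`survival`,
enumeration, `binom.test`, `prcomp`) — the oracle never replaces the
implementation.

# Risk genes, panel, prediction

The original risk-gene procedure lives in unavailable supplementary
material; `identifyRiskGenes()` reconstructs it as the simplest procedure
consistent with the named machinery: dichotomize each candidate gene at
its median (ties: $\ge$ median is "high"), two-group log-rank, keep genes
at $p \le 0.01$ (0.05 where a cohort needs the looser printed threshold),
uncorrected as printed. Direction is +1 (high expression hazardous) when
the high-expression arm has the lower Kaplan-Meier survival at the
cancer's horizon. `commonRiskGenes()` intersects identities across the
group with an `allowedOutliers` parameter (1 reproduces the
one-deviant-cohort semantics).

`assignActualRisk()` encodes the per-cancer follow-up horizons (3 years
for breast/ovary, 1 for colon/rectum/lung, 2 for glioblastoma in the
source analysis; the ambiguous "≥ mean survival period" phrasing is
resolved in favour of the explicit year thresholds): death before the
horizon is high risk, observed time past it is low risk, censoring before
it is indeterminate and excluded from confusion counts — the source is
silent on such patients and excluding them avoids labelling on no
information. `predictRisk()` reconstructs the unpublished per-patient
assignment rule as a majority vote: a panel gene votes risky when
expression lies strictly on its risky side of the cohort median, and a
tie predicts low risk (conservative). `evaluatePrediction()` reports
TP/FP/TN/FN with sensitivity TP/(TP+FN) and specificity TN/(TN+FP),
leaving a metric `NA` rather than 0 when its denominator is empty;
`compareSignatures()` feeds per-sample correctness discordance to McNemar.
`assemblePanel()` applies the per-cancer composition rules (common Set-1,
common Set-2, both, or common plus the cancer's `nIndividual` most
significant own risk genes, ties by gene id) and deduplicates within a
cancer; the worked 6+3+3+3 configuration yields the expected 15-gene
union.

`resampleValidate()` draws RDs without replacement (bootstrap behind a
flag), recomputes medians *inside* each RD, and reports the fraction of
RDs whose predicted risk groups separate at $p < \alpha$; an RD with a
single predicted group counts as non-significant. Patients are resampled,
not genes — the natural reading of "random datasets" for a fixed panel.
Note that RDs drawn from one cohort share that cohort's chance
correlations, so the *conditional* significant fraction under the null is
over-dispersed across cohorts even though the marginal rate is the nominal
5%; the tests therefore calibrate the null marginally over fresh cohorts.

# The synthetic generator

`simulateMulticancer()` emulates the statistical skeleton the analysis
assumes: per (module, cohort) a standard-normal latent factor $f$; module
gene $g$ gets $x_g = l_g m_g f + \sqrt{1-m_g^2}\,\varepsilon$ with sign
$l_g$ (+1 by default, mixed signs optional to exercise unsigned networks)
and magnitude $m_g$ derived from a per-gene *hub gradient* $u_g \sim
U(1 \pm 0.25)$, shared across cohorts and rescaled (iteratively, capped at
0.995) so the expected pairwise within-module correlation equals the
configured `cor` exactly. The gradient matters: perfectly flat loadings
would make every module gene statistically exchangeable, leaving the
connectivity-preservation statistics with no within-module structure to
reproduce while the permutation null (random sets straddling modules and
background) retains plenty — an adversarial geometry no real module
exhibits. Background genes are independent noise; a per-gene baseline
uniform on [6, 12] puts values on a log2-intensity-like scale; an
optional missing-at-random mask is available and off by default.

Survival is proportional-hazards by construction: the latent risk score
of a sample is the mean of $l_g f_{m(g)}$ over the configured risk genes,
and event times are exponential with hazard
$h_0 \exp(\beta_{risk} \cdot \mathrm{score})$. Censoring times are uniform
on $[0, u]$ with $u$ solved by `uniroot` from the closed-form expectation
$P(C<T) = \mathbb{E}[(1-e^{-hu})/(hu)]$ so the expected censored fraction
equals `censoringRate`; rate 0 means complete follow-up. Everything
derives from one integer seed (`withr::with_seed`), and identical
configurations are bit-reproducible.

What the generator does *not* emulate: batch and platform effects,
probe-level noise, copy-number or mutation structure, non-proportional
hazards, informative censoring, overlapping module membership. Passing the
planted-recovery suites therefore demonstrates correctness of the
machinery under the model's own assumptions, not robustness to everything
real cohorts contain.

# Study conditions used by the validation suites

The simulation-backed guarantees run at sizes chosen once as realistic for
the design: six cohorts of 150 samples, three shared 40-gene modules
(within-correlation 0.8/0.7/0.7), 180 background genes, nine risk genes in
the first module at hazard ratio 2.5 per unit score, baseline hazard
$\ln 2 / 730\,\mathrm{days}^{-1}$ (median two years at score 0), 20%
censoring, a 2-year actual-risk horizon; 50 permutations per preservation
call inside the 6×6 grid and 200 where a single call's calibration is the
claim; resampling validation on a 400-sample cohort with 100 RDs of 200.
Parameter-recovery criteria are evaluated as medians over 20 independent
seeds.

# Known limitations

* The static tree cut under-calls diffuse, weakly correlated modules; the
  dynamic hybrid algorithm would recover some of them.
* `Zsummary` composition uses the canonical four-statistic
  density+connectivity composite; implementations differ in the exact
  statistic roster, so numerical parity with any particular reference
  implementation is not a goal (classification agreement is).
* Fisher overlap p-values are uncorrected by design (matching device);
  multiple-testing control, if wanted, belongs downstream.
* Risk-gene identification and patient-level risk assignment are
  reconstructions of procedures whose originals are unpublished; both are
  flagged as such and kept behind small, documented rules.
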