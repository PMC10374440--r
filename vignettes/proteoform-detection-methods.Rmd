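---
title: "Methods: graph-based proteoform group detection from thermal profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-based proteoform group detection from thermal profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters and design decisions behind
`meltforms` — what each statistic assumes, which knobs matter, what the
simulation benchmark does and does not emulate, and where the design was
genuinely open.

## From reporter ions to fold changes

Peptide-spectrum-match reporter signal is summed to peptide level. Per
temperature channel, intensities are normalized by equalizing per-sample
medians in log space — a monotone per-sample rescaling. The detector
consumes *fold changes relative to the lowest temperature*, which are
invariant to any per-sample monotone rescaling of the channel, so the exact
flavor of variance-stabilizing transform is immaterial downstream; a full
arsinh-calibration could be substituted behind the same contract.

Zeros in the input are treated as missing, never as true signal: a zero
reference intensity masks the whole (peptide, cell line) series. Missing
data is carried as an explicit mask throughout; no imputation is performed.

## The similarity graph and its acceptance rules

For a gene with peptides $i, j$ over $N$ cell lines and $K$ temperatures,

$$d_{ij} = \sqrt{\sum_{n,k\ \mathrm{valid}} (x_i^{nk} - x_j^{nk})^2 \cdot
\frac{v}{NK}}, \qquad S_{ij} = \frac{1}{1+d_{ij}},$$

with $v$ the number of jointly observed grid points. The $v/NK$ factor
*shrinks* distances computed from sparse overlaps toward zero, pulling
poorly co-observed peptides together rather than apart. The opposite
completion ($NK/v$, an unbiased estimate of the full-grid distance) is
available as `distance_scaling = "unbiased"`; the shrinking form is the
default because it is the definition the acceptance threshold was
calibrated on. Pairs with $v = 0$ carry no information and are omitted from
the graph.

Leiden community detection runs with the modularity objective at resolution
1 and a fixed iteration budget, seeded and deterministic. Modularity is the
natural objective here because the acceptance rule is itself a modularity
threshold. On complete graphs of up to 8 vertices the test suite verifies
that the returned partition attains the exhaustively enumerated optimum.

A gene is *analyzed* only with ≥ 10 peptides, ≥ 2 quantified peptides in
every cell line where the gene appears at all, and a peptide ambiguity
ratio below 0.5. Accepted communities need ≥ 3 supporting peptides, and the
whole-gene partition must score $Q > 10^{-13}$. That threshold is best read
as "strictly positive": an unsplit gene has exactly $Q = 0$, and tiny
positive values of order $10^{-16}$ arise only from floating-point noise on
effectively unstructured graphs. $Q$ is evaluated on the partition as
returned by Leiden, before dropping sub-minimum communities — the dropped
peptides are reported as unassigned and excluded from proteoform profiles,
so that outlier peptides cannot contaminate accepted groups.

Groups are named `<gene>_1`, `<gene>_2`, … by decreasing size, ties broken
by the lexicographically smallest member peptide; genes not community-
resolved keep the single group `<gene>_0`. Size ordering is arbitrary but
reproducible.

## Sigmoid melting model

$$f(T) = \frac{1-p}{1+\exp(b - a/T)} + p$$

with plateau $p \in [0,1)$; for $a > 0$ the curve falls monotonically from
≈ 1 toward $p$. Fitting is nonlinear least squares with a multi-start
strategy: a grid of inflection candidates $T_0 \in \{44, 46, \dots, 60\}$ °C
and slopes $b \in \{25, 50, 100\}$ with $a = b\,T_0$, ranked by residual
sum of squares with the plateau profiled out analytically (the model is
linear in $p$ given $a, b$), and the best four starts refined by
Levenberg–Marquardt under box constraints. A numerically perfect start is
accepted directly — the Levenberg–Marquardt gradient is singular at an
exact solution — and a bounded quasi-Newton pass is the fall-back if every
refinement fails. Fits need ≥ 4 points; $S_\mathrm{res} =
\sqrt{\mathrm{RSS}/(n-3)}$, and fits with $S_\mathrm{res} \ge 0.1$ are kept
in outputs but flagged rejected.

The melting point is the closed form $T_m = a/(b - \ln(0.5/(0.5-p)))$,
undefined when $p \ge 0.5$ (the curve never crosses 0.5) — flagged, not an
error. Melting AUC integrates the fitted curve over the experiment's fixed
temperature window (default 41–63 °C, absolute tolerance $10^{-8}$) so that
values are comparable across cell lines.

## Differential melting (F across cell lines)

The alternative model fits one sigmoid per cell line, keeping lines with
$S_\mathrm{res} < 0.1$; the null model refits one shared sigmoid over the
kept lines only. The statistic is

$$F = \frac{\mathrm{RSS}^{(0)} - \mathrm{RSS}^{(1)}}{\mathrm{RSS}^{(0)}}
\cdot \frac{d_2}{d_1}, \quad d_1 = \nu_1 - \nu_0,\ d_2 = p_i - \nu_0,$$

with $\nu_0 = 3$, $\nu_1 = 3 \times$ kept lines, $p_i$ the kept
observations. This is deliberately *not* the classical partial-F (which
divides by $\mathrm{RSS}^{(1)}$ with $d_2 = p_i - \nu_1$); the published
form is implemented as the default and the classical variant is exposed as
`f_variant = "classical"` for comparability. Because heterogeneous
cell-line panels violate the parametric null, hits are called by empirical
percentile (90th, type-7 linear interpolation, threshold ties included)
rather than by an FDR threshold; the module reports F and rank, not
p-values. When the null model already fits at numerical precision the
statistic is 0 by convention.

## Co-aggregation and its differential statistic

High-confidence PPI annotations (combined score ≥ 950) are expanded to all
proteoform-pair combinations of the two genes. Per cell line, a pair's
co-aggregation statistic is the Euclidean distance between the two
fold-change curves over shared temperatures (≥ 4 required); the null is the
distance of uniformly sampled non-annotated proteoform pairs in the same
cell line, with the pseudo-count p-value $p = (1 + \#\{d_\mathrm{null} \le
d_\mathrm{obs}\})/(n_\mathrm{null}+1)$ and Benjamini–Hochberg adjustment
per cell line. The upstream reference for this test describes it only
operationally, so this empirical-null construction is the package's own
minimal, fully seeded implementation.

Pairs significant ($p_\mathrm{adj} < 0.1$) in ≥ 1 line enter the
differential analysis: per-line $\mathrm{RSS}_n = \sum_k (x_k^A - x_k^B)^2$
on measured fold changes (not fitted curves), sorted ascending, and

$$F = \frac{\mathrm{RSS}_{(n-1)} - \mathrm{RSS}_{(2)}}{\mathrm{RSS}_{(2)}}.$$

Using second-order statistics makes a single extreme cell line on either
end irrelevant: the statistic is large only when at least two lines
co-melt tightly *and* at least two differ strongly. $n$ counts the lines
where both proteoforms are quantified. $\mathrm{RSS}_{(2)} = 0$ yields an
infinity sentinel with a flag. The top decile of F is flagged.

## Drug-sensitivity association

Melting AUCs of differential-melting hits are regressed against sDSS per
(proteoform, drug) by ordinary least squares with exact t-based two-sided
p-values, jointly BH-adjusted; significance at $p_\mathrm{adj} < 0.1$.
Moderated (empirical-Bayes) variance shrinkage could be added behind the
same interface, but with a single predictor and shared $n$ per test the
ranking is essentially identical and plain OLS keeps the dependency
footprint small. Drugs are pre-filtered to those reaching sDSS ≥ 6 in at
least one cell line — the "minimal effect on any line" reading, which we
take as the intended one over the contradictory phrasing that would keep
drugs *below* the cutoff. Outlier cell lines (e.g. unspecifically
drug-sensitive ones) can be excluded by name.

## The simulation benchmark

`sim_config()` defaults describe the reference conditions: 1,000 negative
proteins and 200 positives (two proteoforms at ΔTm of 1, 2, 3, 4 °C, 50
proteins each; half of the peptides on each proteoform), base melting
points uniform in 50–60 °C, melting-point jitter SD 2 °C, fold-change noise
SD 0.1 with sub-zero draws forced to $10^{-3}$, 8 temperatures
(41–63 °C) × 20 cell lines, at 15 or 50 peptides per protein. Curves follow
the sigmoid above with $p = 0$ and $a = b\,T_m$ (so $f(T_m) = 0.5$
exactly), $b = 50$, normalized to the first temperature so the reference
channel is exactly 1 before noise.

The one genuinely open modeling choice is *where the melting-point jitter
lives*. Implemented and exposed are both readings:

- `per_measurement` (default): every peptide draws an independent Tm jitter
  in every cell line. Peptide-level melting variability is then stochastic
  measurement noise; peptides of a negative protein have no *reproducible*
  structure across cell lines. Under this mode negatives almost always
  yield a single community with $Q = 0$ at machine precision, which is
  exactly the regime in which a $10^{-13}$ modularity threshold is
  meaningful, detection sensitivity grows with ΔTm and coverage, and the
  empirical FDR of the detector stays within the advertised 10%.
- `per_peptide`: one jitter draw per peptide, shared across all cell lines.
  Every peptide then has its own genuinely distinct, fully reproducible
  melting behavior — a continuum of de-facto proteoforms. The detector
  (correctly) splits most such "negatives", so against labels that call
  them negative this mode produces a large apparent false-discovery rate.
  It is retained because persistent peptide-level differences (stable PTM
  pools, constitutive cleavage) are real phenomena worth simulating — but
  they are not *negatives*.

The default is `per_measurement` because it is the only reading consistent
with a near-zero modularity threshold acting as an FDR control, and because
benchmark negatives should be proteins with no reproducible proteoform
structure.

What the generator does *not* emulate: missing data (real deep-TPP tables
are sparse; the detector's masked distances handle this, the benchmark does
not exercise it), peptide ambiguity across genes, intensity-dependent noise
(noise is homoscedastic Gaussian on the fold-change scale), correlated
noise within TMT sets, and plateaus ($p = 0$ throughout). Passing the
benchmark therefore demonstrates correct behavior under idealized noise,
not robustness to all features of real data.

## Evaluation conventions

A protein counts as *detected* with ≥ 2 accepted groups; detection on a
positive is a true positive regardless of whether every peptide landed on
the right proteoform; FDR $= \mathrm{FP}/(\mathrm{TP}+\mathrm{FP})$, 0 when
nothing is detected. ROC analysis ranks proteins by partition modularity
(ties averaged). Threshold calibration scans a grid and returns the most
permissive threshold whose empirical FDR stays at or below the target,
maximizing sensitivity among compliant thresholds, and always reports the
full FDR-versus-threshold table.

## Problem sizes and numerical choices in the shipped checks

The test suite runs the full 1,200-protein benchmark in both peptide
settings once for the FDR check, and five seeds of a 210-protein
(150 negative + 60 positive) configuration per setting for the monotonicity
properties — sizes chosen to keep the whole suite in the minutes range
while leaving ≥ 15 positives per ΔTm level per seed. Exhaustive modularity
oracles stop at 8 vertices (Bell(8) = 4,140 partitions). Tolerances:
$10^{-12}$ for oracle equivalence, $10^{-9}$ for optimizer-dependent
nesting inequalities, quadrature at $10^{-8}$ absolute.

## Known limitations

- Modularity's resolution limit can merge small, adjacent-melting
  communities on large genes; sub-communities below 3 peptides are dropped
  rather than merged.
- The detector is calibrated on complete tensors; FDR under heavy
  missingness has not been characterized.
- The differential-melting F is reported without p-values by design; ranks
  are comparable within a dataset only.
- Empirical co-aggregation p-values are bounded below by
  $1/(n_\mathrm{null}+1)$; with the default 10,000 null pairs, BH-adjusted
  significance at 0.1 needs enough tested pairs per line to be reachable.
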