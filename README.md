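# meltforms

Detection of **functional proteoform groups** from deep thermal proteome
profiling (TPP), with downstream statistics for differential melting,
proteoform co-aggregation and drug-sensitivity association.

## The problem

Bottom-up proteomics quantifies peptides, not proteins. When a gene produces
several molecular forms — splice variants, cleavage products, differently
modified or differently complexed pools — those proteoforms can melt at
different temperatures in a TPP experiment, and the peptides covering them
inherit that behavior. `meltforms` turns this into a detector: peptides of a
gene whose melting fold-change profiles co-vary across many cell lines are
grouped into proteoform groups, without any prior isoform annotation.

The package is aimed at analysts of multi-condition TPP/CETSA panels
(e.g. cell-line cohorts profiled at 8 temperatures with TMT multiplexing)
who want peptide-resolved thermal phenotypes, and at method developers who
need a fully simulated, truth-labelled benchmark for proteoform detection.

## Method at a glance

For each gene, peptides are vertices of a complete weighted graph. Peptide
*i*'s fold change in cell line *n* at temperature *k* is $x_i^{nk}$
(relative to the lowest temperature), and edge weights are similarities

$$S_{ij} = \frac{1}{1 + d_{ij}}, \qquad
  d_{ij} = \sqrt{\sum_{n=1}^{N}\sum_{k=1}^{K}\left(x_i^{nk} - x_j^{nk}\right)^2
  \cdot \frac{v}{NK}},$$

where $v$ counts valid (jointly observed) comparisons. The graph is
partitioned with the Leiden algorithm (modularity objective); communities
become accepted proteoform groups when the gene has ≥ 10 peptides with ≥ 2
peptides per sample and ambiguity ratio < 0.5, the community has ≥ 3
supporting peptides, and the partition modularity exceeds $Q > 10^{-13}$
(a numerical-zero guard: unsplit genes score exactly $Q = 0$).

Downstream, per-proteoform melting curves are fitted with the sigmoid

$$f(T) = \frac{1-p}{1 + e^{\,b - a/T}} + p,$$

giving melting points ($f(T_m) = 0.5$) and melting areas under the curve.
Differential melting across cell lines uses a null (shared curve) versus
alternative (per-line curves) comparison with

$$F = \frac{\mathrm{RSS}^{(0)} - \mathrm{RSS}^{(1)}}{\mathrm{RSS}^{(0)}}
      \cdot \frac{d_2}{d_1},$$

calling proteoforms above the 90th F percentile. Differential
proteoform–proteoform co-aggregation uses the robust order-statistic
$F = (\mathrm{RSS}_{(n-1)} - \mathrm{RSS}_{(2)})/\mathrm{RSS}_{(2)}$ over
per-cell-line curve distances, and thermal stability (melting AUC) is
associated with selective drug sensitivity scores (sDSS) by linear
regression with joint Benjamini–Hochberg adjustment.

A seeded simulation benchmark (1,000 negative + 200 positive proteins, two
proteoforms separated by 1–4 °C, 8 temperatures × 20 cell lines, stated
noise levels) calibrates the detector's false discovery rate and ROC
behavior.

## Worked example

```r
library(meltforms)
library(dplyr)

# simulate a small benchmark: 60 single-proteoform and 40 two-proteoform
# proteins, 15 peptides each, 20 cell lines x 8 temperatures
cfg <- sim_config(n_negative = 60, n_positive = 40,
                  peptides_per_protein = 15)
sim <- simulate_benchmark(cfg, seed = 42)

assignments <- detect_proteoforms(sim$fold_changes, seed = 42)
assignments |>
  filter(!is.na(proteoform_id)) |>
  count(gene, proteoform_id, name = "peptides") |>
  filter(gene %in% c("SIMNEG0001", "SIMPOS0031"))
#> # A tibble: 3 × 3
#>   gene       proteoform_id peptides
#>   <chr>      <chr>            <int>
#> 1 SIMNEG0001 SIMNEG0001_0        15
#> 2 SIMPOS0031 SIMPOS0031_1         8
#> 3 SIMPOS0031 SIMPOS0031_2         7
```

The negative protein keeps a single unsplit group (suffix `_0`); the
positive protein's 15 peptides resolve into two groups of 8 and 7 peptides,
matching its two simulated proteoforms. Against the ground truth:

```r
ev <- evaluate_fdr(assignments, sim$truth)
sprintf("TP = %d, FP = %d, FDR = %.3f", ev$tp, ev$fp, ev$fdr)
#> "TP = 20, FP = 0, FDR = 0.000"
ev$sensitivity_by_delta
#> # A tibble: 4 × 4
#>   delta_tm     n sensitivity detected
#>      <dbl> <int>       <dbl>    <int>
#> 1        1    10           0        0
#> 2        2    10           0        0
#> 3        3    10           1       10
#> 4        4    10           1       10
```

Sensitivity rises with the melting-point separation of the two proteoforms:
1–2 °C shifts are hidden under the 2 °C melting-point noise, 3–4 °C shifts
are fully recovered, with no false detections here. Fitting one melting
curve:

```r
temps <- c(41, 44, 47, 50, 53, 56, 59, 63)
set.seed(1)
y <- melt_sigmoid(temps, a = 50 * 52, b = 50, p = 0.05) + rnorm(8, 0, 0.01)
fit_melt_curve(temps, y)
#> Sigmoid melting-curve fit
#>   a = 2758, b = 52.98, p = 0.05323
#>   S_res = 0.006661 (accepted), Tm = 52.16 degC, AUC = 11.69
```

The true melting point of 52 °C is recovered within 0.2 °C from
noise-corrupted fold changes. `glance()` returns the same fit as a one-row
tibble; `autoplot()` draws data and fitted curve.

A thin command-line front end over these functions ships in
`inst/scripts/meltforms` (subcommands `simulate`, `detect`, `benchmark`,
`nparc`, `coaggregate`, `drugassoc`, `init`), and `run_pipeline()`
orchestrates the full chain with a JSON run manifest.

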