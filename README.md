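# diasis

Spike-in SILAC quantification for data-independent acquisition (DIA)
proteomics in R.

## The problem

Label-free DIA quantification (LFQ) struggles with low-abundance proteins:
identifications drop out between replicates, missing values pile up, and
fold-change estimates for weak signals become unreliable. Spike-in SILAC
(SiS) addresses this by adding the *same* heavy-labelled reference proteome
to every light sample. Heavy peptides are chemically identical to their
light counterparts, co-elute, and share ion mobility, so the heavy channel
acts as an internal anchor in every run: quantification reduces to
light/heavy (L/H) ratios, and samples become comparable through a
ratio-of-ratios that cancels run-to-run technical variation.

`diasis` post-processes multiplexed DIA-NN `report.tsv` output into protein
abundances using this scheme. It is aimed at proteomics analysts who already
run DIA-NN on SILAC spike-in experiments and want a transparent, testable R
implementation of the downstream quantification, plus a synthetic
ground-truth benchmark to validate the whole chain without raw data.

## The method

Per precursor (label-stripped modified sequence + charge) and run, the light
and heavy records are paired and filtered on confidence
(`Global.PG.Q.Value < 0.01`, `Channel.Q.Value < 0.03`, charge > 1,
contaminants removed; all cutoffs strict). Two filtering modes exist:

* **basic** — both channels must pass;
* **requantify** — only the heavy reference must pass. Because a confident
  heavy identification certifies the elution window, a light partner that
  failed q-value filtering is rescued and its reported intensities are used
  (light signal is never imputed, only rescued).

Quantification then proceeds in log10 space:

1. precursor ratios `log10(L/H)` from `Ms1.Translated` and
   `Precursor.Translated` (both columns when both are valid and > 0);
2. protein × run L/H ratio = median over the pooled precursor ratios;
3. global heavy intensity per protein = median over runs of log10 of the
   per-run summed heavy precursor intensities;
4. light abundance: `abundance(p, r) = ratio(p, r) + heavy_global(p)`.

Since the heavy term is constant per protein, across-sample abundance
ratios equal across-sample L/H-ratio ratios, and the spike-in excess cancels
exactly. Two normalizations are provided: anchor-species normalization
(shift each sample so the species with a theoretical 1:1 ratio is centred
on the reference sample, per replicate pair) and run-median centring of L/H
ratios for designs without an anchor species. Differential abundance uses
two-sided Student t-tests on per-replicate log2 abundances without multiple
testing correction, with strict cutoffs p < 0.01 and |log2FC| > 1, and
precision-recall curves restricted to negative fold changes.

The package also ships a synthetic two-species benchmark generator
(`simulate_report()`): an anchor proteome constant across samples, a second
proteome diluted down to 1:50, a heavy spike-in at configurable excess
(2×/5×/20×), correlated quantification columns, intensity-dependent
detection, channel q-values with a configurable bad-ID fraction, and
contaminants — with the ground truth returned alongside.

## Worked example

```r
library(diasis)

design <- benchmark_design(n_replicates = 4)         # S1 = 1:50, S2 = 1:5, S3 = 1
config <- simulation_config(n_proteins_per_species = 200, seed = 42)
sim <- simulate_report(design, config)

records <- records_from_report(sim$report) |>
  flag_contaminants(prefix = "Cont_")

quant <- sis_quantify(records, filter_policy("sis_requant"))
glance(quant)
#> # A tibble: 1 × 5
#>   mode        n_proteins n_runs n_precursor_ratios rescued_fraction
#> 1 sis_requant        400     12              38482           0.0655
```

All 400 simulated proteins are quantified across the 12 runs; 6.6% of the
precursor ratios were rescued by requantify (light side admitted on the
strength of its heavy partner). Normalize, test, and score against the
known dilution design:

```r
abundance <- anchor_normalize(tidy(quant), design)
results <- ttest_diff(abundance, design) |> classify_hits(p_cut = 0.01, fc_cut = 1)
score <- score_against_truth(results, ground_truth(design, config))
score
#> # A tibble: 2 × 7
#>   comparison n_scored n_positive n_negative false_positives true_positives
#> 1 S1_vs_S3        354        157        197               0            157
#> 2 S2_vs_S3        390        193        197               0            193
#> per-tier accuracy:
#>   comparison expected_log2fc     n median_bias mad_spread
#> 1 S1_vs_S3             -5.64   157     0.00677      0.173
#> 2 S1_vs_S3              0      197     0.00105      0.175
#> 3 S2_vs_S3             -2.32   193     0.0467       0.166
#> 4 S2_vs_S3              0      197     0.00884      0.164
```

No anchor-species protein is misclassified as differentially abundant
(`false_positives = 0`), every truly diluted protein is recovered, and the
median bias against the true log2 fold changes (−5.64 at 1:50, −2.32 at
1:5) is below 0.05 log2 units. `plot_volcano(results)`,
`plot_pr_curve(precision_recall(results, truth))` and
`plot_completeness(completeness(abundance, design))` draw the standard
displays.

A thin command-line wrapper over the same functions lives at
`inst/cli/diasis.R` (subcommands `simulate`, `quantify`, `normalize`,
`diffabund`, `benchmark`; see its header for usage).

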