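---
title: "Spike-in SILAC quantification for DIA: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-in SILAC quantification for DIA: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diasis)
```

## The quantification model

A spike-in SILAC (SiS) experiment adds one heavy-labelled reference
proteome, in identical amount, to every light sample before acquisition.
For a precursor observed in run $r$ with light intensity $L$ and heavy
intensity $H$, the quantity carried forward is $\log_{10}(L/H)$. Because
the heavy channel is the same material in every run, the ratio is free of
run-level technical effects that act multiplicatively on both channels —
this is the channel-balance invariance the test suite asserts to 1e-12.

Protein-level ratios are the median of all precursor ratios of that
protein in that run, pooling the two DIA-NN quantification columns
(`Ms1.Translated` and `Precursor.Translated`) into a single list. The
median is deliberately preferred over a mean: precursor ratio lists are
short (often 2–20 values) and occasionally contain interference-driven
outliers, and the median's breakdown point buys robustness at negligible
efficiency cost at these sizes.

Absolute light abundances are reconstructed by adding, in log10 space, a
per-protein *global heavy intensity*: the median over runs of the log10 of
the per-run sum of heavy precursor intensities. Two consequences follow
directly from the arithmetic and are enforced as exact tests:

* across-sample abundance differences equal across-sample ratio
  differences (the heavy term cancels);
* changing the spike-in excess globally leaves every light abundance
  unchanged (ratios shift down, the heavy term shifts up by the same
  amount).

Within the per-run heavy sum, a missing intensity column counts as 0 (it
is a sum over reported intensities), whereas ratio computation requires
strict positivity of both sides — two different contracts, both
deliberate. Runs whose heavy sum is 0 are excluded from the median rather
than entering as $\log_{10} 0 = -\infty$.

## Filtering and the requantify rescue

All q-value filters are strict inequalities, so records sitting exactly at
a threshold are excluded, and a missing tested q-value fails its filter —
the conservative choice for a confidence filter. The defaults are
`Global.PG.Q.Value` < 0.01 and `Channel.Q.Value` < 0.03 per channel,
charge > 1, contaminants removed; label-free (LFQ) comparator data instead
use `Lib.PG.Q.Value` < 0.01 and `Lib.Q.Value` < 0.01 and quantify via
`log10(PG.MaxLFQ)`.

The *requantify* mode exploits the physics of the spike-in: light and
heavy partners co-elute and share ion mobility, so a confident heavy
identification certifies that the instrument sampled the right elution
window. If only the heavy channel passes filtering, the light partner is
admitted anyway and its reported intensities are used. Three boundaries of
this rule matter:

* a pair whose heavy side is absent or fails is always dropped — the
  reference must be confident;
* a light record that is absent from the report entirely cannot be
  rescued; the rescue uses reported light values and never invents signal
  from the heavy channel;
* a rescued light record still passes through the translated-column
  validity rule at ratio time. Applying that rule after pairing (rather
  than before) is the only order under which the `any` rule can rescue a
  record with one sparse column, which is exactly the situation the rule
  exists for.

The validity rule defaults to `both` (both quantification columns present
and > 0), the appropriate choice for standard-input data; `any` is a
policy switch for very low-input data where one column is systematically
sparse. Retention under requantify is provably a superset of basic
filtering with identical ratios on the intersection, and the suite checks
this on 50 randomized instances.

## Normalization

Two schemes are implemented:

* **Anchor normalization** for designs containing a species with a
  theoretical 1:1 across-sample ratio. For each non-reference sample and
  replicate index, the shift is the median abundance difference to the
  reference run of the same replicate, over anchor proteins present in
  both runs; it is subtracted from every protein in that run. The
  reference sample is never shifted. Computing one shift per replicate
  pair (rather than one pooled shift per sample) is the more granular
  reading of a per-replicate ratio design and makes the postcondition —
  anchor median ratio exactly 1 per pair — exact; a `pooled` switch
  provides the coarser variant.
* **Run-median centring** of protein L/H ratios, for designs without an
  anchor species (e.g. super-SILAC references for tissue): each run's
  ratio median is subtracted before abundance reconstruction.

Both operations are idempotent, and their postconditions hold to 1e-12 in
the test suite.

## Differential abundance and evaluation

Across-sample log2 fold changes are computed per replicate pair as
$(\log_{10} a_S - \log_{10} a_{ref}) \cdot \log_2 10$; all log arithmetic
is kept in base 10 internally and converted to base 2 once, at this
boundary. A protein enters a comparison only with a value in every
replicate of both samples — no imputation anywhere in the pipeline,
which is a design position: the spike-in exists to make imputation
unnecessary, and imputing around the detection limit would fabricate
downregulation for proteins that are merely unmeasured.

Significance uses a two-sided pooled-variance Student t-test on the
per-replicate log2 abundances of the two samples (Welch by flag), with no
multiple-testing correction, and strict cutoffs p < 0.01 and
|log2FC| > 1. Degenerate inputs (zero pooled variance) yield an undefined
p-value, reported as missing and never as 0 or as significant. The
implementation is a vectorized closed form; `stats::t.test` serves as an
independent oracle in the tests, and null calibration is checked by a
Kolmogorov–Smirnov uniformity test on 5000 simulated null p-values.

Precision-recall curves are restricted to proteins with negative observed
fold changes (the diluted species can only go down; positive fold changes
carry no signal for the benchmark question), ranked by increasing log2FC
or p-value, with tied scores entering a threshold together and the recall
denominator fixed to the positives of the restricted set. The sweep is
verified against a brute-force enumeration oracle.

## The synthetic benchmark

`simulate_report()` emulates a two-proteome spike-in benchmark: an anchor
species constant across samples, a diluted species at per-sample factors,
and a heavy channel at `spike_excess` times the maximum light amount. The
generator's defaults are the study conditions used throughout:

| parameter | default | rationale |
|---|---|---|
| `n_proteins_per_species` | 500 | enough proteins per tier for stable medians at desk scale |
| `precursors_per_protein` | 5 | typical DIA support per protein; a 1–20 range is available |
| dilution factors | S1 = 1/50, S2 = 1/5, S3 = 1 | 1:50 is the design's extreme tier; the intermediate tier is a realistic mid dilution; the reference is undiluted |
| `spike_excess` | 2 | a moderate excess; 2/5/20 span the sweep of interest |
| `baseline_log10_mean/sd` | 4.5 / 0.8 | spans the 3–7 decade dynamic range typical of DIA precursor intensities |
| `precursor_log10_sd` | 0.6 | ionisation efficiency spread between peptides of one protein |
| `measurement_noise_sd` | 0.1 | log10-scale replicate noise of a well-behaved DIA quantification |
| `column_correlation` | 0.8 | the two quantification columns derive from the same signal and are strongly, not perfectly, correlated |
| detection midpoint / slope | 2.4 / 2.5 | logistic detection on true log10 intensity: near-complete detection above ~10^3, fading below; this reproduces the premise that the abundant heavy reference is detected where faint light signal is not, giving requantify something to rescue |
| `fraction_bad` | 0.02 | small fraction of bad IDs with uniform channel q-values; good IDs draw from Beta(1, 99) |
| `contaminant_fraction` | 0.01 | light-only contaminant proteins under a `Cont_` prefix |

Randomness is organised as per-protein substreams derived from the master
seed, so changing the replicate count does not reshuffle protein
baselines; a fixed seed makes the report byte-identical across runs.

What the simulator does *not* emulate — and therefore what passing tests
do not demonstrate about real data: ratio compression from co-fragmented
interference (measured fold changes shrinking toward 1 at high spike
excess is an empirical observation without a specified mechanism; the
default generator is compression-free, which is precisely what makes the
heavy-excess invariance exact), retention-time or mobility structure,
peptide-level systematic effects such as missed cleavages or labelling
inefficiency, protein inference ambiguity beyond simple groups, and FDR
behaviour of a real search engine (q-values are drawn from a stylised
good/bad mixture, not calibrated to decoys). The detection model depends
on true, not observed, intensity, so simulated data contain no
selection-on-noise bias; real data may.

The generator also leaves the noise level of rescued light signal
identical to that of confidently identified signal. Real rescued records
are expected to be noisier; a study of that effect should inflate
low-intensity noise explicitly rather than rely on the default.

## Problem sizes and numerical choices

The full-scale validation uses 500 proteins per species, 5 precursors per
protein and 4 replicates — the scale at which median recovery of the
extreme 1:50 tier is stable to a few percent — and runs in well under a
minute. Property checks use smaller instances (8–40 proteins, 2–3
replicates) across many random seeds. Exactness assertions (algebraic
invariances, normalization postconditions) are made at 1e-12; assertions
involving a chain of log/exp arithmetic use 1e-9.

Tie-breaking and degenerate-input conventions, collected: even-length
medians take the mean of the two central values (the R convention);
zero-sum heavy runs are excluded from the global-heavy median; proteins
whose group maps to two species are excluded from benchmark scoring with a
warning; an empty precursor-ratio set emits no protein entry rather than
an NA row; `PG.MaxLFQ` values must be constant within a protein × run and
nonpositive values are dropped with a count.

## Known limitations

The pipeline consumes DIA-NN protein groups as given and performs no
inference of its own. The channel encoding of multiplexed DIA-NN reports
varies between minor versions; the reader supports a dedicated channel
column plus a fallback on the modified-sequence label decoration, but
other encodings would need a new dialect. Requantified ratios are, by
construction, lower-precision than doubly-confident ones — the
`rescued_fraction` column exists so downstream analyses can stratify or
down-weight them.
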