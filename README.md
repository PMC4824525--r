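# swathtools

Processing, quality control, FDR estimation and format conversion for
SWATH-MS/DIA peakgroup tables.

## The problem

Data-independent acquisition (SWATH-MS/DIA) pipelines such as OpenSWATH
score and quantify thousands of targeted precursor peptides per injection
and export the result as a large tab-delimited *long-format* table: one row
per quantified precursor (peakgroup) per MS injection, carrying the protein
assignment, an identification confidence score (the m-score; smaller is
better), the quantified signal, a decoy flag, and the `";"`-joined
per-transition annotations and areas.  Downstream statistical tools —
MSstats (differential expression), mapDIA (wide fragment-level input) and
aLFQ (absolute quantification) — each require their own input schema, and
before conversion the table usually needs to be annotated with the study
design, quality-checked across replicates, FDR-controlled and filtered.

`swathtools` covers that processing layer for R users: it reads the
long-format table (with a dialect mechanism for non-OpenSWATH headers),
joins the experimental design, computes replicate QC metrics, estimates the
identification FDR from decoy counts, calibrates m-score thresholds for a
target FDR, filters the data with decoy-symmetric filters, and emits the
three downstream formats.

## The FDR model

A unit — an **assay** (modified peptide sequence × precursor charge), a
**peptide** (modified sequence) or a **protein** (accession set) — is
identified at m-score threshold *c* when its best (minimum) score over all
its rows passes *c*.  With *T(c)* distinct passing target units and *D(c)*
distinct passing decoy units, the estimated FDR is

```
FDR(c) = FFT · D(c) / T(c)
```

where FFT ∈ (0, 1] is the *fraction of false targets* (π₀), the correction
factor for the ratio of decoys to false targets.  FFT = 1 is the naive
target–decoy estimate and never understates the FDR.  Estimates are
available globally across runs (`estimate_fdr_overall()`) and stratified by
run (`estimate_fdr_by_run()`), and `mscore_for_fdr()` inverts the estimate:
it returns the most permissive threshold on a quarter-decade grid whose
estimated FDR stays at or below a target, together with the achieved FDR.

Because false positives accumulate when many runs are combined, and because
distinct-unit counting collapses targets faster than decoys, peptide- and
protein-level FDR typically exceed assay-level FDR — which is exactly why
the threshold calibration is exposed per level.

A synthetic-data generator (`simulate_peakgroups()`) produces OpenSWATH-like
tables with ground-truth true-target / false-target / decoy labels, so the
estimator, the filters and the converters are all testable without any
external download; `true_fdr()` computes the label-based truth the estimator
is validated against.

## Worked example

```r
library(swathtools)

sim <- simulate_peakgroups(sim_config(seed = 42))   # 2 conditions x 2 replicates
t <- annotate_samples(sim$data, sim$design)
t
#> peakgroup_table: 1264 rows, 4 run(s), 334 assay(s), 636 decoy row(s)
#>   annotated: yes

assess_decoy_rate(t)
#> decoy rate: 145 decoy / 145 target peptides (ratio 1)

estimate_fdr_overall(t, fdr_parameters(fft = 0.1))
#> fdr_table (fft = 0.1), 77 thresholds
#>   assay    at m-score 0.1: 154 targets, 58 decoys, FDR 0.03766
#>   peptide  at m-score 0.1: 136 targets, 55 decoys, FDR 0.04044
#>   protein  at m-score 0.1: 64 targets, 39 decoys, FDR 0.06094

th <- mscore_for_fdr(t, "protein", target_fdr = 0.01, fdr_parameters(fft = 0.1))
#> mscore_for_fdr: threshold 0.01 achieves protein FDR 0.00625 (target 0.01)

f <- filter_on_min_peptides(
       filter_mscore_condition(
         filter_proteotypic(t), unclass(th), min_obs = 2), 2)
#> filter_proteotypic: kept 1134 of 1264 rows (300 of 334 assays)
#> filter_mscore_condition: kept 498 of 1134 rows (133 of 300 assays)
#> filter_on_min_peptides: kept 462 of 498 rows (123 of 133 assays)

ms <- to_msstats(disaggregate(f))
nrow(ms)
#> [1] 2098
```

Reading the output: the simulated study has 4 injections with one decoy per
target peptide (ratio 1).  At the loosest threshold (m-score 0.1) the
FFT-corrected protein FDR is ~6%, so `mscore_for_fdr()` tightens the cutoff
to 0.01, where the estimated protein FDR is 0.6%.  The filter chain keeps
proteotypic peptides observed in at least 2 replicates of a condition at
that cutoff, on proteins with at least 2 remaining peptides; the surviving
462 peakgroups disaggregate into 2098 transition rows ready for MSstats.

The same chain is available from a shell via the bundled CLI wrapper:

```sh
Rscript inst/scripts/swathtools-cli.R simulate --output sim --seed 42
Rscript inst/scripts/swathtools-cli.R annotate --input sim_data.tsv \
    --design sim_design.tsv --output annotated.tsv
Rscript inst/scripts/swathtools-cli.R filter --input annotated.tsv \
    --output filtered.tsv --proteotypic --mscore 0.01 --min-obs 2
Rscript inst/scripts/swathtools-cli.R convert-msstats \
    --input filtered.tsv --output msstats.tsv
```

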