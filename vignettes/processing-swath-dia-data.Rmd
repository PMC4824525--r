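---
title: "Processing SWATH-MS/DIA peakgroup tables: models, defaults and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing SWATH-MS/DIA peakgroup tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swathtools)
```

## The data model

`swathtools` operates on the long-format peakgroup table produced by
OpenSWATH-style DIA pipelines: one row per quantified targeted precursor
peptide per MS injection.  Four fields are mandatory — the protein
assignment, the injection identity (filename), the quantified signal, and
an identification confidence score (m-score, in (0, 1], smaller = more
confident) present for targets and decoys alike.  Everything else
(stripped sequence, retention time, aggregated transition strings,
annotation columns) is optional and passes through untouched.

Three conventions of the format deserve care, and the reader enforces all
of them at load time:

* **Protein multiplicity.** Peptides mapping to several proteins carry a
  leading `"N/"` prefix with slash-joined accessions (`"2/P0A1/P0B2"`).
  `parse_protein_name()` splits this into an integer mapping count plus the
  accession list, so the proteotypic filter never works on raw strings.
* **Decoy marking.** Decoys are flagged by an explicit 0/1 column and/or a
  `"DECOY_"` substring in the protein name.  The explicit column wins when
  present; when both exist they must agree, and a disagreement is a hard
  error rather than a silent choice, since every FDR quantity depends on
  this flag.
* **Aggregated transitions.** `aggr_fragment_annotation` and
  `aggr_peak_area` are `";"`-joined with equal cardinality per row; a
  mismatch is rejected with the row index.

Rows whose score is missing, non-finite or outside (0, 1] do occur in
practice (re-quantified rows in some pipelines carry sentinel scores).
They are kept — they still convert — but are excluded from FDR estimation
and score filters, and their count is reported once at load.

Tables are written back as tab-separated UTF-8 with the OpenSWATH header
vocabulary and no quoting.  Floating point values use the shortest decimal
representation that reproduces the double exactly, which makes
write→read→write byte-stable and lets round-trip tests assert bit
equality.

## Annotation

`annotate_samples()` joins a (Filename, Condition, BioReplicate, Run)
design table by exact filename, or by substring when the design lists
basenames and the data carries full paths.  One injection is one run by
default; an explicit Run column overrides.  Replicate labels are opaque —
only grouping matters, never ordering.  When the design is encoded in the
filenames themselves, `design_from_filenames()` extracts it from delimited
tokens of the basename.

## Replicate QC

* `count_analytes()` — distinct target precursors, peptides and proteins
  per run.
* `correlation_between_samples()` — pairwise-complete correlations of
  analyte intensities matched on (modified peptide, charge).  The default
  is Pearson on log2 intensities, since MS intensities are compared on the
  log scale in practice; Spearman on raw intensities is exposed for
  monotone nonlinear distortions.  Pairs sharing fewer than 3 analytes are
  reported as undefined rather than as a meaningless coefficient.
* `signal_matrix()` — analyte × run matrices: peptide level sums intensity
  over charge states, protein level over the protein's peptides.  Both
  aggregations conserve the total target signal (asserted to 1e-9 relative
  in the tests).
* `cv_table()` — coefficients of variation (sample sd / mean, raw
  intensity scale, n−1 denominator; CV is conventionally reported on the
  natural scale) within each condition's replicates and across all
  samples.  Analytes with fewer than two finite observations in a scope
  are excluded; single-replicate conditions are excluded from the
  within-replicate scope with a warning.

Decoys are excluded from every QC output: QC describes the measured
targets, decoys belong to FDR estimation.

## FDR estimation

The estimator is the target–decoy count with the fraction-of-false-targets
correction.  A unit's score is the minimum m-score over its rows (a unit is
identified if its best evidence is); at threshold $c$,

$$\widehat{\mathrm{FDR}}(c) = \mathrm{FFT} \cdot \frac{D(c)}{T(c)},$$

with $T$ and $D$ counts of *distinct* passing target and decoy units.
Units are counted at three levels:

* assay = (modified peptide sequence, precursor charge);
* peptide = modified peptide sequence (the modified rather than stripped
  sequence, configurable in principle, because two modification states are
  distinct identifications);
* protein = the accession set after stripping the multiplicity prefix and
  the decoy marker; a protein passes as soon as any of its peptides'
  assays passes.

Choices that needed fixing where the format leaves room:

* **FFT default 1.0.** FFT is an input, not something estimated from the
  score distribution; 1.0 is the conservative upper bound.  When the decoy
  library is the same size as the target library, the appropriate FFT is
  the believed fraction of false targets among all targets.
* **Threshold grid.** Quarter-decade steps $10^{-k/4}$, $k = 4 \dots 80$
  (1e-1 down to 1e-20).  The threshold search is therefore
  resolution-limited, which is why `mscore_for_fdr()` always reports the
  achieved FDR next to the returned threshold.
* **$T = 0$ cells.** FDR is undefined (NaN), never 0 — an empty passing
  set is not evidence of purity — and such cells are skipped by the
  threshold search.
* **Runs without decoys** (in `estimate_fdr_by_run()`) are flagged
  undefined for the same reason: there is no estimate to report.

## Filtering

All filters share two properties.  First, **decoy symmetry**: no predicate
reads the decoy flag (protein-based grouping uses the name with the
multiplicity prefix stripped but the decoy marker kept), so targets and
decoys are filtered identically and the decoy-estimated FDR remains
interpretable after filtering — on a fixture whose decoys mirror the
targets row-for-row, every filter removes exactly equal numbers of both.
Second, **unit-wholesale semantics** for the observation filters: when an
assay qualifies (passing the cutoff in enough runs or replicates), *all*
its rows are kept, including sub-threshold ones in other runs, because
downstream tools impute or weight across runs; dropping sub-threshold rows
is `filter_mscore()`'s job, applied separately if wanted.

`filter_mscore_condition()` defaults to the *any-condition* reading
(pass in ≥ n replicates of at least one condition), which retains
condition-specific proteins; the stricter every-condition reading is a
flag, not an assumption.  Top-n peptide ranking uses intensity summed over
all runs ("highest intense" is otherwise undefined per-run) with
lexicographic tie-breaks for determinism.  Filters preserve row order,
compose in any order, and attach a removal report (rows and assays
before/after).

## Conversion

`disaggregate()` splits each peakgroup into one row per transition
(token order preserved, so re-aggregation is byte-identical), processing
the table in chunks so memory stays proportional to the chunk size.  The
three converters emit byte-exact header schemas:

* **MSstats** — the 10 canonical columns; `IsotopeLabelType` constant
  `"L"`; `ProductCharge` parsed from a configurable `"_<charge>"` suffix of
  the fragment annotation, empty when not encoded.
* **mapDIA** — wide format, one intensity column per sample ordered by
  (condition, replicate); missing cells are `0` because mapDIA's numeric
  parser expects a number; the RT column is optional behind a flag since
  not every table carries retention times.
* **aLFQ** — run/protein/peptide/transition identifiers with the peakgroup
  intensity as the peptide-level quantity and `"?"` placeholders where no
  concentration map is supplied.

Decoy rows are excluded from all converter outputs by default (downstream
statistics assume targets); `keep_decoys = TRUE` overrides.

## The synthetic-data generator

`simulate_peakgroups()` emulates the input contract, not the instrument.
Its defaults are the package's fixed study conditions, shaped like a small
two-condition SWATH experiment: 2 conditions × 2 biological replicates
(4 injections), 50 proteins with 2–4 peptides of 3–6 transitions, 10% of
peptides mapping to two proteins, 20% of peptides measured at a second
charge state, one mirrored decoy per target peptide, 10% false targets,
log-normal abundances with ~15% replicate CV (σ = 0.15 on the natural-log
scale, so CV ≈ √(e^{σ²}−1) ≈ 0.151), a 2-fold condition effect on 20% of
proteins, and 5% per-run dropout.

The score model is the crux.  True targets draw
log₁₀(m-score) ~ Normal(−5, 1.5) truncated at 1, so most true targets are
confidently identified with a tail of marginal ones.  False targets and
decoys draw from a single shared Uniform(0, 1) null — the p-value-like null
under which a decoy's chance of passing any threshold equals a false
target's.  That identity is precisely the assumption that licenses the FFT
correction, and with one decoy per target peptide the correct correction
factor equals the generated false-target fraction exactly.  The generator
draws everything from one RNG stream keyed by the seed (the caller's RNG
state is restored), so fixtures are reproducible byte-for-byte.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: correlated noise between co-eluting analytes,
interference and integration errors in transition areas, retention-time
drift, score distributions with run-specific batch structure, and decoy
libraries whose score null deviates from the false-target null.  On real
data the FFT itself is uncertain; the conservative default (1.0) exists for
exactly that reason.

Falseness is generated at the peptide level.  Assay- and peptide-level
truth are therefore well defined, and the estimator's calibration is
validated at the assay level; at the protein level "the protein is false"
is only defined when *all* of a protein's peptides are false (the standard
protein-FDR ambiguity for mixed proteins), so protein-level truth is used
for ordering properties rather than tight recovery bounds.

## Validation design and problem sizes

The test suite validates each layer against an independent oracle:

* unit counting against brute-force enumeration on 100 random tables of up
  to 50 rows, at every grid threshold and level;
* estimator calibration on 40 generated studies (false-target fraction 0.1
  and 0.3, 20 seeds each): with FFT set to the generator's true fraction,
  the estimate stays within 3 Monte-Carlo standard errors of the
  label-computed FDR at every threshold with ≥ 20 passing targets, and with
  FFT = 1 it is conservative in ≥ 95% of cells.  The per-cell standard
  error combines Poisson noise on the decoy count with counting noise on
  the false fraction: $\mathrm{SE}^2 = \mathrm{FFT}^2 D/T^2 + F(T-F)/T^3$;
* threshold calibration by self-consistency: filtering at the returned
  threshold and re-estimating never exceeds the target;
* filters against brute-force rule evaluation and the mirrored-decoy
  symmetry fixture;
* converters against frozen byte-exact headers and row-count identities;
* the CV and correlation metrics against two-point closed forms and a
  simulation recovery run with 8 replicates (two replicates estimate an
  individual CV too noisily for a recovery check; the median over ~150
  peptides at n = 8 recovers the σ-implied CV within ~12%).

These sizes (50-protein studies, ≤ 50-row enumeration tables, 40 seeds)
were chosen so each oracle has enough units to be sharp while the whole
suite stays fast enough to run habitually.

## Known limitations

* FFT is user-supplied; no model-based π₀ estimation from the score
  distribution is attempted, and no q-values are computed (both are the
  job of the upstream rescoring or of dedicated tools).
* Peptide-to-protein inference is limited to the multiplicity prefix; no
  protein grouping/parsimony is performed.
* The study design supports one hierarchy level, (condition, biological
  replicate, run); fractionation or technical-replicate nesting must be
  flattened by the user.
* Plots (`plot.fdr_table()`, `plot.cv_table()`, `plot_correlation()`) are
  base-graphics conveniences; the tabular outputs are the tested contract.
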