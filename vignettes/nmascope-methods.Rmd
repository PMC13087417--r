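---
title: "Models and methods behind nmascope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nmascope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmascope)
```

# Scope

nmascope implements the computational backbone of a genotype–phenotype
study of non-muscle actinopathies: disorders caused by constitutional
variants in *ACTB* and *ACTG1*, the two cytoplasmic actin genes. Four
analysis engines (saturation SNV simulation, rule-based clinical
classification, embedding-space cohort statistics, biophysical curve
fitting) sit on top of a family of seeded synthetic-data generators, and a
pipeline driver wires them together with plain-file handoff. This vignette
explains the models, their assumptions, the tunable parameters, and the
design choices made where the method description left the design open.

# Saturation SNV simulation

## Model

A `transcript_model` carries a coding transcript: genomic window, strand,
exon intervals, the ORF footprint (`cds_intervals`, including the stop
codon) and the coding-strand CDS sequence. Coordinates are 1-based
inclusive throughout, the VCF/gnomAD convention, and interval lists are
ordered 5'→3' on the coding strand. Validation enforces the ORF grammar
(starts `ATG`, ends in a stop, length divisible by 3, no internal stop) and
the exon geometry; every violation is reported by name.

`enumerate_snvs()` emits exactly 3 alternates per reference position,
ordered by `(genomic_pos, alt)`. The default `region = "coding_only"` is
the counting basis that makes a 375-residue actin ORF + stop yield 1,128
reference positions and 3,384 alternates per transcript; `full_window`
additionally enumerates intronic/UTR positions (it needs the window
sequence, which the generator always provides). Whether the original
analysis annotated-and-excluded non-coding alternates or never enumerated
them is not decidable from the text, which is why both behaviors are
exposed behind one flag.

## Consequence annotation

The annotator is internal by design — no external predictor is called, so
the package runs offline and the annotation logic is pinned by an oracle
test (below). Each alternate maps to exactly one class using the severity
hierarchy **splice_canonical > start_loss > stop_gain > stop_loss >
missense > synonymous**; canonical splice sites are defined as the 2
intronic bases flanking each junction, so the splice class never competes
with a coding class and the hierarchy only resolves codon-level readings
(any change in codon 1 is a start loss; a change in the terminal stop codon
is a stop loss unless the new codon is again a stop, which is reported
synonymous). Minus-strand models are handled by complementing the forward-
strand alleles onto the coding strand before codon lookup; a property test
checks that a CDS laid out on either strand yields identical consequence
multisets.

**NMD rule.** A stop-gain allele escapes nonsense-mediated decay if the
first base of the new stop codon lies in the last exon or within 50 nt
upstream of the last exon–exon junction (mRNA coordinates over the full
exon structure, so UTR-containing exons are handled); single-exon
transcripts always escape. The 50-nt boundary is inclusive. This is the
standard rule used to split truncating alleles into NMD-subject and
NMD-escape groups.

**Oracle.** On transcripts with ≤ 60-nt CDS the test suite classifies every
alternate a second way: rebuild the full mutant ORF, translate it
completely, and compare whole protein products. The two routes must agree
exactly. Synonymous/missense/nonsense tallies are additionally checked
against direct codon-table enumeration.

## Population comparison

`summarize_consequences()` joins the enumeration against a population
variant table keyed by `(chrom, pos, ref, alt)`. Sub-table provenance
travels as a `tag` column; union counts deduplicate by key (a row present
in two tagged sub-tables counts once) and per-tag tallies are reported
alongside. "Frequency" is taken from an `AF` column when present and from
`AC/AN` otherwise, since the original column choice is not documented.
Observed variants the enumeration cannot contain (indels, out-of-window
rows) are counted separately rather than dropped silently; an SNV row whose
ref contradicts the model's base at that position is skipped with a per-row
warning and counted. gnomAD's default 75-nt exon padding is reproduced by
`filter_population_window(pad = 75)`.

# The diagnostic workflow as a rule engine

The published workflow is a figure, not pseudocode, so the engine fixes an
explicit rule order and records the full trace of fired rules with every
assignment — the implemented reading is inspectable rather than implied.
The order is: (1) gene + variant-class routing (ACTG1 truncating point
variants → likely benign; ACTG1 whole-gene deletion → contiguous 17q25
deletion group; any ACTB pLoF or deletion → *ACTB* pLoF disorder,
regardless of the NMD call, since NMD-subject and NMD-escape carriers were
found clinically comparable); (2) the functional-LoF arm (ACTB
missense/in-frame with the ACTB-LoF gestalt and no frontal pachygyria);
(3) DDS1, gated on the exact token `Arg183Trp` in *ACTB* plus dystonia or
deafness; (4) BWCFF on gestalt **and/or** frontal pachygyria, split
BWCFF1/BWCFF2 by gene; (5) ACTG1 isolated hearing loss with no other flag
present; (6) provisional unNMA for remaining protein-altering carriers;
(7) unclassifiable otherwise (splice alleles have no published arm).

Phenotype flags are tri-state (`present`/`absent`/`unknown`). Rule
predicates treat `unknown` as not-present — the same counting convention
the original phenogrid used for incomplete clinical information — but the
tri-state value is preserved in the record for audit. Where the experts'
conflict resolution is not documented (e.g. a BWCFF gestalt co-occurring
with isolated hearing loss), the fixed order encodes one defensible
reading: it is flagged here as a package choice, not asserted as the
original authors' intent. DDS1 deliberately outranks BWCFF so that the one
genotype with a pathognomonic association is never absorbed by the broader
gestalt arm; a monotonicity test guarantees that adding pachygyria can
never move a record *out* of BWCFF.

# Embedding-space cohort statistics

Facial photographs are consumed only as encoder output: one 512-dimensional
vector per image. Similarity is cosine distance, `1 − u·v/(‖u‖‖v‖)`,
bounded in [0, 2] and invariant to positive rescaling; `mean_pairwise()`
averages all cross pairs (between-group) or all unordered distinct pairs
(within-group) and is pinned to a brute-force double loop in the tests.

Control distributions are resampled from a mixed-syndrome pool: pairs of
equally sized cohorts drawn from the same syndrome versus from two
different syndromes. The decision threshold is derived by ROC analysis;
the operating criterion — not named in the method description — is the
Youden-J maximum over an exhaustive scan of candidate thresholds (midpoints
of adjacent pooled values), ties broken toward the larger threshold. The
published operating value c = 0.896 ships as the default constant
`GESTALT_THRESHOLD` and is not recomputed, because recomputation requires
the original 1,499-image control pool.

`compare_cohorts()` runs 100 subsampling iterations (the published count);
the subsample size — not published — defaults to 75% of each cohort without
replacement, minimum 2 images. The decision is "different" iff at least
50% of subsampled comparisons exceed c. PPV uses the printed formula with
prior p = 0.5 (equal prior odds); sensitivity/specificity are estimated
from the control distributions as the probability of a different-/same-
syndrome control distance falling inside/outside the observed subsampled
range. `cohesion()` reports the left-tail percentile (mid-rank for ties,
0–100 scale, two decimals, matching the "1.61st percentile" reporting
style) of the cohort's within-group mean distance against random
equal-size batches from the pool.

Cluster-batch sizes for the control pool are not published; the pool
generator's defaults (tens of syndromes, ~10 images each) were chosen once
as a plausible rare-disease database shape and are configurable.

# Biophysical curve analyses

**Kinetics.** Polymerization (rising) and depolymerization (falling) pyrene
traces are fitted by nonlinear least squares to a single exponential,
`F0 + A(1 − e^(−kt))` or `F0 + A·e^(−kt)`; the apparent half-time is
`t½ = ln 2 / k`, the parametric route implied by "single-exponential fit"
(a threshold-crossing read-off, `half_time_crossing()`, is provided as a
sensitivity check — the two coincide exactly on a clean exponential).
Initial guesses are F0 from the first-quartile signal, A from the signal
range, and k from a log-linear regression of the normalized approach to
plateau; the fit uses the bounded `port` algorithm with k > 0, and rejects
constant-signal traces, non-convergence, and non-positive rate estimates
with named errors. Fits are invariant to affine signal rescaling and time
shifts (absorbed by F0/A). The default fit window is the full trace, as in
the original analysis; an optional window start excludes a nucleation lag.
Each fit reports its residual RMS so multi-phase traces can be recognized
by residuals far above the noise floor. Traces are fitted individually
(whether the published half-times were per-replicate fits or a global fit
is not stated).

**Melt curves.** Thermofluor curves are smoothed with a centered moving
polynomial window (width 5 points, order 2 — no smoothing is named in the
method, and this is the mildest standard choice), differentiated by central
differences on the temperature grid, and Tm is the temperature at the
first-derivative maximum. Ties within numerical noise break to the lower
temperature; a maximum at the grid boundary (e.g. a linear ramp with
constant derivative) is flagged unreliable with a warning rather than
reported as a Tm.

# Synthetic data: the stated world

Generator defaults are the study's stated conditions, fixed once:

- **Transcripts:** 375 codons + stop (1,128 coding nt), several exons,
  either strand; intronic spacers and small exonic UTRs so splice/UTR
  classes are reachable.
- **Population:** observed rows sampled from the enumeration at configured
  per-class counts against AN = 862,260 alleles (~431,130 individuals, the
  aggregate the study compared against), plus indel decoys that the SNV
  enumeration cannot match.
- **Cohort:** 290 subjects = 275 SNV carriers (145 *ACTB* + 130 *ACTG1*) +
  15 whole-gene deletions; the 259 protein-altering carriers split
  73 BWCFF1 / 40 BWCFF2 / 60 hearing loss / 13 DDS1 / 8 functional-LoF /
  65 unNMA. Splits not printed (unNMA by gene 35/30, 16 *ACTB* pLoF SNVs,
  deletions 8/7) follow by subtraction from the printed totals. Flags are
  generated to satisfy the subject's true subtype rule, then corrupted
  present↔absent at a configurable noise rate that never touches genotype
  fields.
- **Embeddings:** 75 images in four groups (38 BWCFF / 19 ACTB-LoF /
  15 unNMA / 3 BWCFF-unNMA), unit vectors from spherical clusters (mean
  direction + isotropic Gaussian angular noise, re-normalized) — a von
  Mises–Fisher-like construction, appropriate because cosine distance sees
  only directions.
- **Traces/melts:** exact model curves plus Gaussian noise, truth (k, Tm)
  recorded.

What the generators deliberately do **not** emulate: real genome background
composition and mutational signatures, real facial-embedding geometry
(true encoder output is not isotropic around a cluster mean), plate-reader
artifacts (drift, evaporation, outlier wells), or inter-rater noise in
clinical flags beyond independent flips. A green parameter-recovery test
therefore establishes that the estimators are correct on data satisfying
their model assumptions — not that the assumptions hold for any particular
laboratory's data.

# Numerical choices and degenerate inputs

- Cosine distances are clamped to [0, 2] against floating-point spill;
  zero-norm vectors are a domain error at container construction.
- The ROC scan warns and returns the midpoint when the two control
  distributions are identical.
- Cohesion with one control batch can only produce percentiles {0, 50,
  100} (mid-rank of an exact tie is 50).
- The derivative-peak finder uses a 1e-9 relative tolerance when locating
  the maximum so that an exactly constant derivative resolves to the grid
  boundary (and is flagged) instead of being decided by rounding noise.
- All resampling routines draw from a private seeded RNG stream that is
  saved and restored around each call, so package functions never perturb
  a user's random sequence, and identical seeds reproduce identical
  reports end to end (the pipeline manifest checksums verify this).

# Known limitations

- The consequence annotator handles SNVs only; indels appear solely as
  population-table decoys and cohort variant classes.
- The published embedding figures (within-group distances, percentiles)
  and biophysical values (half-times, Tm shifts) cannot be reproduced
  numerically without the original image database and protein
  measurements; the test suite substitutes property-based checks at
  generator-controlled truth.
- The splice arm of the diagnostic workflow is undefined in the source
  material; splice-class records without an NMD call are reported
  unclassifiable rather than guessed.
- `make_transcript(n_codons = n)` counts amino-acid codons excluding the
  stop (CDS length `3(n+1)`), the convention consistent with the
  375-codon / 1,128-nt arithmetic.
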