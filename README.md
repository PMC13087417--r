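# nmascope

Computational toolkit for genotype–phenotype dissection of **non-muscle
actinopathies (NMAs)** — the spectrum of disorders caused by constitutional
variants in the cytoplasmic actin genes *ACTB* and *ACTG1*.

## Who this is for

Clinical geneticists and computational biologists who need to

1. **saturate** an actin (or any coding) transcript with every possible
   single-nucleotide variant and compare the enumeration against
   gnomAD-style population extracts,
2. **classify** variant carriers through a deterministic, auditable
   diagnostic workflow into NMA subtypes,
3. **quantify** whether patient cohorts are distinct in facial-embedding
   space (GestaltMatcher-style 512-d vectors), and
4. **fit** pyrene-actin polymerization/depolymerization traces and
   thermal-shift melt curves.

Every input family has a seeded synthetic generator with recorded ground
truth, so all statistics are testable by parameter recovery.

## The methods in brief

- **Saturation simulation.** A 375-residue actin ORF plus stop codon has
  1,128 coding reference positions; each admits 3 alternate alleles, so two
  transcripts give 1,128 × 3 × 2 = 6,768 alternates. Each alternate is
  annotated internally (start_loss, stop_gain, stop_loss, missense,
  synonymous, splice_canonical, intronic, UTR) with the severity hierarchy
  splice > start_loss > stop_gain > stop_loss > missense > synonymous.
  Premature stops receive an NMD call by the 50-nt rule: a stop in the last
  exon or within 50 nt upstream of the last exon–exon junction escapes
  nonsense-mediated decay.
- **Diagnostic workflow.** A fixed-order rule engine: gene + variant-class
  routing (ACTG1 truncating point variants likely benign; ACTB pLoF →
  *ACTB* pLoF disorder; whole-gene deletions split by gene), then the
  functional-LoF, DDS1 (*ACTB* p.Arg183Trp with dystonia/deafness), BWCFF
  (gestalt and/or frontal pachygyria), isolated hearing loss, and
  provisional unNMA arms. Every assignment carries its full rule trace.
- **Embedding statistics.** Cosine distance d(u,v) = 1 − u·v/(‖u‖‖v‖);
  mean pairwise distances within/between cohorts; resampled same-/different-
  syndrome control distributions; ROC threshold at the Youden-J maximum
  (shipped operating value c = 0.896); a 100-iteration subsampling decision
  rule (different if ≥ 50% of subsampled comparisons exceed c);
  PPV = sens·p / (sens·p + (1−spec)(1−p)) with p = 0.5; and within-group
  cohesion as the left-tail percentile of d(C) against random equal-size
  batches.
- **Biophysics.** Single-exponential fits F0 + A(1 − e^(−kt)) (rising) /
  F0 + A e^(−kt) (falling) with t½ = ln 2 / k; melt Tm from the peak of
  the first derivative of the smoothed melting function.

## Worked example

```r
library(nmascope)

model <- make_transcript(n_codons = 375, n_exons = 6, strand = "-", seed = 11)
model
#> <transcript_model> SYNGENE chrS:1000-2827 (-)
#>   exons: 6 | CDS: 1128 nt (376 codons incl. stop)

v <- enumerate_snvs(model, "coding_only")      # 3,384 alternates
table(v$nmd_call[v$consequence == "stop_gain"])
#>    escapes_NMD subject_to_NMD
#>             19            115

pop <- make_population(model, n_per_class = c(missense = 43, synonymous = 80),
                       seed = 12)
summarize_consequences(v, pop$table)
#> <consequence_summary> 3384 enumerated alternates
#>             class n_enumerated n_observed       cum_af
#>  splice_canonical            0          0 0.0000000000
#>        start_loss            9          0 0.0000000000
#>         stop_gain          134          0 0.0000000000
#>         stop_loss            8          0 0.0000000000
#>          missense         2374         43 0.0004940505
#>        synonymous          859         80 0.0010078167
#>          intronic            0          0 0.0000000000
#>               utr            0          0 0.0000000000

res <- classify_cohort(make_cohort(seed = 13)$records)
res
#> <nma_cohort_result> 290 subjects
#>  ACTB_pLoF_disorder              BWCFF1              BWCFF2                DDS1
#>                  32                  73                  40                  13
#>            ACTG1_HL               unNMA del17q25_contiguous
#>                  60                  65                   7

emb <- make_embeddings(seed = 14, within_sd = 0.15)   # 75 images, 4 groups
compare_cohorts(cohort_vectors(emb, "BWCFF"),
                cohort_vectors(emb, "ACTB_LoF"), seed = 15)
#> <cohort_comparison> d = 1.0009 vs c = 0.896 | 100% above -> different

fit_half_time(make_traces(k = 0.1, noise_sd = 10, seed = 16)$traces[[1]])
#> <exponential_fit> polymerization: k = 0.1004 /s, t1/2 = 6.904 s, rms = 9.97

melt_tm(make_melts(Tm = 60, noise_sd = 5, seed = 17)$curves[[1]])
#> <melt_result> Tm = 60.00 degC
```

Reading the numbers: the enumeration partitions all 3,384 alternates into
consequence classes (no splice/intronic/UTR rows under `coding_only`); 43
of the enumerated missense alternates are "observed" in the synthetic
population at a cumulative allele frequency of ~0.05%. The classifier
reproduces the generated cohort composition (the 32 *ACTB* pLoF disorder
subjects pool the point-variant, deletion and functional-LoF routes). The
two synthetic facial cohorts sit ~1.0 apart in cosine distance — above the
c = 0.896 operating threshold in 100/100 subsampled comparisons, hence
"different". The kinetic fit recovers the generating rate (k = 0.1/s,
t½ = ln 2/k ≈ 6.93 s) from a 1%-noise trace, and the melt-curve Tm lands on
the generator's 60 °C midpoint.

## Pipeline & CLI

```sh
Rscript inst/exec/nmascope run --seed 1 --out demo/       # simulate -> analyze -> report
Rscript inst/exec/nmascope saturate --transcript T.fa --exons T.tsv --out out/
Rscript inst/exec/nmascope classify --cohort cohort.tsv --out out/
Rscript inst/exec/nmascope gestalt --embeddings E.csv --cohorts BWCFF,ACTB_LoF --out out/
Rscript inst/exec/nmascope kinetics --traces T.csv --curves M.csv --out out/
```

`run` writes a manifest (`manifest.json`) with per-stage status, wall time
and md5 checksums of every output, plus a Markdown report.

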