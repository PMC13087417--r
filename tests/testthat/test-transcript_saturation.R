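test_that("a one-codon toy CDS yields 3 alternates per coding position", {
  model <- toy_single_exon("ATGTAA")
  v <- enumerate_snvs(model, "coding_only")
  expect_equal(nrow(v), 18L)
  expect_true(all(v$ref != v$alt))
  # deterministic ordering by (genomic_pos, alt)
  expect_equal(order(v$genomic_pos, v$alt), seq_len(nrow(v)))
  # class counts partition the total
  expect_equal(sum(table(v$consequence)), nrow(v))
})

test_that("enumeration counts scale as 3 x CDS length and full_window covers the window", {
  model <- make_transcript(n_codons = 40L, n_exons = 2L, seed = 7L)
  v <- enumerate_snvs(model, "coding_only")
  expect_equal(nrow(v), 3L * nchar(model$cds_sequence))
  w <- enumerate_snvs(model, "full_window")
  expect_equal(nrow(w), 3L * (model$genome_end - model$genome_start + 1L))
  expect_setequal(unique(w$consequence[is.na(w$cds_pos)]),
                  c("splice_canonical", "intronic", "utr"))
  # coding rows of the full window agree with the coding-only enumeration
  wc <- w[!is.na(w$cds_pos), c("genomic_pos", "alt", "consequence")]
  vc <- v[, c("genomic_pos", "alt", "consequence")]
  expect_equal(wc[order(wc$genomic_pos, wc$alt), ],
               vc[order(vc$genomic_pos, vc$alt), ],
               ignore_attr = TRUE)
  no_geno <- model
  no_geno$genome_sequence <- NULL
  expect_error(enumerate_snvs(no_geno, "full_window"), "genome_sequence")
})

test_that("malformed CDS models are rejected naming the violated invariant", {
  expect_error(toy_single_exon("ATGCTTAA"), "divisible by 3")
  expect_error(toy_single_exon("CTGCTTTAA"), "start with ATG")
  expect_error(toy_single_exon("ATGCTTCTT"), "stop codon")
  expect_error(toy_single_exon("ATGTAACTTTAA"), "internal stop")
})

test_that("start, synonymous and stop consequences follow the genetic code", {
  model <- toy_single_exon("ATGCTTTAA", start = 101L)
  # first base of the start codon: ATG -> CTG
  a <- annotate_consequence(model, 101L, "A", "C")
  expect_equal(a$consequence, "start_loss")
  # third-position CTT -> CTG, both Leu
  a <- annotate_consequence(model, 106L, "T", "G")
  expect_equal(a$consequence, "synonymous")
  expect_equal(a$aa_ref, a$aa_alt)
  # stop codon TAA -> CAA loses the stop
  a <- annotate_consequence(model, 107L, "T", "C")
  expect_equal(a$consequence, "stop_loss")
  # stop codon TAA -> TGA keeps it
  a <- annotate_consequence(model, 108L, "A", "G")
  expect_equal(a$consequence, "synonymous")
  # CTT -> CAT is missense with aa fields filled
  a <- annotate_consequence(model, 105L, "T", "A")
  expect_equal(a$consequence, "missense")
  expect_equal(a$aa_pos, 2L)
  expect_error(annotate_consequence(model, 100L, "A", "C"), "outside")
  expect_error(annotate_consequence(model, 101L, "A", "A"), "differ")
})

test_that("the 50-nt rule splits stop gains into NMD subject and escape", {
  model <- toy_nmd_transcript()
  # internal codons are TAC; C->A at a codon third base creates TAA.
  # codon 17 starts at CDS position 49: 250 - 49 = 201 nt upstream of the
  # last junction -> subject to NMD
  a <- annotate_consequence(model, 51L, "C", "A")
  expect_equal(a$consequence, "stop_gain")
  expect_equal(a$nmd_call, "subject_to_NMD")
  # codon 94 starts at CDS position 280, inside the last exon -> escapes.
  # genomic position of CDS 282: exon3 starts at genomic 491 = CDS 251
  g <- 491L + (282L - 251L)
  a <- annotate_consequence(model, g, "C", "A")
  expect_equal(a$consequence, "stop_gain")
  expect_equal(a$nmd_call, "escapes_NMD")
  # codon 81 starts at CDS 241: 250 - 241 = 9 nt upstream -> escapes
  g <- 221L + (243L - 101L)  # exon2 starts at genomic 221 = CDS 101
  a <- annotate_consequence(model, g, "C", "A")
  expect_equal(a$nmd_call, "escapes_NMD")
  # non-stop-gain rows carry not_applicable
  v <- enumerate_snvs(model, "coding_only")
  expect_true(all(v$nmd_call[v$consequence != "stop_gain"] ==
                    "not_applicable"))
  expect_true(all(v$nmd_call[v$consequence == "stop_gain"] %in%
                    c("subject_to_NMD", "escapes_NMD")))
})

test_that("single-exon stop gains always escape NMD", {
  model <- toy_single_exon(paste0("ATG", strrep("TAC", 30), "TAA"))
  v <- enumerate_snvs(model, "coding_only")
  sg <- v[v$consequence == "stop_gain", ]
  expect_gt(nrow(sg), 0L)
  expect_true(all(sg$nmd_call == "escapes_NMD"))
})

test_that("minus-strand models complement alleles onto the coding strand", {
  model <- toy_single_exon("ATGCTTTAA", start = 201L, strand = "-")
  # CDS base 1 (A of ATG) sits at genomic_end; forward ref is T
  a <- annotate_consequence(model, model$genome_end, "T", "G")
  expect_equal(a$consequence, "start_loss")  # A -> C on the coding strand
  v <- enumerate_snvs(model, "coding_only")
  expect_equal(nrow(v), 27L)
  # same CDS on the plus strand gives the same consequence multiset
  vp <- enumerate_snvs(toy_single_exon("ATGCTTTAA"), "coding_only")
  expect_equal(sort(v$consequence), sort(vp$consequence))
})

test_that("strand round-trip: identical consequence multisets on +/- models", {
  for (seed in c(3L, 11L)) {
    mp <- make_transcript(n_codons = 30L, n_exons = 3L, strand = "+",
                          seed = seed)
    mm <- make_transcript(n_codons = 30L, n_exons = 3L, strand = "-",
                          seed = seed)
    expect_identical(mp$cds_sequence, mm$cds_sequence)
    vp <- enumerate_snvs(mp, "coding_only")
    vm <- enumerate_snvs(mm, "coding_only")
    expect_equal(sort(vp$consequence), sort(vm$consequence))
    expect_equal(sort(vp$nmd_call), sort(vm$nmd_call))
  }
})

test_that("consequences match the full-ORF retranslation oracle on small transcripts", {
  cases <- expand.grid(n_codons = c(2L, 10L, 19L), n_exons = c(1L, 3L),
                       strand = c("+", "-"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    model <- make_transcript(n_codons = cases$n_codons[i],
                             n_exons = cases$n_exons[i],
                             strand = cases$strand[i], seed = 100L + i)
    expect_lte(nchar(model$cds_sequence), 63L)
    v <- enumerate_snvs(model, "coding_only")
    alt_coding <- if (model$strand == "+") v$alt
                  else unname(c(A = "T", C = "G", G = "C", T = "A")[v$alt])
    expected <- mapply(oracle_consequence,
                       cds_pos = v$cds_pos, alt_coding = alt_coding,
                       MoreArgs = list(cds_sequence = model$cds_sequence))
    expect_equal(v$consequence, unname(expected),
                 label = sprintf("case %d (%s, %d exons)", i,
                                 cases$strand[i], cases$n_exons[i]))
  }
})

test_that("synonymous/missense/nonsense tallies agree with direct codon enumeration", {
  model <- make_transcript(n_codons = 25L, n_exons = 1L, seed = 42L)
  v <- enumerate_snvs(model, "coding_only")
  codons <- substring(model$cds_sequence,
                      seq(1, nchar(model$cds_sequence), 3),
                      seq(3, nchar(model$cds_sequence), 3))
  gc_tab <- Biostrings::GENETIC_CODE
  counts <- c(missense = 0L, synonymous = 0L, stop_gain = 0L)
  n <- length(codons)
  for (ci in 2:(n - 1)) {            # internal codons only
    for (pos in 1:3) for (b in setdiff(c("A", "C", "G", "T"),
                                       substr(codons[ci], pos, pos))) {
      mut <- codons[ci]; substr(mut, pos, pos) <- b
      cls <- if (gc_tab[[mut]] == "*") "stop_gain"
             else if (gc_tab[[mut]] == gc_tab[[codons[ci]]]) "synonymous"
             else "missense"
      counts[cls] <- counts[cls] + 1L
    }
  }
  internal <- v[v$aa_pos > 1 & v$aa_pos < n, ]
  expect_equal(as.integer(table(factor(internal$consequence,
                                       names(counts)))),
               unname(as.integer(counts)))
})

test_that("summarize joins population rows onto the enumeration by key", {
  model <- make_transcript(n_codons = 30L, n_exons = 1L, seed = 5L)
  v <- enumerate_snvs(model, "coding_only")

  # empty population: all observed counts and frequencies are zero
  s0 <- summarize_consequences(v, NULL)
  expect_equal(s0$total_alternates, nrow(v))
  expect_true(all(s0$by_class$n_observed == 0L))
  expect_true(all(s0$by_class$cum_af == 0))
  expect_equal(sum(s0$by_class$n_enumerated), nrow(v))

  # hand-built table: 3 enumerated missense hits + 1 indel decoy
  mis <- v[v$consequence == "missense", ][c(1, 5, 9), ]
  pop <- data.frame(
    chrom = c(mis$chrom, model$chrom),
    pos = c(mis$genomic_pos, model$genome_start),
    ref = c(mis$ref, "AT"),
    alt = c(mis$alt, "A"),
    AF = c(1e-4, 2e-4, 3e-4, 5e-4))
  s <- summarize_consequences(v, pop)
  expect_equal(s$by_class$n_observed[s$by_class$class == "missense"], 3L)
  expect_equal(s$by_class$cum_af[s$by_class$class == "missense"], 6e-4)
  expect_equal(s$n_unmatched_observed, 1L)  # the indel

  # AC/AN rows are converted to frequencies
  pop2 <- data.frame(chrom = mis$chrom, pos = mis$genomic_pos, ref = mis$ref,
                     alt = mis$alt, AC = c(2L, 4L, 6L), AN = 1000L)
  s2 <- summarize_consequences(v, pop2)
  expect_equal(s2$by_class$cum_af[s2$by_class$class == "missense"], 0.012)
})

test_that("summarize deduplicates tagged sub-tables and reports per tag", {
  model <- make_transcript(n_codons = 20L, n_exons = 1L, seed = 9L)
  v <- enumerate_snvs(model, "coding_only")
  hit <- v[v$consequence == "synonymous", ][1:2, ]
  sub <- data.frame(chrom = hit$chrom, pos = hit$genomic_pos, ref = hit$ref,
                    alt = hit$alt, AF = 1e-4)
  pop <- rbind(cbind(sub, tag = "controls"), cbind(sub, tag = "non_neuro"))
  s <- summarize_consequences(v, pop)
  syn <- s$by_class$class == "synonymous"
  expect_equal(s$by_class$n_observed[syn], 2L)     # counted once in the union
  expect_equal(s$by_class$cum_af[syn], 2e-4)
  expect_named(s$by_tag, c("controls", "non_neuro"))
  expect_equal(s$by_tag$controls$n_observed[syn], 2L)
})

test_that("population rows with inconsistent ref are warned about and skipped", {
  model <- make_transcript(n_codons = 20L, n_exons = 1L, seed = 9L)
  v <- enumerate_snvs(model, "coding_only")
  row <- v[1, ]
  bad_ref <- setdiff(c("A", "C", "G", "T"), c(row$ref, row$alt))[1]
  pop <- data.frame(chrom = row$chrom, pos = row$genomic_pos, ref = bad_ref,
                    alt = row$alt, AF = 1e-4)
  expect_warning(s <- summarize_consequences(v, pop), "contradicts")
  expect_equal(s$n_skipped_inconsistent_ref, 1L)
  expect_true(all(s$by_class$n_observed == 0L))
})

test_that("population windows are filtered with configurable exon padding", {
  model <- toy_nmd_transcript()  # exons 1-100, 221-370, 341+... on chrT
  pop <- data.frame(chrom = c("chrT", "chrT", "chrT", "chrX"),
                    pos = c(50L, 180L, 150L, 50L),
                    ref = "A", alt = "C", AF = 1e-4)
  f75 <- filter_population_window(pop, model, pad = 75L)
  expect_equal(f75$pos, c(50L, 180L, 150L))  # 180 and 150 within 75 of exons
  f0 <- filter_population_window(pop, model, pad = 0L)
  expect_equal(f0$pos, 50L)
  expect_equal(nrow(filter_population_window(pop[4, ], model)), 0L)
})

test_that("transcript FASTA+interval and population TSV/VCF round-trips work", {
  model <- make_transcript(n_codons = 15L, n_exons = 2L, strand = "-",
                           seed = 3L)
  fa <- tempfile(fileext = ".fa"); bed <- tempfile(fileext = ".tsv")
  write_transcript(model, fa, bed)
  back <- read_transcript(fa, bed)
  expect_equal(back$cds_sequence, model$cds_sequence)
  expect_equal(back$exons, model$exons, ignore_attr = TRUE)
  expect_equal(back$strand, model$strand)
  expect_equal(enumerate_snvs(back, "coding_only"),
               enumerate_snvs(model, "coding_only"))

  pop <- data.frame(chrom = "chr7", pos = c(100L, 200L), ref = c("A", "G"),
                    alt = c("T", "C"), AC = c(3L, 5L), AN = 1000L)
  tsv <- tempfile(fileext = ".tsv")
  write.table(pop, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_population(tsv, tag = "controls")$pos, pop$pos)

  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Allele number\">",
    "##contig=<ID=chr7>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr7\t100\t.\tA\tT\t.\t.\tAC=3;AN=1000",
    "chr7\t200\t.\tG\tC\t.\t.\tAC=5;AN=1000"), vcf)
  got <- read_population(vcf)
  expect_equal(got$pos, c(100L, 200L))
  expect_equal(got$AC, c(3L, 5L))
  expect_equal(got$ref, c("A", "G"))
})
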