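# Independent oracles and hand-built fixtures shared across test files.

# Brute-force consequence oracle: rebuild the full mutant ORF, translate the
# whole thing, and classify by comparing the complete protein products.
# Works in coding-strand space (cds_pos, coding-strand alt).
oracle_consequence <- function(cds_sequence, cds_pos, alt_coding) {
  mut <- cds_sequence
  substr(mut, cds_pos, cds_pos) <- alt_coding
  split_codons <- function(s)
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  aa <- function(s) unname(Biostrings::GENETIC_CODE[split_codons(s)])
  if (substr(mut, 1, 3) != "ATG") return("start_loss")
  ref_aa <- aa(cds_sequence)
  mut_aa <- aa(mut)
  n <- length(ref_aa)
  if (identical(mut_aa, ref_aa)) return("synonymous")
  if (mut_aa[n] != "*" && all(mut_aa[-n] == ref_aa[-n])) return("stop_loss")
  first_mut_stop <- which(mut_aa == "*")[1]
  if (!is.na(first_mut_stop) && first_mut_stop < n) return("stop_gain")
  if (mut_aa[n] == "*" && ref_aa[n] == "*") {
    if (any(mut_aa[-n] != ref_aa[-n])) return("missense")
  }
  "missense"
}

# Brute-force mean pairwise cosine distance: explicit double loop.
brute_mean_pairwise <- function(A, B = NULL) {
  cosd <- function(u, v) 1 - sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  if (is.null(B)) {
    n <- nrow(A)
    acc <- 0; m <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      acc <- acc + cosd(A[i, ], A[j, ]); m <- m + 1
    }
    acc / m
  } else {
    acc <- 0
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
      acc <- acc + cosd(A[i, ], B[j, ])
    acc / (nrow(A) * nrow(B))
  }
}

# Explicit per-pair cross cosine distance matrix (no vectorized algebra).
cross_cosine_oracle <- function(A, B) {
  out <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    out[i, j] <- 1 - sum(A[i, ] * B[j, ]) /
      sqrt(sum(A[i, ]^2) * sum(B[j, ]^2))
  out
}

# Single-exon plus-strand toy transcript with an explicit CDS, placed at an
# arbitrary genomic offset.
toy_single_exon <- function(cds = "ATGCTTTAA", start = 101L,
                            strand = "+", chrom = "chrT") {
  L <- nchar(cds)
  genome <- if (strand == "+") cds
            else as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(cds)))
  transcript_model(
    gene_symbol = "TOY", chrom = chrom, strand = strand,
    exons = data.frame(start = start, end = start + L - 1L),
    cds_intervals = data.frame(start = start, end = start + L - 1L),
    cds_sequence = cds, genome_sequence = genome,
    genome_start = start, genome_end = start + L - 1L)
}

# Three-exon plus-strand transcript whose internal codons are all TAC
# (Tyr), so a C->A at any codon third position creates a premature stop.
# Exon CDS chunks are 100 / 150 / 53 nt (301:303-nt CDS from 100 codons +
# stop), introns 120 nt, no UTRs. mRNA coordinates equal CDS coordinates,
# so the last exon-exon junction sits at mRNA position 250.
toy_nmd_transcript <- function() {
  n_codons <- 100L
  cds <- paste0("ATG", strrep("TAC", n_codons - 1L), "TAA")
  L <- nchar(cds)  # 303
  chunks <- c(100L, 150L, L - 250L)
  intron <- strrep("G", 120L)
  pieces <- substring(cds, cumsum(c(0L, chunks[-3])) + 1L, cumsum(chunks))
  genome <- paste0(pieces[1], intron, pieces[2], intron, pieces[3])
  s1 <- 1L
  e1 <- chunks[1]; s2 <- e1 + 121L; e2 <- s2 + chunks[2] - 1L
  s3 <- e2 + 121L; e3 <- s3 + chunks[3] - 1L
  transcript_model(
    gene_symbol = "NMDTOY", chrom = "chrT", strand = "+",
    exons = data.frame(start = c(s1, s2, s3), end = c(e1, e2, e3)),
    cds_intervals = data.frame(start = c(s1, s2, s3), end = c(e1, e2, e3)),
    cds_sequence = cds, genome_sequence = genome,
    genome_start = 1L, genome_end = e3)
}

# One fully-specified clinical record with every flag defaulting to unknown.
toy_record <- function(subject_id = "P1", gene = "ACTB",
                       variant_class = "missense",
                       protein_change = "Ala12Gly", ...) {
  individual_record(subject_id, gene, variant_class, protein_change, ...)
}
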