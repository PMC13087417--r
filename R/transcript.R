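#' Coding transcript model
#'
#' Container for a coding transcript: genomic window, strand, exon structure,
#' the subset of exon space covering the open reading frame (including the
#' stop codon), and the coding-strand CDS sequence. This is the substrate of
#' the saturation SNV enumeration.
#'
#' Coordinates are 1-based inclusive throughout (VCF/gnomAD convention).
#' `exons` and `cds_intervals` are data frames with `start`/`end` genomic
#' columns, ordered 5'->3' on the coding strand: ascending genomic order on
#' the plus strand, descending on the minus strand.
#'
#' @param gene_symbol Gene name, e.g. `"ACTB"`.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (1-based inclusive
#'   genomic), ordered 5'->3' on the coding strand.
#' @param cds_intervals data.frame like `exons`; the ORF footprint including
#'   the stop codon. Must lie inside exon space.
#' @param cds_sequence Character scalar, coding-strand nucleotide sequence of
#'   the CDS: length divisible by 3, starts `ATG`, ends in a stop codon, no
#'   internal stop.
#' @param genome_sequence Optional forward-strand sequence of the whole
#'   genomic window `genome_start..genome_end`; required only for
#'   `region = "full_window"` enumeration.
#' @param genome_start,genome_end Window bounds; default to the exon extremes.
#'
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene_symbol, chrom, strand, exons, cds_intervals,
                             cds_sequence, genome_sequence = NULL,
                             genome_start = NULL, genome_end = NULL) {
  exons <- as.data.frame(exons)[, c("start", "end")]
  cds_intervals <- as.data.frame(cds_intervals)[, c("start", "end")]
  if (is.null(genome_start)) genome_start <- min(exons$start)
  if (is.null(genome_end)) genome_end <- max(exons$end)
  obj <- structure(
    list(gene_symbol = as.character(gene_symbol),
         chrom = as.character(chrom),
         genome_start = as.integer(genome_start),
         genome_end = as.integer(genome_end),
         strand = strand,
         exons = exons,
         cds_intervals = cds_intervals,
         cds_sequence = toupper(as.character(cds_sequence)),
         genome_sequence = if (is.null(genome_sequence)) NULL
                           else toupper(as.character(genome_sequence))),
    class = "transcript_model")
  validate_transcript_model(obj)
  obj
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Validate a transcript model
#'
#' Checks every structural invariant of [transcript_model()] and stops with a
#' message naming the first violated one.
#'
#' @param model A `transcript_model`.
#' @return The model, invisibly.
#' @export
validate_transcript_model <- function(model) {
  stopifnot(inherits(model, "transcript_model"))
  if (!model$strand %in% c("+", "-"))
    stop("invalid transcript: strand must be '+' or '-'")
  ex <- model$exons
  cds <- model$cds_intervals
  if (nrow(ex) < 1L || any(ex$end < ex$start))
    stop("invalid transcript: malformed exon intervals")
  if (any(cds$end < cds$start))
    stop("invalid transcript: malformed CDS intervals")
  # non-overlapping and ordered 5'->3' on the coding strand
  ord <- if (model$strand == "+") order(ex$start) else order(-ex$start)
  if (!identical(ord, seq_len(nrow(ex))))
    stop("invalid transcript: exons not ordered 5'->3' on the coding strand")
  exs <- ex[order(ex$start), , drop = FALSE]
  if (nrow(exs) > 1L && any(exs$start[-1L] <= exs$end[-nrow(exs)]))
    stop("invalid transcript: overlapping exons")
  # CDS inside exon space
  exon_pos <- unlist(Map(seq.int, exs$start, exs$end))
  cds_pos <- unlist(Map(seq.int, pmin(cds$start, cds$end),
                        pmax(cds$start, cds$end)))
  if (!all(cds_pos %in% exon_pos))
    stop("invalid transcript: CDS intervals extend outside exon space")
  seq <- model$cds_sequence
  L <- nchar(seq)
  if (L != length(cds_pos))
    stop("invalid transcript: cds_sequence length (", L,
         ") != total CDS interval length (", length(cds_pos), ")")
  if (L %% 3L != 0L)
    stop("invalid transcript: CDS length not divisible by 3")
  if (L < 6L)
    stop("invalid transcript: CDS shorter than two codons")
  if (substr(seq, 1L, 3L) != "ATG")
    stop("invalid transcript: CDS does not start with ATG")
  codons <- codon_split(seq)
  if (!codons[length(codons)] %in% STOP_CODONS)
    stop("invalid transcript: CDS does not end in a stop codon")
  if (any(codons[-length(codons)] %in% STOP_CODONS))
    stop("invalid transcript: internal stop codon in CDS")
  if (grepl("[^ACGT]", seq))
    stop("invalid transcript: cds_sequence contains non-ACGT characters")
  if (!is.null(model$genome_sequence)) {
    win <- model$genome_end - model$genome_start + 1L
    if (nchar(model$genome_sequence) != win)
      stop("invalid transcript: genome_sequence length != genomic window size")
  }
  invisible(model)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s %s:%d-%d (%s)\n", x$gene_symbol, x$chrom,
              x$genome_start, x$genome_end, x$strand))
  cat(sprintf("  exons: %d | CDS: %d nt (%d codons incl. stop)\n",
              nrow(x$exons), nchar(x$cds_sequence), nchar(x$cds_sequence) / 3))
  invisible(x)
}

codon_split <- function(seq) {
  substring(seq, seq(1L, nchar(seq), 3L), seq(3L, nchar(seq), 3L))
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_base <- function(x) unname(COMPLEMENT[x])

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

translate_cds <- function(seq) {
  codons <- codon_split(seq)
  aa <- Biostrings::GENETIC_CODE[codons]
  unname(aa)
}

# Genomic coordinates of each CDS base, ordered by cds position 1..L.
cds_genomic_positions <- function(model) {
  iv <- model$cds_intervals
  if (model$strand == "+") {
    unlist(Map(seq.int, iv$start, iv$end))
  } else {
    unlist(Map(seq.int, iv$end, iv$start))
  }
}

# Genomic coordinates of each exonic base in transcript (mRNA) order.
exon_genomic_positions <- function(model) {
  iv <- model$exons
  if (model$strand == "+") {
    unlist(Map(seq.int, iv$start, iv$end))
  } else {
    unlist(Map(seq.int, iv$end, iv$start))
  }
}

#' Read a transcript model from FASTA + interval table
#'
#' The FASTA file carries the coding-strand CDS sequence (first record; an
#' optional second record named `genome` carries the forward-strand window
#' sequence). The interval file is a tab-separated table with columns
#' `feature` (`exon` or `CDS`), `start`, `end` (1-based inclusive genomic),
#' plus header comment lines `#gene=`, `#chrom=`, `#strand=` and optionally
#' `#genome_start=`, `#genome_end=`. Rows must appear in 5'->3' coding-strand
#' order.
#'
#' @param fasta_file Path to the FASTA file.
#' @param interval_file Path to the interval table.
#' @return A [transcript_model()].
#' @export
read_transcript <- function(fasta_file, interval_file) {
  seqs <- Biostrings::readDNAStringSet(fasta_file)
  cds_sequence <- as.character(seqs[[1L]])
  genome_sequence <- if ("genome" %in% names(seqs))
    as.character(seqs[["genome"]]) else NULL
  lines <- readLines(interval_file)
  hdr <- grep("^#", lines, value = TRUE)
  get_hdr <- function(key, required = TRUE) {
    hit <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (length(hit) == 0L) {
      if (required) stop("interval file missing header #", key, "=")
      return(NULL)
    }
    sub(paste0("^#", key, "="), "", hit[1L])
  }
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)],
                           stringsAsFactors = FALSE)
  stopifnot(all(c("feature", "start", "end") %in% names(tab)))
  gs <- get_hdr("genome_start", required = FALSE)
  ge <- get_hdr("genome_end", required = FALSE)
  transcript_model(
    gene_symbol = get_hdr("gene"),
    chrom = get_hdr("chrom"),
    strand = get_hdr("strand"),
    exons = tab[tab$feature == "exon", c("start", "end")],
    cds_intervals = tab[tab$feature == "CDS", c("start", "end")],
    cds_sequence = cds_sequence,
    genome_sequence = genome_sequence,
    genome_start = if (is.null(gs)) NULL else as.integer(gs),
    genome_end = if (is.null(ge)) NULL else as.integer(ge))
}

#' Write a transcript model to FASTA + interval table
#'
#' Inverse of [read_transcript()].
#'
#' @param model A `transcript_model`.
#' @param fasta_file,interval_file Output paths.
#' @return Invisibly, the two paths.
#' @export
write_transcript <- function(model, fasta_file, interval_file) {
  seqs <- Biostrings::DNAStringSet(c(cds = model$cds_sequence))
  names(seqs) <- paste0(model$gene_symbol, "_CDS")
  if (!is.null(model$genome_sequence)) {
    seqs <- c(seqs, Biostrings::DNAStringSet(c(genome = model$genome_sequence)))
  }
  Biostrings::writeXStringSet(seqs, fasta_file)
  hdr <- c(paste0("#gene=", model$gene_symbol),
           paste0("#chrom=", model$chrom),
           paste0("#strand=", model$strand),
           paste0("#genome_start=", model$genome_start),
           paste0("#genome_end=", model$genome_end),
           "#coordinates=1-based inclusive")
  tab <- rbind(
    data.frame(feature = "exon", start = model$exons$start,
               end = model$exons$end),
    data.frame(feature = "CDS", start = model$cds_intervals$start,
               end = model$cds_intervals$end))
  con <- file(interval_file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta_file, interval_file))
}
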