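#' Enumerate all single-nucleotide alternates over a transcript
#'
#' Simulates every possible single-nucleotide alteration over either the
#' coding positions of a transcript (the counting basis used for saturation
#' tallies: a 375-codon ORF plus stop gives 1,128 reference positions and
#' 3,384 alternates) or over its whole genomic window. Each reference
#' position yields exactly 3 alternate alleles, reported on the genome
#' forward strand and annotated via [annotate_consequence()].
#'
#' @param model A [transcript_model()].
#' @param region `"coding_only"` (default) enumerates CDS positions only;
#'   `"full_window"` enumerates every position in
#'   `genome_start..genome_end` and requires `model$genome_sequence`.
#' @return A data.frame of simulated variants, ordered by
#'   `(genomic_pos, alt)`, with columns `chrom`, `genomic_pos`, `ref`,
#'   `alt`, `cds_pos`, `consequence`, `aa_ref`, `aa_alt`, `aa_pos`,
#'   `nmd_call`.
#' @export
enumerate_snvs <- function(model, region = c("coding_only", "full_window")) {
  region <- match.arg(region)
  validate_transcript_model(model)
  if (region == "coding_only") {
    gpos <- cds_genomic_positions(model)
    cds_base <- strsplit(model$cds_sequence, "", fixed = TRUE)[[1L]]
    ref <- if (model$strand == "+") cds_base else complement_base(cds_base)
    o <- order(gpos)
    gpos <- gpos[o]
    ref <- ref[o]
  } else {
    if (is.null(model$genome_sequence))
      stop("full_window enumeration requires model$genome_sequence")
    gpos <- seq.int(model$genome_start, model$genome_end)
    ref <- strsplit(model$genome_sequence, "", fixed = TRUE)[[1L]]
  }
  bases <- c("A", "C", "G", "T")
  # 3 alternates per reference position, ordered by (genomic_pos, alt)
  alt <- unlist(lapply(ref, function(b) bases[bases != b]), use.names = FALSE)
  pos3 <- rep(gpos, each = 3L)
  ref3 <- rep(ref, each = 3L)
  ann <- annotate_consequence(model, pos3, ref3, alt)
  ann
}

CONSEQUENCE_CLASSES <- c("splice_canonical", "start_loss", "stop_gain",
                         "stop_loss", "missense", "synonymous",
                         "intronic", "utr")

#' Annotate the functional consequence of single-nucleotide alterations
#'
#' Internal re-implementation of transcript consequence annotation for SNVs.
#' Each alternate allele maps to exactly one class of
#' `r paste(CONSEQUENCE_CLASSES, collapse = ", ")`, resolved by the severity
#' hierarchy splice_canonical > start_loss > stop_gain > stop_loss >
#' missense > synonymous (canonical splice sites are the 2 intronic bases
#' flanking each exon junction, so the splice class never competes with a
#' coding one). Alleles are given on the genome forward strand; minus-strand
#' models are handled by complementing onto the coding strand before codon
#' lookup. Stop-gain alleles additionally receive a nonsense-mediated-decay
#' call by the 50-nt rule: a premature stop escapes NMD if it lies in the
#' last exon or within 50 nt upstream of the last exon-exon junction.
#'
#' @param model A [transcript_model()].
#' @param genomic_pos,ref,alt Equal-length vectors of 1-based forward-strand
#'   positions and single-nucleotide alleles.
#' @return A data.frame with one row per input allele (see
#'   [enumerate_snvs()]).
#' @export
annotate_consequence <- function(model, genomic_pos, ref, alt) {
  n <- length(genomic_pos)
  stopifnot(length(ref) == n, length(alt) == n)
  genomic_pos <- as.integer(genomic_pos)
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(ref == alt)) stop("ref and alt must differ")
  if (any(genomic_pos < model$genome_start | genomic_pos > model$genome_end))
    stop("position outside the transcript's genomic window [",
         model$genome_start, ", ", model$genome_end, "]")

  gpos_cds <- cds_genomic_positions(model)
  cds_idx <- match(genomic_pos, gpos_cds)      # cds_pos or NA
  # verify forward-strand ref where the model knows the base
  cds_base <- strsplit(model$cds_sequence, "", fixed = TRUE)[[1L]]
  known <- !is.na(cds_idx)
  expected <- cds_base[cds_idx[known]]
  if (model$strand == "-") expected <- complement_base(expected)
  if (any(expected != ref[known]))
    stop("ref allele does not match the model's sequence at position(s) ",
         paste(utils::head(genomic_pos[known][expected != ref[known]], 3L),
               collapse = ", "))

  exs <- model$exons[order(model$exons$start), , drop = FALSE]
  exon_pos <- unlist(Map(seq.int, exs$start, exs$end))
  splice_pos <- integer(0)
  if (nrow(exs) > 1L) {
    for (j in seq_len(nrow(exs) - 1L)) {
      intron <- seq.int(exs$end[j] + 1L, exs$start[j + 1L] - 1L)
      keep <- unique(c(utils::head(intron, 2L), utils::tail(intron, 2L)))
      splice_pos <- c(splice_pos, keep)
    }
  }

  consequence <- rep(NA_character_, n)
  aa_ref <- aa_alt <- rep(NA_character_, n)
  aa_pos <- rep(NA_integer_, n)
  nmd_call <- rep("not_applicable", n)

  in_cds <- known
  in_splice <- genomic_pos %in% splice_pos
  in_exon <- genomic_pos %in% exon_pos
  consequence[in_splice] <- "splice_canonical"
  consequence[!in_splice & !in_cds & in_exon] <- "utr"
  consequence[!in_splice & !in_cds & !in_exon] <- "intronic"

  cc <- which(in_cds)
  if (length(cc)) {
    p <- cds_idx[cc]
    alt_cod_strand <- if (model$strand == "+") alt[cc]
                      else complement_base(alt[cc])
    codon_idx <- (p - 1L) %/% 3L + 1L
    offset <- (p - 1L) %% 3L + 1L
    codons <- codon_split(model$cds_sequence)
    n_codon <- length(codons)
    ref_codon <- codons[codon_idx]
    mut_codon <- ref_codon
    substr(mut_codon, offset, offset) <- alt_cod_strand
    aa_r <- unname(Biostrings::GENETIC_CODE[ref_codon])
    aa_a <- unname(Biostrings::GENETIC_CODE[mut_codon])
    cls <- ifelse(codon_idx == 1L, "start_loss",
           ifelse(codon_idx == n_codon,
                  ifelse(aa_a == "*", "synonymous", "stop_loss"),
           ifelse(aa_a == "*", "stop_gain",
           ifelse(aa_a == aa_r, "synonymous", "missense"))))
    consequence[cc] <- cls
    aa_ref[cc] <- aa_r
    aa_alt[cc] <- aa_a
    aa_pos[cc] <- codon_idx
    sg <- cc[cls == "stop_gain"]
    if (length(sg)) {
      nmd_call[sg] <- nmd_escape_call(model, cds_idx[sg])
    }
  }

  data.frame(chrom = model$chrom, genomic_pos = genomic_pos, ref = ref,
             alt = alt, cds_pos = cds_idx, consequence = consequence,
             aa_ref = aa_ref, aa_alt = aa_alt, aa_pos = aa_pos,
             nmd_call = nmd_call, stringsAsFactors = FALSE)
}

# 50-nt rule on mRNA coordinates: a premature termination codon escapes NMD
# if its first base lies in the last exon or <= 50 nt upstream of the last
# exon-exon junction. `cds_pos` addresses the mutated base; the PTC starts at
# the first base of its codon.
nmd_escape_call <- function(model, cds_pos) {
  exon_g <- exon_genomic_positions(model)
  widths <- model$exons$end - model$exons$start + 1L
  n_ex <- length(widths)
  if (n_ex == 1L) return(rep("escapes_NMD", length(cds_pos)))
  last_junction <- cumsum(widths)[n_ex - 1L]  # mRNA coord of junction 5' base
  gpos_cds <- cds_genomic_positions(model)
  t0 <- match(gpos_cds[1L], exon_g)           # mRNA coord of CDS base 1
  ptc_cds <- 3L * ((cds_pos - 1L) %/% 3L) + 1L
  ptc_t <- t0 + ptc_cds - 1L
  ifelse(last_junction - ptc_t <= 50L, "escapes_NMD", "subject_to_NMD")
}

#' Restrict a population variant table to a transcript window
#'
#' Keeps rows on the model's chromosome whose position falls within any exon
#' padded by `pad` nucleotides on both sides (gnomAD-style exon padding,
#' default 75 nt).
#'
#' @param population Population variant table (see
#'   [summarize_consequences()]).
#' @param model A [transcript_model()].
#' @param pad Padding in nucleotides around each exon.
#' @return The filtered table.
#' @export
filter_population_window <- function(population, model, pad = 75L) {
  ex <- model$exons
  keep <- population$chrom == model$chrom &
    Reduce(`|`, Map(function(s, e) population$pos >= s - pad &
                      population$pos <= e + pad,
                    ex$start, ex$end))
  population[keep, , drop = FALSE]
}

#' Summarize a saturation enumeration against observed population variants
#'
#' Joins the enumerated alternates against a population variant table keyed
#' by `(chrom, pos, ref, alt)` and tallies, per consequence class, the
#' number of enumerated alternates, the number of distinct observed
#' population variants, and the cumulative allele frequency. Duplicate
#' population rows across tagged sub-tables are deduplicated by key for the
#' union counts and additionally reported per tag. Observed variants absent
#' from the enumeration (e.g. indels or out-of-window rows) are counted
#' separately; rows whose single-nucleotide ref contradicts the enumerated
#' reference at that position are skipped with a warning and counted.
#'
#' @param variants Enumeration from [enumerate_snvs()].
#' @param population data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   and either `AF` or `AC` + `AN`; optional `tag` column carries sub-table
#'   provenance. May be `NULL`/empty.
#' @return A list of class `consequence_summary`: `total_alternates`,
#'   `by_class` (data.frame `class`, `n_enumerated`, `n_observed`,
#'   `cum_af`), `n_unmatched_observed`, `n_skipped_inconsistent_ref`,
#'   `by_tag` (per-tag `by_class` tables).
#' @export
summarize_consequences <- function(variants, population = NULL) {
  classes <- CONSEQUENCE_CLASSES
  enum_key <- paste(variants$chrom, variants$genomic_pos, variants$ref,
                    variants$alt, sep = ":")
  n_enum <- table(factor(variants$consequence, levels = classes))

  empty <- data.frame(class = classes,
                      n_enumerated = as.integer(n_enum),
                      n_observed = 0L, cum_af = 0,
                      stringsAsFactors = FALSE)
  out <- list(total_alternates = nrow(variants), by_class = empty,
              n_unmatched_observed = 0L, n_skipped_inconsistent_ref = 0L,
              by_tag = list())
  class(out) <- "consequence_summary"
  if (is.null(population) || nrow(population) == 0L) return(out)

  pop <- as.data.frame(population)
  if (!"AF" %in% names(pop)) {
    if (!all(c("AC", "AN") %in% names(pop)))
      stop("population table needs an AF column or AC and AN columns")
    pop$AF <- ifelse(pop$AN > 0, pop$AC / pop$AN, 0)
  }
  if (!"tag" %in% names(pop)) pop$tag <- "all"

  # drop SNV rows contradicting the enumerated reference base
  pos_key <- paste(pop$chrom, pop$pos, sep = ":")
  enum_pos_key <- paste(variants$chrom, variants$genomic_pos, sep = ":")
  ref_at <- variants$ref[match(pos_key, enum_pos_key)]
  is_snv <- nchar(pop$ref) == 1L & nchar(pop$alt) == 1L
  bad <- is_snv & !is.na(ref_at) & pop$ref != ref_at
  if (any(bad)) {
    for (i in which(bad))
      warning(sprintf("population row %s:%d ref %s contradicts enumerated ref %s; skipped",
                      pop$chrom[i], pop$pos[i], pop$ref[i], ref_at[i]),
              call. = FALSE)
    out$n_skipped_inconsistent_ref <- sum(bad)
    pop <- pop[!bad, , drop = FALSE]
  }

  tally <- function(sub) {
    key <- paste(sub$chrom, sub$pos, sub$ref, sub$alt, sep = ":")
    sub <- sub[!duplicated(key), , drop = FALSE]
    key <- key[!duplicated(key)]
    hit <- match(key, enum_key)
    matched <- !is.na(hit)
    cls <- factor(variants$consequence[hit[matched]], levels = classes)
    data.frame(class = classes,
               n_enumerated = as.integer(n_enum),
               n_observed = as.integer(table(cls)),
               cum_af = as.numeric(tapply(sub$AF[matched], cls, sum,
                                          default = 0)),
               stringsAsFactors = FALSE)
  }
  out$by_class <- tally(pop)
  key_all <- paste(pop$chrom, pop$pos, pop$ref, pop$alt, sep = ":")
  dedup <- pop[!duplicated(key_all), , drop = FALSE]
  out$n_unmatched_observed <-
    sum(is.na(match(paste(dedup$chrom, dedup$pos, dedup$ref, dedup$alt,
                          sep = ":"), enum_key)))
  out$by_tag <- lapply(split(pop, pop$tag), tally)
  out
}

#' @export
print.consequence_summary <- function(x, ...) {
  cat("<consequence_summary>", x$total_alternates, "enumerated alternates\n")
  print(x$by_class, row.names = FALSE)
  cat("unmatched observed:", x$n_unmatched_observed,
      "| skipped inconsistent ref:", x$n_skipped_inconsistent_ref, "\n")
  invisible(x)
}

#' Read a population variant table (TSV or VCF)
#'
#' TSV input needs columns `chrom`, `pos`, `ref`, `alt` and `AF` or
#' `AC`/`AN` (optional `tag`). VCF input is parsed with the
#' \pkg{VariantAnnotation} package; `AC`/`AN` are taken from the INFO field
#' when present.
#'
#' @param path File path; format chosen by extension (`.vcf` vs anything
#'   else).
#' @param tag Optional provenance tag recorded in a `tag` column.
#' @return A data.frame population table.
#' @export
read_population <- function(path, tag = NULL) {
  if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path)) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
      stop("VCF input requires the VariantAnnotation package")
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    info <- VariantAnnotation::info(vcf)
    alt <- as.character(unlist(rr$ALT))
    pop <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                      pos = GenomicRanges::start(rr),
                      ref = as.character(rr$REF),
                      alt = alt, stringsAsFactors = FALSE)
    if (all(c("AC", "AN") %in% names(info))) {
      pop$AC <- as.integer(unlist(info$AC))
      pop$AN <- as.integer(info$AN)
    } else if ("AF" %in% names(info)) {
      pop$AF <- as.numeric(unlist(info$AF))
    } else {
      pop$AF <- 0
    }
  } else {
    pop <- utils::read.delim(path, stringsAsFactors = FALSE,
                             comment.char = "#")
    stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(pop)))
  }
  if (!is.null(tag)) pop$tag <- tag
  pop
}

#' Write enumerated variants / summaries
#'
#' @param variants Enumeration data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_variants <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_variants
#' @param summary A `consequence_summary`.
#' @export
write_summary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
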