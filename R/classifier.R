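#' Non-muscle actinopathy (NMA) classification labels
#'
#' The diagnostic workflow assigns each ACTB/ACTG1 variant carrier exactly
#' one of these labels. `unNMA` (unspecified non-muscle actinopathy) is a
#' provisional designation.
#' @export
NMA_LABELS <- c("ACTB_pLoF_disorder", "BWCFF1", "BWCFF2", "DDS1", "ACTG1_HL",
                "unNMA", "ACTG1_pLoF_likely_benign", "del17q25_contiguous",
                "unclassifiable")

VARIANT_CLASSES <- c("missense", "inframe_indel", "stop_gain", "frameshift",
                     "start_loss", "splice", "whole_gene_deletion")

PHENOTYPE_FLAGS <- c("bwcff_gestalt", "actb_lof_gestalt", "frontal_pachygyria",
                     "isolated_hearing_loss", "dystonia", "deafness",
                     "thrombocytopenia", "developmental_delay",
                     "congenital_anomalies")

TRISTATE <- c("present", "absent", "unknown")

#' Build one study-subject record
#'
#' A record couples the subject's genotype (gene, variant class, simple
#' protein-change token, NMD call for truncating alleles) with tri-state
#' phenotype flags (`"present"`, `"absent"`, `"unknown"`). Flags left
#' unspecified default to `"unknown"`; rule predicates treat `unknown` as
#' not-present (the counting convention for incomplete clinical
#' information), but the tri-state value is preserved for audit.
#'
#' @param subject_id Unique subject identifier.
#' @param gene `"ACTB"` or `"ACTG1"`.
#' @param variant_class One of
#'   `r paste(VARIANT_CLASSES, collapse = ", ")`.
#' @param protein_change Simple protein token such as `"Arg183Trp"`;
#'   required for missense/in-frame records, must be `NA` otherwise.
#' @param nmd_call `"subject_to_NMD"`, `"escapes_NMD"` or
#'   `"not_applicable"`.
#' @param ... Phenotype flags by name (see `PHENOTYPE_FLAGS`).
#' @return A one-row data.frame.
#' @export
individual_record <- function(subject_id, gene, variant_class,
                              protein_change = NA_character_,
                              nmd_call = "not_applicable", ...) {
  flags <- list(...)
  unknown <- setdiff(names(flags), PHENOTYPE_FLAGS)
  if (length(unknown)) stop("unknown phenotype flag(s): ",
                            paste(unknown, collapse = ", "))
  rec <- data.frame(subject_id = as.character(subject_id), gene = gene,
                    variant_class = variant_class,
                    protein_change = as.character(protein_change),
                    nmd_call = nmd_call, stringsAsFactors = FALSE)
  for (f in PHENOTYPE_FLAGS)
    rec[[f]] <- if (is.null(flags[[f]])) "unknown" else flags[[f]]
  validate_records(rec)
  rec
}

#' Validate cohort records
#'
#' @param records data.frame of [individual_record()] rows.
#' @return The records, invisibly.
#' @export
validate_records <- function(records) {
  need <- c("subject_id", "gene", "variant_class", "protein_change",
            "nmd_call", PHENOTYPE_FLAGS)
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("cohort table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(records$subject_id))
    stop("duplicate subject_id in cohort: ",
         paste(unique(records$subject_id[duplicated(records$subject_id)]),
               collapse = ", "))
  if (!all(records$gene %in% c("ACTB", "ACTG1")))
    stop("gene must be ACTB or ACTG1")
  if (!all(records$variant_class %in% VARIANT_CLASSES))
    stop("invalid variant_class value(s)")
  if (!all(records$nmd_call %in% c("subject_to_NMD", "escapes_NMD",
                                   "not_applicable")))
    stop("invalid nmd_call value(s)")
  for (f in PHENOTYPE_FLAGS)
    if (!all(records[[f]] %in% TRISTATE))
      stop("flag ", f, " must be one of present/absent/unknown")
  pav <- records$variant_class %in% c("missense", "inframe_indel")
  if (any(pav & (is.na(records$protein_change) |
                 records$protein_change == "")))
    stop("protein_change required for missense/inframe_indel records")
  if (any(!pav & !is.na(records$protein_change)))
    stop("protein_change must be NA for non protein-altering records")
  invisible(records)
}

flag_present <- function(record, flag) {
  identical(record[[flag]], "present")  # unknown counted as not present
}

#' Classify one subject through the NMA diagnostic workflow
#'
#' Deterministic rule engine implementing the variant- and phenotype-led
#' diagnostic workflow for ACTB/ACTG1 variant carriers. Rules fire in a
#' fixed order and the full trace of fired rules is returned:
#'
#' 1. `R1_*` gene + variant-class routing: ACTG1 truncating point variants
#'    are considered likely benign; ACTG1 whole-gene deletions route to the
#'    contiguous 17q25 deletion group; any ACTB predicted loss-of-function
#'    allele (stop gain, frameshift, start loss, regardless of NMD call) or
#'    whole-gene deletion routes to the ACTB pLoF disorder.
#' 2. `R2_actb_functional_lof`: ACTB missense/in-frame carriers with the
#'    ACTB-LoF facial gestalt and without frontal pachygyria join the ACTB
#'    pLoF disorder (unstable-protein arm).
#' 3. `R3_dds1`: ACTB p.Arg183Trp with dystonia or deafness is
#'    dystonia-deafness syndrome 1.
#' 4. `R4_bwcff`: missense/in-frame with the BWCFF gestalt and/or frontal
#'    predominant pachygyria is BWCFF1 (ACTB) or BWCFF2 (ACTG1).
#' 5. `R5_actg1_hl`: ACTG1 missense with isolated hearing loss and no other
#'    phenotype flag present.
#' 6. `R6_unnma`: remaining missense/in-frame carriers are provisionally
#'    unspecified NMA.
#' 7. `R7_unclassifiable`: anything else (e.g. splice alleles without an
#'    NMD call, ACTG1 start loss).
#'
#' @param record A one-row data.frame from [individual_record()] (or one
#'   row of a validated cohort table).
#' @return A list of class `nma_assignment`: `subject_id`, `label`,
#'   `rule_trace` (character vector of fired rule ids), `provisional`.
#' @export
classify <- function(record) {
  record <- as.data.frame(record)
  stopifnot(nrow(record) == 1L)
  validate_records(record)
  trace <- character(0)
  gene <- record$gene
  vc <- record$variant_class
  pav <- vc %in% c("missense", "inframe_indel")
  label <- NULL

  trace <- c(trace, "R1_gene_variant_routing")
  if (gene == "ACTG1" && vc %in% c("stop_gain", "frameshift")) {
    label <- "ACTG1_pLoF_likely_benign"
    trace <- c(trace, "R1a_actg1_plof_point")
  } else if (gene == "ACTG1" && vc == "whole_gene_deletion") {
    label <- "del17q25_contiguous"
    trace <- c(trace, "R1b_actg1_deletion")
  } else if (gene == "ACTB" &&
             vc %in% c("stop_gain", "frameshift", "start_loss",
                       "whole_gene_deletion")) {
    label <- "ACTB_pLoF_disorder"
    trace <- c(trace, "R1c_actb_plof")
  }

  if (is.null(label) && gene == "ACTB" && pav &&
      flag_present(record, "actb_lof_gestalt") &&
      !flag_present(record, "frontal_pachygyria")) {
    label <- "ACTB_pLoF_disorder"
    trace <- c(trace, "R2_actb_functional_lof")
  }
  if (is.null(label) && gene == "ACTB" &&
      identical(record$protein_change, "Arg183Trp") &&
      (flag_present(record, "dystonia") || flag_present(record, "deafness"))) {
    label <- "DDS1"
    trace <- c(trace, "R3_dds1")
  }
  if (is.null(label) && pav &&
      (flag_present(record, "bwcff_gestalt") ||
       flag_present(record, "frontal_pachygyria"))) {
    label <- if (gene == "ACTB") "BWCFF1" else "BWCFF2"
    trace <- c(trace, "R4_bwcff")
  }
  if (is.null(label) && gene == "ACTG1" && vc == "missense" &&
      flag_present(record, "isolated_hearing_loss") &&
      !any(vapply(setdiff(PHENOTYPE_FLAGS, "isolated_hearing_loss"),
                  function(f) flag_present(record, f), logical(1)))) {
    label <- "ACTG1_HL"
    trace <- c(trace, "R5_actg1_hl")
  }
  if (is.null(label) && pav) {
    label <- "unNMA"
    trace <- c(trace, "R6_unnma")
  }
  if (is.null(label)) {
    label <- "unclassifiable"
    trace <- c(trace, "R7_unclassifiable")
  }
  structure(list(subject_id = record$subject_id, label = label,
                 rule_trace = trace, provisional = label == "unNMA"),
            class = "nma_assignment")
}

#' @export
print.nma_assignment <- function(x, ...) {
  cat(sprintf("<nma_assignment> %s -> %s%s [%s]\n", x$subject_id, x$label,
              if (x$provisional) " (provisional)" else "",
              paste(x$rule_trace, collapse = " > ")))
  invisible(x)
}

#' Classify a whole cohort
#'
#' Applies [classify()] to every record, in stable `subject_id` order, and
#' tabulates per-label counts plus a label-by-gene cross-tab.
#'
#' @param records Cohort data.frame (one [individual_record()] row per
#'   subject; `subject_id` unique).
#' @return A list of class `nma_cohort_result`: `assignments` (data.frame
#'   `subject_id`, `gene`, `label`, `provisional`, `rule_trace`),
#'   `counts` (named integer vector over all labels), `by_gene`
#'   (label x gene table).
#' @export
classify_cohort <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) {
    counts <- stats::setNames(integer(length(NMA_LABELS)), NMA_LABELS)
    return(structure(list(
      assignments = data.frame(subject_id = character(0),
                               gene = character(0), label = character(0),
                               provisional = logical(0),
                               rule_trace = character(0)),
      counts = counts,
      by_gene = table(factor(character(0), NMA_LABELS),
                      factor(character(0), c("ACTB", "ACTG1")))),
      class = "nma_cohort_result"))
  }
  validate_records(records)
  records <- records[order(records$subject_id), , drop = FALSE]
  res <- lapply(seq_len(nrow(records)),
                function(i) classify(records[i, , drop = FALSE]))
  assignments <- data.frame(
    subject_id = vapply(res, `[[`, "", "subject_id"),
    gene = records$gene,
    label = vapply(res, `[[`, "", "label"),
    provisional = vapply(res, `[[`, TRUE, "provisional"),
    rule_trace = vapply(res, function(r) paste(r$rule_trace, collapse = ";"),
                        ""),
    stringsAsFactors = FALSE)
  lab <- factor(assignments$label, levels = NMA_LABELS)
  structure(list(assignments = assignments,
                 counts = stats::setNames(as.integer(table(lab)), NMA_LABELS),
                 by_gene = table(lab, factor(records$gene,
                                             c("ACTB", "ACTG1")))),
            class = "nma_cohort_result")
}

#' @export
print.nma_cohort_result <- function(x, ...) {
  cat("<nma_cohort_result>", nrow(x$assignments), "subjects\n")
  print(x$counts[x$counts > 0])
  invisible(x)
}

#' Read / write cohort tables
#'
#' Cohort records travel as TSV (one row per subject, `NA` for missing
#' protein_change) or JSON arrays of record objects.
#'
#' @param path File path; `.json` selects JSON, anything else TSV.
#' @return A validated cohort data.frame.
#' @export
read_cohort <- function(path) {
  if (grepl("\\.json$", path)) {
    records <- jsonlite::fromJSON(path)
    records$protein_change[records$protein_change %in% c("", "NA")] <-
      NA_character_
  } else {
    records <- utils::read.delim(path, stringsAsFactors = FALSE,
                                 na.strings = c("NA", ""))
    records$subject_id <- as.character(records$subject_id)
  }
  validate_records(records)
  records
}

#' @rdname read_cohort
#' @param records Cohort data.frame.
#' @export
write_cohort <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_cohort
#' @param result An `nma_cohort_result`.
#' @param assignments_path,report_path Output TSV / JSON paths.
#' @export
write_assignments <- function(result, assignments_path, report_path = NULL) {
  utils::write.table(result$assignments, assignments_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(report_path)) {
    report <- list(n = nrow(result$assignments),
                   counts = as.list(result$counts),
                   by_gene = lapply(seq_len(ncol(result$by_gene)), function(j)
                     stats::setNames(as.list(result$by_gene[, j]),
                                     rownames(result$by_gene))))
    names(report$by_gene) <- colnames(result$by_gene)
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(assignments_path)
}
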