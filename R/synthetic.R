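# Seeded generators for every input family the analyses consume. Each
# generator records its ground truth so parameter-recovery tests can use the
# generator's bookkeeping as the oracle.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state, so seeded generators do not
#' perturb the global stream.
#'
#' @param seed Integer seed (mandatory for all generators).
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) stop("a seed is mandatory")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

NON_STOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

#' Generate a synthetic coding transcript
#'
#' Builds a valid random open reading frame (start codon, non-stop internal
#' codons, terminal stop) with a configurable exon structure, optional
#' exonic UTRs, intronic spacers and flanking sequence, on either strand.
#' The default of 375 codons plus stop mirrors an actin ORF: 1,128 coding
#' nucleotides.
#'
#' @param n_codons Number of amino-acid codons (excluding the stop);
#'   CDS length is `3 * (n_codons + 1)`.
#' @param n_exons Number of exons the CDS is split across.
#' @param strand `"+"` or `"-"`.
#' @param chrom,genome_start Placement of the window.
#' @param utr5_len,utr3_len Exonic UTR lengths attached to the first/last
#'   exon.
#' @param intron_len Length of each intronic spacer (>= 4 so both canonical
#'   splice dinucleotides exist).
#' @param flank_len Extra window sequence beyond the transcript ends.
#' @param seed Integer seed.
#' @return A [transcript_model()] with `genome_sequence` populated.
#' @export
make_transcript <- function(n_codons = 375L, n_exons = 3L, strand = "+",
                            chrom = "chrS", genome_start = 1000L,
                            utr5_len = 30L, utr3_len = 30L,
                            intron_len = 120L, flank_len = 20L, seed = 1L) {
  if (n_codons < 2L) stop("config error: n_codons must be >= 2")
  L <- 3L * (n_codons + 1L)
  if (n_exons < 1L || n_exons > L)
    stop("config error: impossible exon partition (", n_exons,
         " exons for ", L, " coding nt)")
  if (n_exons > 1L && intron_len < 4L)
    stop("config error: intron_len must be >= 4")
  with_seed(seed, {
    cds <- paste0("ATG",
                  paste(sample(NON_STOP_CODONS, n_codons - 1L, replace = TRUE),
                        collapse = ""),
                  sample(c("TAA", "TAG", "TGA"), 1L))
    # contiguous CDS chunks per exon, each >= 1 nt
    cuts <- if (n_exons > 1L)
      sort(sample(seq_len(L - 1L), n_exons - 1L)) else integer(0)
    chunk_len <- diff(c(0L, cuts, L))
    rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")
    # assemble the window along the coding strand, tracking feature spans
    pieces <- character(0)
    cursor <- 0L
    exon_x <- cds_x <- list()
    add <- function(s) { pieces <<- c(pieces, s); cursor <<- cursor + nchar(s) }
    if (flank_len > 0L) add(rand_nt(flank_len))
    cds_off <- 0L
    for (j in seq_len(n_exons)) {
      ex_start <- cursor + 1L
      if (j == 1L && utr5_len > 0L) add(rand_nt(utr5_len))
      cs <- cursor + 1L
      add(substr(cds, cds_off + 1L, cds_off + chunk_len[j]))
      cds_off <- cds_off + chunk_len[j]
      cds_x[[j]] <- c(cs, cursor)
      if (j == n_exons && utr3_len > 0L) add(rand_nt(utr3_len))
      exon_x[[j]] <- c(ex_start, cursor)
      if (j < n_exons) add(rand_nt(intron_len))
    }
    if (flank_len > 0L) add(rand_nt(flank_len))
    w_coding <- paste(pieces, collapse = "")
    L_win <- nchar(w_coding)
    genome_end <- genome_start + L_win - 1L
    to_g <- function(x) if (strand == "+") genome_start + x - 1L
                        else genome_end - x + 1L
    iv <- function(spans) {
      df <- do.call(rbind, lapply(spans, function(s) {
        g <- sort(c(to_g(s[1L]), to_g(s[2L])))
        data.frame(start = g[1L], end = g[2L])
      }))
      df  # list order is 5'->3' on the coding strand by construction
    }
    transcript_model(
      gene_symbol = "SYNGENE", chrom = chrom, strand = strand,
      exons = iv(exon_x), cds_intervals = iv(cds_x),
      cds_sequence = cds,
      genome_sequence = if (strand == "+") w_coding else revcomp(w_coding),
      genome_start = genome_start, genome_end = genome_end)
  })
}

#' Generate a gnomAD-style population variant table
#'
#' Samples observed variants from the transcript's saturation enumeration
#' at configured per-class counts, plus non-overlapping decoy rows (small
#' indels inside the window) that no SNV enumeration can match. Allele
#' counts are drawn per row against a fixed total allele number. The
#' configured per-class counts are returned as the ground truth.
#'
#' @param model A [transcript_model()].
#' @param n_per_class Named integer vector of observed-variant counts per
#'   consequence class (names from `enumerate_snvs()` classes).
#' @param n_decoys Number of indel decoy rows.
#' @param an Total allele number (default emulates a ~431,130-individual
#'   aggregate: 862,260 alleles).
#' @param ac_max Per-variant allele counts are drawn uniformly from
#'   `1..ac_max`.
#' @param tag Provenance tag stored on every row.
#' @param seed Integer seed.
#' @return A list: `table` (population data.frame), `truth` (the per-class
#'   counts and decoy count).
#' @export
make_population <- function(model, n_per_class = c(missense = 10L,
                                                   synonymous = 15L),
                            n_decoys = 0L, an = 862260L, ac_max = 20L,
                            tag = "controls", seed = 1L) {
  if (any(n_per_class < 0L) || n_decoys < 0L)
    stop("config error: counts must be >= 0")
  enum <- enumerate_snvs(model, "coding_only")
  with_seed(seed, {
    rows <- lapply(names(n_per_class), function(cls) {
      idx <- which(enum$consequence == cls)
      if (length(idx) < n_per_class[[cls]])
        stop("config error: only ", length(idx), " enumerated ", cls,
             " alternates; cannot sample ", n_per_class[[cls]])
      pick <- idx[sample.int(length(idx), n_per_class[[cls]])]
      data.frame(chrom = enum$chrom[pick], pos = enum$genomic_pos[pick],
                 ref = enum$ref[pick], alt = enum$alt[pick],
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    if (is.null(tab))
      tab <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        stringsAsFactors = FALSE)
    if (n_decoys > 0L) {
      pos <- sample(seq.int(model$genome_start, model$genome_end - 1L),
                    n_decoys, replace = TRUE)
      decoys <- data.frame(chrom = model$chrom, pos = pos,
                           ref = vapply(pos, function(p) paste0(
                             sample(c("A", "C", "G", "T"), 1L), "A"), ""),
                           alt = sample(c("A", "C", "G", "T"), n_decoys,
                                        replace = TRUE),
                           stringsAsFactors = FALSE)
      tab <- rbind(tab, decoys)
    }
    if (nrow(tab)) {
      tab$AC <- sample.int(ac_max, nrow(tab), replace = TRUE)
      tab$AN <- an
      tab$tag <- tag
    } else {
      tab$AC <- integer(0); tab$AN <- integer(0); tab$tag <- character(0)
    }
    list(table = tab,
         truth = list(n_per_class = as.list(n_per_class),
                      n_decoys = n_decoys))
  })
}

#' Default synthetic cohort composition
#'
#' Per-subtype counts mirroring the published cohort arithmetic: 290
#' variant carriers = 275 single-nucleotide-variant carriers (145 ACTB +
#' 130 ACTG1) + 15 whole-gene deletions; the 259 protein-altering-variant
#' carriers split into BWCFF1 (73), BWCFF2 (40), ACTG1 hearing loss (60),
#' DDS1 (13), ACTB functional-LoF missense/in-frame (8) and unNMA (65 = 35
#' ACTB + 30 ACTG1); the remaining SNV carriers are 16 ACTB pLoF point
#' variants, and the deletions split 8 ACTB / 7 ACTG1.
#' @export
DEFAULT_COHORT_COMPOSITION <- c(
  BWCFF1 = 73L, BWCFF2 = 40L, ACTG1_HL = 60L, DDS1 = 13L,
  ACTB_func_LoF = 8L, unNMA_ACTB = 35L, unNMA_ACTG1 = 30L,
  ACTB_pLoF_SNV = 16L, ACTB_del = 8L, ACTG1_del = 7L)

AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
         "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
         "Tyr", "Val")

random_protein_change <- function(n) {
  repeat {
    tok <- paste0(sample(AA3, n, replace = TRUE),
                  sample.int(374L, n, replace = TRUE),
                  sample(AA3, n, replace = TRUE))
    if (!any(tok == "Arg183Trp")) return(tok)  # reserved for DDS1
  }
}

#' Generate a synthetic clinical cohort with known subtype truth
#'
#' Emits one record per subject with genotype fields and phenotype flags
#' constructed to satisfy the diagnostic-workflow rule for the subject's
#' true subtype; flags are then corrupted (present <-> absent flips) at the
#' configured noise rate, never touching gene/variant fields so genotype
#' routing stays valid. With `flag_noise = 0` the classifier reproduces the
#' truth labels exactly.
#'
#' @param composition Named counts per generator subtype (default
#'   [DEFAULT_COHORT_COMPOSITION]).
#' @param flag_noise Probability of flipping each phenotype flag.
#' @param seed Integer seed.
#' @return A list: `records` (cohort data.frame), `truth` (data.frame
#'   `subject_id`, `subtype`, `label` with the expected workflow label).
#' @export
make_cohort <- function(composition = DEFAULT_COHORT_COMPOSITION,
                        flag_noise = 0, seed = 1L) {
  if (any(composition < 0L)) stop("config error: counts must be >= 0")
  if (flag_noise < 0 || flag_noise > 1)
    stop("config error: flag_noise must be in [0, 1]")
  known <- names(DEFAULT_COHORT_COMPOSITION)
  if (!all(names(composition) %in% known))
    stop("unknown subtype(s): ",
         paste(setdiff(names(composition), known), collapse = ", "))
  label_of <- c(BWCFF1 = "BWCFF1", BWCFF2 = "BWCFF2", ACTG1_HL = "ACTG1_HL",
                DDS1 = "DDS1", ACTB_func_LoF = "ACTB_pLoF_disorder",
                unNMA_ACTB = "unNMA", unNMA_ACTG1 = "unNMA",
                ACTB_pLoF_SNV = "ACTB_pLoF_disorder",
                ACTB_del = "ACTB_pLoF_disorder",
                ACTG1_del = "del17q25_contiguous")
  with_seed(seed, {
    recs <- list(); truth <- list(); counter <- 0L
    emit <- function(subtype, gene, variant_class, protein_change,
                     nmd_call = "not_applicable", ...) {
      counter <<- counter + 1L
      id <- sprintf("S%04d", counter)
      recs[[counter]] <<- individual_record(id, gene, variant_class,
                                            protein_change, nmd_call, ...)
      truth[[counter]] <<- data.frame(subject_id = id, subtype = subtype,
                                      label = label_of[[subtype]],
                                      stringsAsFactors = FALSE)
    }
    for (subtype in names(composition)) {
      for (i in seq_len(composition[[subtype]])) {
        switch(subtype,
          BWCFF1 = {
            mode <- sample(c("gestalt", "pachygyria", "both"), 1L)
            emit(subtype, "ACTB", "missense", random_protein_change(1L),
                 bwcff_gestalt = if (mode != "pachygyria") "present" else "unknown",
                 frontal_pachygyria = if (mode != "gestalt") "present" else "absent",
                 developmental_delay = sample(TRISTATE, 1L))
          },
          BWCFF2 = {
            mode <- sample(c("gestalt", "pachygyria", "both"), 1L)
            emit(subtype, "ACTG1", "missense", random_protein_change(1L),
                 bwcff_gestalt = if (mode != "pachygyria") "present" else "unknown",
                 frontal_pachygyria = if (mode != "gestalt") "present" else "absent",
                 developmental_delay = sample(TRISTATE, 1L))
          },
          ACTG1_HL = emit(subtype, "ACTG1", "missense",
                          random_protein_change(1L),
                          isolated_hearing_loss = "present",
                          bwcff_gestalt = "absent",
                          frontal_pachygyria = "absent",
                          developmental_delay = "absent"),
          DDS1 = emit(subtype, "ACTB", "missense", "Arg183Trp",
                      dystonia = sample(c("present", "present", "absent"), 1L),
                      deafness = "present",
                      bwcff_gestalt = "absent",
                      frontal_pachygyria = "absent"),
          ACTB_func_LoF = emit(subtype, "ACTB",
                               sample(c("missense", "inframe_indel"), 1L),
                               random_protein_change(1L),
                               actb_lof_gestalt = "present",
                               frontal_pachygyria = "absent",
                               thrombocytopenia = sample(TRISTATE, 1L),
                               developmental_delay = "present"),
          unNMA_ACTB = emit(subtype, "ACTB", "missense",
                            random_protein_change(1L),
                            bwcff_gestalt = "absent",
                            actb_lof_gestalt = "absent",
                            frontal_pachygyria = "absent",
                            developmental_delay = "present",
                            congenital_anomalies = sample(TRISTATE, 1L)),
          unNMA_ACTG1 = emit(subtype, "ACTG1", "missense",
                             random_protein_change(1L),
                             bwcff_gestalt = "absent",
                             frontal_pachygyria = "absent",
                             isolated_hearing_loss = "absent",
                             developmental_delay = "present",
                             congenital_anomalies = sample(TRISTATE, 1L)),
          ACTB_pLoF_SNV = emit(subtype, "ACTB",
                               sample(c("stop_gain", "frameshift",
                                        "start_loss"), 1L,
                                      prob = c(0.5, 0.4, 0.1)),
                               NA_character_,
                               nmd_call = sample(c("subject_to_NMD",
                                                   "escapes_NMD"), 1L),
                               developmental_delay = "present",
                               thrombocytopenia = sample(TRISTATE, 1L)),
          ACTB_del = emit(subtype, "ACTB", "whole_gene_deletion",
                          NA_character_,
                          developmental_delay = "present",
                          thrombocytopenia = sample(TRISTATE, 1L)),
          ACTG1_del = emit(subtype, "ACTG1", "whole_gene_deletion",
                           NA_character_,
                           developmental_delay = sample(TRISTATE, 1L)))
      }
    }
    records <- do.call(rbind, recs)
    truth <- do.call(rbind, truth)
    if (is.null(records)) {
      records <- individual_record("tmp", "ACTB", "missense", "Ala1Gly")[0, ]
      truth <- data.frame(subject_id = character(0), subtype = character(0),
                          label = character(0))
    }
    if (flag_noise > 0 && nrow(records)) {
      for (f in PHENOTYPE_FLAGS) {
        flip <- stats::runif(nrow(records)) < flag_noise &
          records[[f]] != "unknown"
        records[[f]][flip] <- ifelse(records[[f]][flip] == "present",
                                     "absent", "present")
      }
    }
    list(records = records, truth = truth)
  })
}

#' Default synthetic facial-embedding composition
#'
#' Cluster sizes mirroring the published image analysis: 75 images across
#' BWCFF (38), ACTB LoF (19), unNMA (15) and BWCFF_unNMA (3).
#' @export
DEFAULT_EMBEDDING_COMPOSITION <- c(BWCFF = 38L, ACTB_LoF = 19L,
                                   unNMA = 15L, BWCFF_unNMA = 3L)

#' Generate synthetic facial embeddings from spherical clusters
#'
#' Each cluster has a unit mean direction; vectors are drawn as the mean
#' direction plus isotropic Gaussian angular noise and re-normalized to the
#' unit sphere (a von Mises-Fisher-like construction: cosine distance only
#' sees directions). Smaller `within_sd` means tighter clusters.
#'
#' @param composition Named cluster sizes (default
#'   [DEFAULT_EMBEDDING_COMPOSITION]).
#' @param k Embedding dimension (default 512, the facial encoder's output
#'   size).
#' @param within_sd Per-coordinate angular noise SD.
#' @param orthogonal If `TRUE`, cluster mean directions are exactly
#'   orthonormal (angular separation pi/2); otherwise random directions
#'   (near-orthogonal in high dimension).
#' @param seed Integer seed.
#' @return An [embedding_set()] with `cohort`/`syndrome` set to the cluster
#'   name; cluster truth in attribute `"truth"`.
#' @export
make_embeddings <- function(composition = DEFAULT_EMBEDDING_COMPOSITION,
                            k = 512L, within_sd = 0.05, orthogonal = FALSE,
                            seed = 1L) {
  if (any(composition < 1L)) stop("config error: cluster sizes must be >= 1")
  if (within_sd < 0) stop("config error: within_sd must be >= 0")
  m <- length(composition)
  if (orthogonal && m > k) stop("config error: more clusters than dimensions")
  with_seed(seed, {
    centers <- if (orthogonal) diag(1, k)[seq_len(m), , drop = FALSE]
    else {
      z <- matrix(stats::rnorm(m * k), m, k)
      z / sqrt(rowSums(z^2))
    }
    vecs <- do.call(rbind, lapply(seq_len(m), function(j) {
      n <- composition[[j]]
      x <- matrix(centers[j, ], n, k, byrow = TRUE) +
        matrix(stats::rnorm(n * k, sd = within_sd), n, k)
      x / sqrt(rowSums(x^2))
    }))
    labels <- rep(names(composition), composition)
    out <- embedding_set(vecs, cohort = labels, syndrome = labels)
    attr(out, "truth") <- list(composition = as.list(composition),
                               centers = centers, within_sd = within_sd)
    out
  })
}

#' Generate a multi-syndrome control pool
#'
#' Convenience wrapper over [make_embeddings()] emulating a large
#' mixed-syndrome database pool: `n_syndromes` clusters of
#' `images_per_syndrome` images each.
#'
#' @param n_syndromes,images_per_syndrome Pool shape.
#' @inheritParams make_embeddings
#' @return An [embedding_set()].
#' @export
make_control_pool <- function(n_syndromes = 40L, images_per_syndrome = 10L,
                              k = 512L, within_sd = 0.3, seed = 1L) {
  comp <- stats::setNames(rep(images_per_syndrome, n_syndromes),
                          sprintf("SYN%03d", seq_len(n_syndromes)))
  make_embeddings(comp, k = k, within_sd = within_sd, seed = seed)
}

#' Generate synthetic kinetic traces
#'
#' Single-exponential signals `F0 + A (1 - exp(-k t))` (polymerization) or
#' `F0 + A exp(-k t)` (depolymerization) plus Gaussian noise; the true `k`
#' of every trace is recorded.
#'
#' @param n_traces Number of traces.
#' @param k True rate constant(s) in 1/s (recycled over traces).
#' @param mode Trace mode.
#' @param n_points,t_max Time grid: `n_points` samples over `[0, t_max]`
#'   seconds.
#' @param F0,A Baseline and amplitude.
#' @param noise_sd Gaussian noise SD in signal units (>= 0).
#' @param seed Integer seed.
#' @return A list: `traces` (named list of [kinetic_trace()]), `truth`
#'   (data.frame `trace_id`, `k`, `t_half`).
#' @export
make_traces <- function(n_traces = 1L, k = 0.1, mode = "polymerization",
                        n_points = 200L, t_max = 120, F0 = 100, A = 1000,
                        noise_sd = 0, seed = 1L) {
  if (noise_sd < 0) stop("config error: noise_sd must be >= 0")
  if (n_points < 8L) stop("config error: n_points must be >= 8")
  kk <- rep_len(k, n_traces)
  with_seed(seed, {
    tgrid <- seq(0, t_max, length.out = n_points)
    traces <- lapply(seq_len(n_traces), function(i) {
      mu <- if (mode == "polymerization") F0 + A * (1 - exp(-kk[i] * tgrid))
            else F0 + A * exp(-kk[i] * tgrid)
      kinetic_trace(tgrid, mu + stats::rnorm(n_points, sd = noise_sd),
                    mode = mode)
    })
    names(traces) <- sprintf("trace%03d", seq_len(n_traces))
    list(traces = traces,
         truth = data.frame(trace_id = names(traces), k = kk,
                            t_half = log(2) / kk))
  })
}

#' Generate synthetic melt curves
#'
#' Two-state sigmoid `F0 + A / (1 + exp(-(T - Tm) / slope))` plus Gaussian
#' noise over a linear temperature grid; the analytic inflection point
#' (= the true Tm) of every curve is recorded.
#'
#' @param n_curves Number of curves.
#' @param Tm True melting temperature(s) in degrees C (recycled).
#' @param slope Transition width parameter in degrees C.
#' @param t_min,t_max,t_step Temperature grid.
#' @param F0,A Baseline and amplitude.
#' @param noise_sd Gaussian noise SD in signal units (>= 0).
#' @param seed Integer seed.
#' @return A list: `curves` (named list of [melt_curve()]), `truth`
#'   (data.frame `trace_id`, `Tm`).
#' @export
make_melts <- function(n_curves = 1L, Tm = 60, slope = 1.5, t_min = 40,
                       t_max = 80, t_step = 0.5, F0 = 50, A = 500,
                       noise_sd = 0, seed = 1L) {
  if (noise_sd < 0) stop("config error: noise_sd must be >= 0")
  tms <- rep_len(Tm, n_curves)
  if (any(tms <= t_min) || any(tms >= t_max))
    stop("config error: Tm must lie inside the temperature grid")
  with_seed(seed, {
    grid <- seq(t_min, t_max, by = t_step)
    curves <- lapply(seq_len(n_curves), function(i) {
      mu <- F0 + A / (1 + exp(-(grid - tms[i]) / slope))
      melt_curve(grid, mu + stats::rnorm(length(grid), sd = noise_sd))
    })
    names(curves) <- sprintf("melt%03d", seq_len(n_curves))
    list(curves = curves,
         truth = data.frame(trace_id = names(curves), Tm = tms))
  })
}

#' Write trace / melt sets to CSV (long format)
#'
#' @param traces Named list of [kinetic_trace()] objects.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_traces <- function(traces, path) {
  df <- do.call(rbind, lapply(names(traces), function(id)
    data.frame(trace_id = id, time_s = traces[[id]]$time,
               signal = traces[[id]]$signal)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @param curves Named list of [melt_curve()] objects.
#' @export
write_melts <- function(curves, path) {
  df <- do.call(rbind, lapply(names(curves), function(id)
    data.frame(trace_id = id, temp_C = curves[[id]]$temperature,
               signal = curves[[id]]$signal)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
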