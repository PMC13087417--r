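# End-to-end orchestration: simulate -> saturate / classify / gestalt /
# kinetics -> report, with plain-file handoff between stages so each stage is
# independently scriptable.

#' Default pipeline configuration
#'
#' A complete demo configuration: a two-gene saturation of 375-codon
#' transcripts, a population extract, the default 290-subject cohort, the
#' 75-image embedding fixture with a mixed-syndrome control pool, and small
#' trace/melt batches. All stages derive their seeds from `seed`.
#'
#' @param seed Master integer seed.
#' @return A nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  seed <- as.integer(seed)
  list(
    seed = seed,
    transcripts = list(
      list(gene = "ACTB_like", n_codons = 375L, n_exons = 6L, strand = "-"),
      list(gene = "ACTG1_like", n_codons = 375L, n_exons = 6L, strand = "+")),
    population = list(n_missense = 43L, n_synonymous = 100L, n_decoys = 5L),
    cohort = list(composition = as.list(DEFAULT_COHORT_COMPOSITION),
                  flag_noise = 0),
    gestalt = list(composition = as.list(DEFAULT_EMBEDDING_COMPOSITION),
                   k = 512L, within_sd = 0.15,
                   cohorts = c("BWCFF", "ACTB_LoF"),
                   threshold = GESTALT_THRESHOLD,
                   n_iterations = 100L, subsample_fraction = 0.75,
                   pool = list(n_syndromes = 30L, images_per_syndrome = 12L,
                               within_sd = 0.3),
                   n_batches = 200L),
    kinetics = list(n_traces = 6L, k = 0.1, noise_sd = 10, n_points = 150L,
                    t_max = 120),
    melts = list(n_curves = 6L, Tm = 60, slope = 1.5, noise_sd = 5))
}

stage_runner <- function(manifest_env) {
  function(name, deps, fun) {
    m <- manifest_env
    failed_dep <- deps[vapply(deps, function(d)
      !identical(m$stages[[d]]$status, "ok"), TRUE)]
    if (length(failed_dep)) {
      m$stages[[name]] <- list(status = "skipped",
                               reason = paste("dependency failed:",
                                              paste(failed_dep, collapse = ",")),
                               outputs = character(0), wall_s = 0)
      message(sprintf("[%s] skipped (%s)", name, m$stages[[name]]$reason))
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(list(ok = TRUE, outputs = fun()),
                    error = function(e) list(ok = FALSE,
                                             msg = conditionMessage(e)))
    wall <- proc.time()[["elapsed"]] - t0
    if (res$ok) {
      m$stages[[name]] <- list(status = "ok", outputs = res$outputs,
                               checksums = as.list(tools::md5sum(res$outputs)),
                               wall_s = round(wall, 3))
      message(sprintf("[%s] ok (%.2fs)", name, wall))
    } else {
      m$stages[[name]] <- list(status = "failed", reason = res$msg,
                               outputs = character(0), wall_s = round(wall, 3))
      message(sprintf("[%s] FAILED: %s", name, res$msg))
    }
    invisible(NULL)
  }
}

#' Run the full pipeline
#'
#' Executes, in dependency order: synthetic-data generation, saturation
#' enumeration + population summary per transcript, cohort classification,
#' embedding-space comparisons and cohesion, and kinetic/melt fitting.
#' Every stage writes plain files under `out_dir`; the run manifest lists
#' every output with an md5 checksum, so a rerun with identical
#' configuration and seed reproduces identical checksums for the
#' deterministic stages. A stage failure is recorded in the manifest,
#' downstream stages are skipped, and the manifest's `ok` flag turns
#' `FALSE` (the CLI exits nonzero).
#'
#' @param config Configuration list (see [default_config()]) or a path to a
#'   JSON file holding one.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the run manifest (list of class `run_manifest`), also
#'   written to `manifest.json`, with a human-readable `report.md`.
#' @export
run_all <- function(config = default_config(), out_dir) {
  if (is.character(config))
    config <- jsonlite::fromJSON(config, simplifyDataFrame = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, paste0(...))
  seed <- as.integer(config$seed %||% 1L)

  cfg_file <- p("config.json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  m <- new.env()
  m$stages <- list()
  run_stage <- stage_runner(m)
  state <- new.env()

  run_stage("simulate", character(0), function() {
    out <- character(0)
    state$models <- list()
    for (i in seq_along(config$transcripts)) {
      tc <- config$transcripts[[i]]
      model <- make_transcript(n_codons = tc$n_codons %||% 375L,
                               n_exons = tc$n_exons %||% 3L,
                               strand = tc$strand %||% "+",
                               chrom = paste0("chrS", i),
                               seed = seed + i)
      model$gene_symbol <- tc$gene %||% paste0("GENE", i)
      fa <- p(model$gene_symbol, ".fa"); bed <- p(model$gene_symbol, ".tsv")
      write_transcript(model, fa, bed)
      pc <- config$population
      pop <- make_population(model,
                             n_per_class = c(missense = pc$n_missense %||% 20L,
                                             synonymous = pc$n_synonymous %||% 20L),
                             n_decoys = pc$n_decoys %||% 0L,
                             seed = seed + 100L + i)
      pf <- p(model$gene_symbol, "_population.tsv")
      utils::write.table(pop$table, pf, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      jsonlite::write_json(pop$truth, p(model$gene_symbol,
                                        "_population_truth.json"),
                           auto_unbox = TRUE, digits = NA)
      state$models[[model$gene_symbol]] <- model
      out <- c(out, fa, bed, pf, p(model$gene_symbol,
                                   "_population_truth.json"))
    }
    coh <- make_cohort(composition = unlist(config$cohort$composition),
                       flag_noise = config$cohort$flag_noise %||% 0,
                       seed = seed + 200L)
    write_cohort(coh$records, p("cohort.tsv"))
    utils::write.table(coh$truth, p("cohort_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    gc_ <- config$gestalt
    emb <- make_embeddings(composition = unlist(gc_$composition),
                           k = gc_$k %||% 512L,
                           within_sd = gc_$within_sd %||% 0.15,
                           seed = seed + 300L)
    write_embeddings(emb, p("embeddings.csv"))
    pool <- make_control_pool(n_syndromes = gc_$pool$n_syndromes %||% 30L,
                              images_per_syndrome =
                                gc_$pool$images_per_syndrome %||% 12L,
                              k = gc_$k %||% 512L,
                              within_sd = gc_$pool$within_sd %||% 0.3,
                              seed = seed + 301L)
    write_embeddings(pool, p("pool.csv"))
    kc <- config$kinetics
    tr <- make_traces(n_traces = kc$n_traces %||% 4L, k = kc$k %||% 0.1,
                      noise_sd = kc$noise_sd %||% 0,
                      n_points = kc$n_points %||% 150L,
                      t_max = kc$t_max %||% 120, seed = seed + 400L)
    write_traces(tr$traces, p("traces.csv"))
    utils::write.table(tr$truth, p("traces_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    mc <- config$melts
    ml <- make_melts(n_curves = mc$n_curves %||% 4L, Tm = mc$Tm %||% 60,
                     slope = mc$slope %||% 1.5,
                     noise_sd = mc$noise_sd %||% 0, seed = seed + 500L)
    write_melts(ml$curves, p("melts.csv"))
    utils::write.table(ml$truth, p("melts_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    c(out, p("cohort.tsv"), p("cohort_truth.tsv"), p("embeddings.csv"),
      p("pool.csv"), p("traces.csv"), p("traces_truth.tsv"), p("melts.csv"),
      p("melts_truth.tsv"))
  })

  run_stage("saturate", "simulate", function() {
    out <- character(0)
    for (gene in names(state$models)) {
      model <- state$models[[gene]]
      enum <- enumerate_snvs(model, "coding_only")
      pop <- read_population(p(gene, "_population.tsv"))
      summ <- summarize_consequences(enum, pop)
      vf <- p(gene, "_saturation.tsv"); sf <- p(gene, "_summary.json")
      write_variants(enum, vf)
      write_summary(summ, sf)
      out <- c(out, vf, sf)
    }
    out
  })

  run_stage("classify", "simulate", function() {
    records <- read_cohort(p("cohort.tsv"))
    res <- classify_cohort(records)
    write_assignments(res, p("assignments.tsv"), p("classification.json"))
    c(p("assignments.tsv"), p("classification.json"))
  })

  run_stage("gestalt", "simulate", function() {
    emb <- read_embeddings(p("embeddings.csv"))
    pool <- read_embeddings(p("pool.csv"))
    gc_ <- config$gestalt
    cohorts <- gc_$cohorts %||% utils::head(unique(emb$cohort), 2L)
    ctrl <- build_control_distributions(pool, n_pairs = 100L,
                                        cohort_size = 5L, seed = seed + 310L)
    cmp <- compare_cohorts(cohort_vectors(emb, cohorts[1L]),
                           cohort_vectors(emb, cohorts[2L]),
                           c = gc_$threshold %||% GESTALT_THRESHOLD,
                           n_iterations = gc_$n_iterations %||% 100L,
                           subsample_fraction =
                             gc_$subsample_fraction %||% 0.75,
                           seed = seed + 311L, controls = ctrl)
    coh <- lapply(unique(emb$cohort), function(cc) {
      v <- cohort_vectors(emb, cc)
      if (nrow(v) < 2L) return(NULL)
      r <- cohesion(v, pool, n_batches = gc_$n_batches %||% 200L,
                    seed = seed + 312L)
      list(cohort = cc, d = r$d,
           left_tail_percentile = r$left_tail_percentile)
    })
    report <- list(
      comparison = list(cohorts = cohorts, d = cmp$d, c = cmp$c,
                        fraction_above = cmp$fraction_above,
                        decision = cmp$decision, ppv = cmp$ppv,
                        seed = cmp$seed),
      cohesion = Filter(Negate(is.null), coh))
    jsonlite::write_json(report, p("gestalt.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    p("gestalt.json")
  })

  run_stage("kinetics", "simulate", function() {
    fits <- fit_traces(read_traces(p("traces.csv")))
    utils::write.table(fits, p("kinetic_fits.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    melts <- fit_melts(read_melts(p("melts.csv")))
    utils::write.table(melts, p("melt_fits.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    c(p("kinetic_fits.tsv"), p("melt_fits.tsv"))
  })

  statuses <- vapply(m$stages, `[[`, "", "status")
  manifest <- structure(list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = seed,
    out_dir = normalizePath(out_dir),
    package_version = as.character(utils::packageVersion("nmascope")),
    stages = m$stages,
    ok = all(statuses == "ok")), class = "run_manifest")
  jsonlite::write_json(unclass(manifest), p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(render_report_md(manifest), p("report.md"))
  invisible(manifest)
}

render_report_md <- function(manifest) {
  lines <- c("# nmascope pipeline report", "",
             paste0("- seed: ", manifest$seed),
             paste0("- config hash: ", manifest$config_hash),
             paste0("- package: nmascope ", manifest$package_version),
             paste0("- overall: ", if (manifest$ok) "OK" else "FAILED"), "",
             "| stage | status | wall (s) | outputs |",
             "|-------|--------|----------|---------|")
  for (nm in names(manifest$stages)) {
    st <- manifest$stages[[nm]]
    lines <- c(lines, sprintf("| %s | %s | %.2f | %s |", nm, st$status,
                              st$wall_s,
                              paste(basename(st$outputs), collapse = ", ")))
  }
  lines
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>", if (x$ok) "OK" else "FAILED", "| seed", x$seed, "\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-9s %s\n", nm, x$stages[[nm]]$status))
  invisible(x)
}
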