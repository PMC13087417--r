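test_that("gene + variant-class routing fires before any phenotype rule", {
  # ACTG1 truncating point variants are likely benign, whatever the flags
  a <- classify(toy_record(gene = "ACTG1", variant_class = "stop_gain",
                           protein_change = NA))
  expect_equal(a$label, "ACTG1_pLoF_likely_benign")
  expect_true("R1a_actg1_plof_point" %in% a$rule_trace)
  a <- classify(toy_record(gene = "ACTG1", variant_class = "frameshift",
                           protein_change = NA, bwcff_gestalt = "present"))
  expect_equal(a$label, "ACTG1_pLoF_likely_benign")
  # whole-gene deletions split by gene
  expect_equal(classify(toy_record(gene = "ACTG1",
                                   variant_class = "whole_gene_deletion",
                                   protein_change = NA))$label,
               "del17q25_contiguous")
  expect_equal(classify(toy_record(gene = "ACTB",
                                   variant_class = "whole_gene_deletion",
                                   protein_change = NA))$label,
               "ACTB_pLoF_disorder")
  # ACTB pLoF routes identically for either NMD call
  for (nmd in c("subject_to_NMD", "escapes_NMD"))
    for (vc in c("stop_gain", "frameshift", "start_loss"))
      expect_equal(classify(toy_record(gene = "ACTB", variant_class = vc,
                                       protein_change = NA,
                                       nmd_call = nmd))$label,
                   "ACTB_pLoF_disorder")
})

test_that("functional-LoF, DDS1, BWCFF, HL and unNMA arms fire in order", {
  # ACTB missense with the LoF gestalt and no pachygyria -> pLoF disorder
  a <- classify(toy_record(actb_lof_gestalt = "present",
                           frontal_pachygyria = "absent"))
  expect_equal(a$label, "ACTB_pLoF_disorder")
  expect_true("R2_actb_functional_lof" %in% a$rule_trace)
  # Arg183Trp with dystonia and deafness -> DDS1
  a <- classify(toy_record(protein_change = "Arg183Trp",
                           dystonia = "present", deafness = "present"))
  expect_equal(a$label, "DDS1")
  # pachygyria alone diagnoses BWCFF even with unknown gestalt
  a <- classify(toy_record(frontal_pachygyria = "present"))
  expect_equal(a$label, "BWCFF1")
  expect_equal(classify(toy_record(gene = "ACTG1",
                                   frontal_pachygyria = "present"))$label,
               "BWCFF2")
  # gestalt alone also suffices
  expect_equal(classify(toy_record(bwcff_gestalt = "present"))$label,
               "BWCFF1")
  # ACTG1 missense with isolated hearing loss and nothing else
  expect_equal(classify(toy_record(gene = "ACTG1",
                                   isolated_hearing_loss = "present"))$label,
               "ACTG1_HL")
  # ...but any other present flag blocks the HL arm
  expect_equal(classify(toy_record(gene = "ACTG1",
                                   isolated_hearing_loss = "present",
                                   developmental_delay = "present"))$label,
               "unNMA")
  # featureless missense falls through to provisional unNMA
  a <- classify(toy_record())
  expect_equal(a$label, "unNMA")
  expect_true(a$provisional)
  # splice variants have no arm -> unclassifiable
  expect_equal(classify(toy_record(variant_class = "splice",
                                   protein_change = NA))$label,
               "unclassifiable")
})

test_that("unknown flags count as not-present but are preserved in records", {
  rec <- toy_record(gene = "ACTG1", isolated_hearing_loss = "present")
  expect_equal(rec$developmental_delay, "unknown")
  expect_equal(classify(rec)$label, "ACTG1_HL")  # unknowns do not block
})

test_that("DDS1 requires ACTB and the Arg183Trp token", {
  # same token in ACTG1 is not DDS1
  expect_equal(classify(toy_record(gene = "ACTG1",
                                   protein_change = "Arg183Trp",
                                   dystonia = "present"))$label, "unNMA")
  # Arg183Trp without dystonia/deafness is not DDS1 either
  expect_equal(classify(toy_record(protein_change = "Arg183Trp"))$label,
               "unNMA")
  # DDS1 beats a coincident BWCFF gestalt (fixed rule order)
  a <- classify(toy_record(protein_change = "Arg183Trp",
                           dystonia = "present",
                           bwcff_gestalt = "present"))
  expect_equal(a$label, "DDS1")
})

test_that("classification is total, deterministic, and label-gene consistent", {
  coh <- make_cohort(flag_noise = 0.35, seed = 77L)
  for (i in seq_len(nrow(coh$records))) {
    rec <- coh$records[i, , drop = FALSE]
    a1 <- classify(rec)
    a2 <- classify(rec)
    expect_identical(a1$label, a2$label)
    expect_true(a1$label %in% NMA_LABELS)
    expect_gt(length(a1$rule_trace), 0L)
    if (a1$label == "BWCFF1") expect_equal(rec$gene, "ACTB")
    if (a1$label == "BWCFF2") expect_equal(rec$gene, "ACTG1")
    if (a1$label == "DDS1") {
      expect_equal(rec$gene, "ACTB")
      expect_equal(rec$protein_change, "Arg183Trp")
    }
    expect_equal(a1$provisional, a1$label == "unNMA")
  }
})

test_that("setting pachygyria present never moves a missense record out of BWCFF", {
  coh <- make_cohort(flag_noise = 0.35, seed = 13L)
  mis <- coh$records[coh$records$variant_class %in%
                       c("missense", "inframe_indel"), ]
  before <- vapply(seq_len(nrow(mis)),
                   function(i) classify(mis[i, , drop = FALSE])$label, "")
  mis$frontal_pachygyria <- "present"
  after <- vapply(seq_len(nrow(mis)),
                  function(i) classify(mis[i, , drop = FALSE])$label, "")
  was_bwcff <- before %in% c("BWCFF1", "BWCFF2")
  expect_true(all(after[was_bwcff] %in% c("BWCFF1", "BWCFF2")))
})

test_that("classify_cohort tabulates labels with stable ordering", {
  empty <- classify_cohort(make_cohort(composition = integer(0))$records)
  expect_true(all(empty$counts == 0L))
  expect_equal(nrow(empty$assignments), 0L)

  one <- classify_cohort(toy_record("D1", protein_change = "Arg183Trp",
                                    dystonia = "present"))
  expect_equal(unname(one$counts["DDS1"]), 1L)
  expect_equal(sum(one$counts), 1L)

  dup <- rbind(toy_record("X"), toy_record("X"))
  expect_error(classify_cohort(dup), "duplicate subject_id")

  res <- classify_cohort(make_cohort(seed = 4L)$records)
  expect_equal(res$assignments$subject_id,
               sort(res$assignments$subject_id))
  expect_equal(sum(res$counts), 290L)
  expect_equal(sum(res$by_gene), 290L)
})

test_that("noiseless synthetic cohorts are relabeled exactly as generated", {
  coh <- make_cohort(flag_noise = 0, seed = 21L)
  res <- classify_cohort(coh$records)
  merged <- merge(res$assignments, coh$truth, by = "subject_id")
  expect_equal(merged$label.x, merged$label.y)
  # per-label counts equal the generator's configuration
  expect_equal(unname(res$counts["BWCFF1"]), 73L)
  expect_equal(unname(res$counts["BWCFF2"]), 40L)
  expect_equal(unname(res$counts["ACTG1_HL"]), 60L)
  expect_equal(unname(res$counts["DDS1"]), 13L)
  expect_equal(unname(res$counts["unNMA"]), 65L)
  expect_equal(unname(res$counts["ACTB_pLoF_disorder"]), 8L + 16L + 8L)
  expect_equal(unname(res$counts["del17q25_contiguous"]), 7L)
})

test_that("record validation rejects malformed cohorts", {
  expect_error(individual_record("P", "TP53", "missense", "Ala1Gly"),
               "ACTB or ACTG1")
  expect_error(individual_record("P", "ACTB", "weird", "Ala1Gly"),
               "variant_class")
  expect_error(individual_record("P", "ACTB", "missense", NA),
               "protein_change required")
  expect_error(individual_record("P", "ACTB", "stop_gain", "Ala1Gly"),
               "must be NA")
  expect_error(individual_record("P", "ACTB", "missense", "Ala1Gly",
                                 dystonia = "maybe"), "present/absent/unknown")
  expect_error(individual_record("P", "ACTB", "missense", "Ala1Gly",
                                 not_a_flag = "present"), "unknown phenotype")
})

test_that("cohort TSV and JSON round-trips preserve records and labels", {
  coh <- make_cohort(composition = c(BWCFF1 = 3L, DDS1 = 2L, ACTB_del = 1L),
                     seed = 8L)
  tsv <- tempfile(fileext = ".tsv")
  write_cohort(coh$records, tsv)
  back <- read_cohort(tsv)
  expect_equal(back$protein_change, coh$records$protein_change)
  expect_equal(classify_cohort(back)$counts,
               classify_cohort(coh$records)$counts)

  js <- tempfile(fileext = ".json")
  jsonlite::write_json(coh$records, js, auto_unbox = FALSE, digits = NA,
                       na = "string")
  backj <- read_cohort(js)
  expect_equal(classify_cohort(backj)$counts,
               classify_cohort(coh$records)$counts)

  out_tsv <- tempfile(fileext = ".tsv"); out_js <- tempfile(fileext = ".json")
  res <- classify_cohort(coh$records)
  write_assignments(res, out_tsv, out_js)
  rep <- jsonlite::fromJSON(out_js)
  expect_equal(rep$n, 6L)
  expect_equal(rep$counts$BWCFF1, 3L)
})
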