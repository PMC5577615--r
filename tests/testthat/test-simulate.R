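test_that("planted precursors annotate back to their planted boundaries", {
  set.seed(1)
  for (label in c("A", "B", "C", "D")) {
    plant <- simulate_precursor(label)
    sp <- predict_signal_peptide(plant$precursor)
    expect_true(sp$present)
    expect_equal(sp$cleavage_pos, 23)
    ann <- annotate_precursor(plant$precursor, sp)
    expect_true(ann$accepted)
    m <- mature_from_annotation(ann)
    expect_equal(m$sequence, plant$mature)
    expect_equal(m$amidated, plant$amidated)
    expect_equal(classify_subfamily(m$sequence)$label, label)
  }
})

test_that("subfamily C cores are built without proline", {
  set.seed(2)
  for (i in 1:10) {
    plant <- simulate_precursor("C")
    expect_lte(composition(plant$mature)$fractions[["P"]], 0.05)
  }
})

test_that("amidated plants end one residue before the glycine donor", {
  set.seed(3)
  seen_amidated <- FALSE
  for (i in 1:20) {
    plant <- simulate_precursor("A")
    if (!plant$amidated) next
    seen_amidated <- TRUE
    core_end <- regmatches(plant$precursor,
                           regexpr("[A-Z]+?GKR", plant$precursor))
    expect_true(grepl(paste0(plant$mature, "GKR"), plant$precursor,
                      fixed = TRUE))
  }
  expect_true(seen_amidated)
})

test_that("simulation is deterministic and respects empty configs", {
  cfg <- sim_config(n_planted = 0, n_decoys = 10, seed = 2)
  sim <- simulate_transcriptome(cfg)
  expect_equal(nrow(sim$transcripts), 10)
  expect_equal(nrow(sim$truth), 0)
  sim2 <- simulate_transcriptome(cfg)
  expect_identical(sim, sim2)
  fa1 <- withr::local_tempfile(fileext = ".fasta")
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(sim$transcripts, fa1)
  write_fasta(sim2$transcripts, fa2)
  expect_identical(readLines(fa1), readLines(fa2))
})

test_that("reverse translation re-extracts the planted protein", {
  set.seed(4)
  cfg <- sim_config(n_planted = 5, n_decoys = 0, seed = 4)
  sim <- simulate_transcriptome(cfg)
  orfs <- extract_orfs(sim$transcripts)
  for (i in seq_len(nrow(sim$truth))) {
    hit <- orfs[orfs$transcript_id == sim$truth$transcript_id[i], ]
    expect_true(sim$truth$precursor[i] %in% hit$protein)
  }
})

test_that("recovery metrics count matches, misses and spurious reports", {
  truth <- tibble::tibble(
    transcript_id = c("t1", "t2", "t3"),
    mature = c("RPRA", "RPRV", "RPRL"),
    amidated = c(TRUE, FALSE, FALSE)
  )
  reports <- tibble::tibble(
    transcript_id = c("t1", "x9"),
    mature = c("RPRA", "RPRA"),
    amidated = c(TRUE, TRUE)
  )
  res <- evaluate_recovery(reports, truth)
  expect_equal(res$sensitivity, 1 / 3)
  expect_equal(res$precision, 1 / 2)
  expect_equal(res$exact_mature_match_rate, 1 / 3)
  empty <- evaluate_recovery(reports[0, ], truth)
  expect_equal(empty$sensitivity, 0)
  expect_true(is.na(empty$precision))
  expect_false(empty$precision_defined)
  expect_error(
    evaluate_recovery(reports, dplyr::bind_rows(truth, truth[1, ])),
    "duplicate"
  )
})

test_that("each decoy class fails at the gate it is named for", {
  cfg <- sim_config(n_planted = 0, n_decoys = 40, seed = 5)
  sim <- simulate_transcriptome(cfg)
  scr <- screen_transcriptome(sim$transcripts)
  audit <- merge(sim$decoys, scr$orfs, by = c("transcript_id", "protein"))
  expect_equal(nrow(audit), 40)   # every decoy ORF re-identified
  expect_equal(audit$outcome[audit$class == "no_signal"] |> unique(),
               "no_signal")
  expect_equal(audit$outcome[audit$class == "low_cationicity"] |> unique(),
               "window_filter")
  expect_equal(audit$outcome[audit$class == "no_dibasic"] |> unique(),
               "no_dibasic")
  expect_equal(
    audit$outcome[audit$class == "cationic_but_basic_tail"] |> unique(),
    "tail_not_anionic"
  )
})

test_that("generator configs round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(n_planted = 3, n_decoys = 6, seed = 11,
         subfamily_mix = list(A = 0.5, C = 0.5)),
    path, auto_unbox = TRUE, digits = NA
  )
  cfg <- read_sim_config(path)
  expect_equal(cfg$n_planted, 3)
  expect_equal(cfg$subfamily_mix, c(A = 0.5, C = 0.5))
  sim <- simulate_transcriptome(cfg)
  expect_equal(nrow(sim$transcripts), 9)
  expect_true(all(sim$truth$subfamily %in% c("A", "C")))
})
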