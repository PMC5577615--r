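test_that("empty input yields an empty, well-formed report", {
  scr <- screen_transcriptome(tibble::tibble(id = character(),
                                             sequence = character()))
  expect_s3_class(scr, "amp_screen")
  expect_equal(nrow(tidy(scr)), 0)
  expect_equal(glance(scr)$n_orfs, 0)
})

test_that("a planted precursor transcript survives every gate", {
  set.seed(101)
  plant <- simulate_precursor("A")
  cds <- lcamp:::reverse_translate(plant$precursor)
  transcript <- paste0("GGTAA", cds, "CCCGG")
  scr <- screen_transcriptome(tibble::tibble(id = "t1", sequence = transcript))
  cand <- tidy(scr)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$mature, plant$mature)
  expect_equal(cand$amidated, plant$amidated)
  expect_equal(cand$subfamily, "A")
  expect_equal(cand$signal_end, 23)
})

test_that("candidate flags recompute identically from the stored mature", {
  set.seed(103)
  sim <- simulate_transcriptome(sim_config(n_planted = 6, n_decoys = 0,
                                           seed = 103))
  scr <- screen_transcriptome(sim$transcripts)
  cand <- tidy(scr)
  expect_gt(nrow(cand), 0)
  for (i in seq_len(nrow(cand))) {
    comp <- composition(cand$mature[i])
    pi <- isoelectric_point(cand$mature[i], amidated = cand$amidated[i])
    expect_equal(cand$pi_gt_threshold[i], as.numeric(pi) > 11)
    expect_equal(cand$arg_gt_threshold[i], comp$fractions[["R"]] > 0.10)
    expect_equal(cand$length_in_range[i],
                 comp$length >= 23 && comp$length <= 42)
    expect_equal(cand$frac_r[i], comp$fractions[["R"]])
  }
})

test_that("every gated ORF is accounted for by exactly one outcome", {
  set.seed(107)
  sim <- simulate_transcriptome(sim_config(n_planted = 4, n_decoys = 16,
                                           seed = 107))
  scr <- screen_transcriptome(sim$transcripts)
  expect_true(all(scr$orfs$outcome %in% lcamp:::screen_stage_levels))
  g <- glance(scr)
  stage_cols <- paste0("n_", lcamp:::screen_stage_levels)
  expect_equal(sum(unlist(g[stage_cols])), g$n_orfs)
  expect_equal(g$n_candidate, nrow(tidy(scr)))
})

test_that("loosening a threshold never decreases the candidate count", {
  sim <- simulate_transcriptome(sim_config(n_planted = 8, n_decoys = 32,
                                           seed = 109))
  base <- nrow(tidy(screen_transcriptome(sim$transcripts)))
  looser <- list(
    filter_config(rp_fraction_threshold = 0.15),
    filter_config(window_pi_threshold = 6.0),
    filter_config(min_codons = 30),
    filter_config(max_codons = 200),
    filter_config(min_mature = 5)
  )
  for (cfg in looser) {
    expect_gte(nrow(tidy(screen_transcriptome(sim$transcripts, cfg))), base)
  }
})

test_that("either_R_or_P mode is stricter than the combined class", {
  # RPGG repeats: R and P are each ~25% per window but 50% combined
  region <- strrep("RPGG", 10)
  combined <- lcamp:::window_filter_pass(
    region, filter_config(window_pi_threshold = 14)
  )
  expect_true(combined$pass)
  either <- lcamp:::window_filter_pass(
    region, filter_config(filter_mode = "either_R_or_P",
                          window_pi_threshold = 14)
  )
  expect_false(either$pass)
})

test_that("the candidate report and run summary are written faithfully", {
  sim <- simulate_transcriptome(sim_config(n_planted = 3, n_decoys = 0,
                                           seed = 113))
  scr <- screen_transcriptome(sim$transcripts)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_candidate_report(scr, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(tidy(scr)))
  expect_true(all(c("mature", "subfamily", "pct_r") %in% names(back)))
  js <- withr::local_tempfile(fileext = ".json")
  write_run_summary(scr, js, seed = 113)
  summary <- jsonlite::read_json(js)
  expect_equal(summary$seed, 113)
  expect_equal(summary$n_candidates, nrow(tidy(scr)))
  expect_equal(summary$config$window, 15)
})
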