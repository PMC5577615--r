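test_that("hydrophilic proteins have no predicted signal peptide", {
  sp <- predict_signal_peptide(strrep("D", 40))
  expect_false(sp$present)
  expect_false(predict_signal_peptide("MKR")$present)  # too short
})

test_that("the consensus-like signal peptide cleaves at position 23", {
  protein <- paste0(consensus_signal_A(), "RPRIPRYPRWRPRIPRYPRW")
  sp <- predict_signal_peptide(protein)
  expect_true(sp$present)
  expect_equal(sp$cleavage_pos, 23)
  expect_equal(sp$source, "heuristic")
  expect_gte(sp$score, 1.5)
})

test_that("external overrides win over the heuristic", {
  ov <- tibble::tibble(protein_id = "p1", cleavage_pos = 19L)
  sp <- predict_signal_peptide(strrep("D", 40), id = "p1", overrides = ov)
  expect_true(sp$present)
  expect_equal(sp$cleavage_pos, 19)
  expect_equal(sp$source, "external")
})

test_that("dibasic motifs are found with overlaps, from a start index", {
  one <- find_dibasic_sites("AAAKRAAA")
  expect_equal(one$motif, "KR")
  expect_equal(one$start, 3L)
  rrr <- find_dibasic_sites("RRR")
  expect_equal(rrr$start, c(0L, 1L))
  expect_equal(rrr$motif, c("RR", "RR"))
  set.seed(9)
  p <- random_peptide(80)
  got <- find_dibasic_sites(p, search_from = 10)
  want <- oracle_dibasic(p, from = 10)
  expect_equal(got$motif, want$motif)
  expect_equal(got$start, want$start)
})

make_precursor <- function(core = strrep("RP", 15), tail = "DDEEDDEE") {
  paste0(consensus_signal_A(), core, "KR", tail)
}

test_that("a canonical precursor is decomposed into four tiling regions", {
  p <- make_precursor()
  sp <- predict_signal_peptide(p)
  ann <- annotate_precursor(p, sp, id = "synthetic1")
  expect_true(ann$accepted)
  r <- ann$regions
  expect_equal(r$signal_end, 23)
  expect_equal(r$core_end - r$core_start, 30)
  expect_equal(ann$site$motif, "KR")
  expect_lt(ann$tail_net_charge_ph7, 0)
  expect_equal(ann$tail_de_fraction, 1.0)
  # tiling: |signal| + |core| + 2 + |tail| == |precursor|
  expect_equal(r$signal_end + (r$core_end - r$core_start) + 2 +
                 (r$tail_end - r$tail_start), nchar(p))
})

test_that("rejections carry machine-readable reasons", {
  sp <- predict_signal_peptide(make_precursor())
  basic_tail <- annotate_precursor(make_precursor(tail = "KKKKKKKK"), sp)
  expect_false(basic_tail$accepted)
  expect_equal(basic_tail$reason, "tail_not_anionic")
  no_site <- annotate_precursor(
    paste0(consensus_signal_A(), strrep("RP", 15), "DDEEDDEE"), sp
  )
  expect_equal(no_site$reason, "no_dibasic")
  short_core <- annotate_precursor(
    paste0(consensus_signal_A(), "RPRPA", "KR", "DDEEDDEE"), sp
  )
  expect_equal(short_core$reason, "mature_too_short")
  expect_error(annotate_precursor("MAAA", list(present = FALSE)), "signal")
})

test_that("the first dibasic site with an anionic tail is selected", {
  p <- paste0(consensus_signal_A(), "RPRPRPRPRPRP", "KR", "RARARARARARA",
              "KR", "DDEED")
  sp <- predict_signal_peptide(p)
  ann <- annotate_precursor(p, sp)
  expect_true(ann$accepted)
  expect_equal(ann$site$start, 23 + 12 + 2 + 12)
  expect_equal(ann$tail, "DDEED")
})

test_that("maturation reproduces convertase/CPE/PAM outcomes", {
  # amidated outcome, as for the printed A-group peptides ending ...PTIYA-NH2
  core <- "YSWPRMPRIPRLPRYPRYPRYPRWPRWPRQPTIYAG"
  p <- paste0(consensus_signal_A(), core, "KR", "DDEEDDEEDD")
  ann <- annotate_precursor(p, predict_signal_peptide(p))
  m <- mature_from_annotation(ann)
  expect_equal(m$sequence, sub("G$", "", core))
  expect_true(m$amidated)
  expect_equal(m$trace,
               c("convertase_cut", "cpe_removed:R", "cpe_removed:K",
                 "pam_amidation"))
  # free-acid outcome: nothing to trim after the cut
  core2 <- "GRRGYRSWRRGVTIQESKSSTLNTED"
  p2 <- paste0(consensus_signal_A(), core2, "KR", "DDEEDDEEDD")
  ann2 <- annotate_precursor(p2, predict_signal_peptide(p2))
  m2 <- mature_from_annotation(ann2)
  expect_equal(m2$sequence, core2)
  expect_false(m2$amidated)
})

test_that("CPE iterates through mixed basic runs before PAM fires once", {
  res <- lcamp:::process_peptide("AAAGRKR", trace = "convertase_cut")
  expect_equal(res$sequence, "AAA")
  expect_true(res$amidated)
  expect_equal(res$trace, c("convertase_cut", "cpe_removed:R",
                            "cpe_removed:K", "cpe_removed:R",
                            "pam_amidation"))
  # a double glycine donates only one amide
  gg <- lcamp:::process_peptide("AAAGG")
  expect_equal(gg$sequence, "AAAG")
  expect_true(gg$amidated)
  expect_error(lcamp:::process_peptide("KR"), "empty")
})

test_that("maturation is idempotent and free acids never end in K/R/G", {
  set.seed(41)
  for (i in 1:30) {
    p <- paste0(random_peptide(20), random_peptide(5, c("K", "R", "G")))
    res <- tryCatch(lcamp:::process_peptide(p), error = function(e) NULL)
    if (is.null(res)) next
    last <- substr(res$sequence, nchar(res$sequence), nchar(res$sequence))
    if (!res$amidated) {
      # with a free carboxylate, CPE/PAM would still act on K/R/G
      expect_false(last %in% c("K", "R", "G"))
    }
    again <- lcamp:::process_peptide(res$sequence, amidated = res$amidated)
    expect_equal(again$sequence, res$sequence)
    expect_equal(again$amidated, res$amidated)
  }
})
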