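test_that("composition counts residues over the full length, X inert", {
  expect_equal(composition("RRRR")$fractions[["R"]], 1.0)
  comp <- composition("RXRX")
  expect_equal(comp$fractions[["R"]], 0.5)
  expect_equal(sum(comp$counts), comp$length)
  expect_error(composition(""), "empty")
  # fractions sum to 1 without X, below 1 with X
  set.seed(2)
  p <- random_peptide(40)
  expect_equal(sum(composition(p)$fractions), 1.0)
  expect_lt(sum(composition(paste0(p, "XX"))$fractions), 1.0)
})

test_that("printed mature peptides reproduce hand-counted compositions", {
  fa <- myticalin_functional()
  a5 <- fa$sequence[fa$id == "A5"]
  expect_equal(composition(a5)$fractions[["P"]], 10 / 35)
  expect_equal(pct_floor(composition(a5)$fractions[["P"]]), 28)
  a3 <- fa$sequence[fa$id == "A3"]
  expect_equal(composition(a3)$fractions[["R"]], 8 / 32)
})

test_that("glycine at the mean of terminal pKas is a neutral zwitterion", {
  pka <- pka_table()
  mid <- (pka$n_terminus + pka$c_terminus) / 2
  expect_lt(abs(net_charge("G", ph = mid)), 1e-9)
})

test_that("net charge matches a hand-summed Henderson-Hasselbalch evaluation", {
  # myticalin A3, amidated: 8 R, 1 K, 1 H, 5 Y, free N-terminus
  a3 <- "YGWPRMPRIPRKPRYPRYPRYPRWPRHPTIYA"
  hh_pos <- function(n, pka, ph) n / (1 + 10^(ph - pka))
  hh_neg <- function(n, pka, ph) n / (1 + 10^(pka - ph))
  manual <- hh_pos(1, 7.50, 7) + hh_pos(8, 12.00, 7) + hh_pos(1, 10.00, 7) +
    hh_pos(1, 5.98, 7) - hh_neg(5, 10.00, 7)
  expect_equal(net_charge(a3, ph = 7, amidated = TRUE), manual)
})

test_that("net charge decreases strictly in pH for ionizable peptides", {
  set.seed(17)
  for (i in 1:20) {
    p <- random_peptide(25)
    ph <- seq(0.5, 13.5, length.out = 40)
    z <- net_charge(p, ph)
    expect_true(all(diff(z) < 0))
  }
})

test_that("two-group peptides have the closed-form pI (pKa1 + pKa2) / 2", {
  synth <- pka_table(list(
    side_chain = c(D = 4.05, E = 4.45, H = 5.98, C = 9.0, Y = 10.0,
                   K = 10.0, R = 12.0),
    n_terminus = 9.0, c_terminus = 3.0, name = "synthetic"
  ))
  pi <- isoelectric_point("GGG", pka = synth)
  expect_equal(as.numeric(pi), 6.0, tolerance = 1e-5)
  expect_equal(attr(pi, "status"), "ok")
})

test_that("any defined pI zeroes the net charge", {
  set.seed(19)
  for (i in 1:20) {
    p <- random_peptide(15)
    pi <- isoelectric_point(p)
    if (attr(pi, "status") == "ok") {
      expect_lt(abs(net_charge(p, ph = as.numeric(pi))), 1e-3)
    }
  }
})

test_that("bisection agrees with a fine pH-grid scan", {
  set.seed(3)
  n_checked <- 0
  while (n_checked < 30) {
    p <- random_peptide(20)
    pi <- isoelectric_point(p)
    if (attr(pi, "status") != "ok") next
    expect_lt(abs(as.numeric(pi) - oracle_pi(p)), 0.01)
    n_checked <- n_checked + 1
  }
})

test_that("peptides with no acidic (or basic) group report sentinels", {
  expect_equal(as.numeric(isoelectric_point("KRKR", amidated = TRUE)), 14)
  expect_equal(attr(isoelectric_point("KRKR", amidated = TRUE), "status"),
               "always_positive")
  no_basic <- isoelectric_point("DEDE", include_termini = FALSE)
  expect_equal(as.numeric(no_basic), 0)
  expect_equal(attr(no_basic, "status"), "always_negative")
})

test_that("basic insertions and amidation never lower the pI", {
  set.seed(29)
  for (i in 1:15) {
    p <- random_peptide(20)
    base <- isoelectric_point(p)
    if (attr(base, "status") != "ok") next
    with_r <- isoelectric_point(paste0(p, "R"))
    expect_gte(as.numeric(with_r) + 1e-6, as.numeric(base))
    amid <- isoelectric_point(p, amidated = TRUE)
    expect_gte(as.numeric(amid) + 1e-6, as.numeric(base))
  }
})

test_that("window scans reduce to brute-force window maxima", {
  expect_equal(window_scan("RPRPRPRPRPRPRPR", 15)$max_value, 1.0)
  short <- window_scan("RPA", 15)
  expect_equal(short$max_value, 2 / 3)     # degenerate window = whole sequence
  expect_length(short$values, 1)
  set.seed(5)
  p <- random_peptide(60)
  scan <- window_scan(p, 15)
  brute <- vapply(1:46, function(s) {
    w <- substr(p, s, s + 14)
    (nchar(w) - nchar(gsub("[RP]", "", w))) / 15
  }, numeric(1))
  expect_equal(scan$values, brute)
  expect_equal(scan$max_value, max(brute))
  # full-length window equals the global statistic
  full <- window_scan(p, nchar(p))
  comp <- composition(p)
  expect_equal(full$max_value, comp$fractions[["R"]] + comp$fractions[["P"]])
})

test_that("window pI uses side chains only and scores sentinels", {
  scan <- window_scan("KRKRKRKRKR", 5, "side_chain_pi")
  expect_equal(scan$max_value, 14)         # no acidic side chain in any window
  neutral <- window_scan("GGGGG", 5, "side_chain_pi")
  expect_equal(neutral$max_value, 7)       # nothing ionizable at all
  mixed <- window_scan("DDDDD", 5, "side_chain_pi")
  expect_equal(mixed$max_value, 0)
})

test_that("characterize_peptides reports the discovery profile per row", {
  fa <- myticalin_functional()
  ch <- characterize_peptides(fa)
  expect_equal(nrow(ch), 4)
  expect_equal(ch$length, c(32, 35, 35, 35))
  expect_true(all(ch$pi > 11))
  expect_true(all(ch$frac_r > 0.10))
  expect_true(all(ch$net_charge_ph7 > 0))
  expect_equal(ch$amidated, c(TRUE, TRUE, TRUE, FALSE))
})
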