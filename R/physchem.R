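AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

check_protein_letters <- function(p, allow_stop = FALSE) {
  allowed <- c(AA20, "X", if (allow_stop) "*")
  letters <- strsplit(p, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(letters), allowed)
  if (length(bad) > 0) {
    abort(paste0("unexpected residue letter(s): ", paste(bad, collapse = ", ")))
  }
  letters
}

#' Amino-acid composition of a peptide
#'
#' Counts every residue of a peptide and reports per-residue fractions over
#' the full sequence length. The placeholder `X` (unknown residue, e.g. from
#' an `N`-containing codon) contributes to the length but to no named
#' residue's count, so fractions are conservative in its presence.
#'
#' @param p Amino-acid string over the 20 standard letters plus `X`.
#' @return A `composition_profile`: list with `counts` (named integer vector
#'   over the 20 residues plus `X`), `length`, and `fractions`
#'   (`counts / length` for the 20 standard residues).
#' @examples
#' composition("RRRR")$fractions[["R"]]
#' @export
composition <- function(p) {
  stopifnot(is.character(p), length(p) == 1)
  if (nchar(p) == 0) {
    abort("cannot compute composition of an empty sequence")
  }
  letters <- check_protein_letters(p)
  counts <- table(factor(letters, levels = c(AA20, "X")))
  counts <- setNames(as.integer(counts), names(counts))
  structure(
    list(counts = counts,
         length = length(letters),
         fractions = counts[AA20] / length(letters)),
    class = "composition_profile"
  )
}

#' @export
print.composition_profile <- function(x, ...) {
  cat("<composition_profile> length", x$length, "\n")
  nz <- x$fractions[x$fractions > 0]
  cat(" ", paste(names(nz), sprintf("%.3f", nz), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Truncate a fraction to a percentage
#'
#' Converts a fraction to a percent value truncated (floored) towards zero
#' at the requested number of decimal digits, matching the convention used
#' in the package's reports (10/35 -> 28 at zero digits).
#'
#' @param x Numeric fraction(s) in `[0, 1]`.
#' @param digits Decimal digits to keep (default 0).
#' @return Numeric percentage(s).
#' @export
pct_floor <- function(x, digits = 0) {
  floor(x * 100 * 10^digits) / 10^digits
}

count_ionizable <- function(letters, amidated, include_termini) {
  c(
    K = sum(letters == "K"), R = sum(letters == "R"), H = sum(letters == "H"),
    D = sum(letters == "D"), E = sum(letters == "E"),
    C = sum(letters == "C"), Y = sum(letters == "Y"),
    n_term = as.integer(include_termini),
    c_term = as.integer(include_termini && !amidated)
  )
}

charge_from_counts <- function(counts, ph, pka) {
  basic_pka <- c(pka$n_terminus, pka$side_chain[c("K", "R", "H")])
  basic_n <- counts[c("n_term", "K", "R", "H")]
  acidic_pka <- c(pka$c_terminus, pka$side_chain[c("D", "E", "C", "Y")])
  acidic_n <- counts[c("c_term", "D", "E", "C", "Y")]
  vapply(ph, function(x) {
    pos <- sum(basic_n / (1 + 10^(x - basic_pka)))
    neg <- sum(acidic_n / (1 + 10^(acidic_pka - x)))
    pos - neg
  }, numeric(1))
}

#' Henderson-Hasselbalch net charge of a peptide
#'
#' Sums the fractional protonation of every ionizable group: each basic
#' group (N-terminus, K, R, H) contributes `1 / (1 + 10^(pH - pKa))` and
#' each acidic group (C-terminus, D, E, C, Y) contributes
#' `-1 / (1 + 10^(pKa - pH))`. A C-terminally amidated peptide has no free
#' C-terminal carboxylate, so `amidated = TRUE` removes that acidic group.
#'
#' @param p Amino-acid string (20 standard letters plus `X`; `X` is inert).
#' @param ph pH value(s) in `[0, 14]`; vectorized.
#' @param amidated Is the C-terminus amidated?
#' @param include_termini Include the terminal groups? Set `FALSE` for
#'   internal fragments such as sliding windows.
#' @param pka A [pka_table()] (or the name of a built-in table).
#' @return Net charge, one value per element of `ph`.
#' @examples
#' net_charge("GRRRRYRYWRRGYRSWRRGVTIQERSKSSTLNTED", ph = 7)
#' @export
net_charge <- function(p, ph = 7, amidated = FALSE, include_termini = TRUE,
                       pka = pka_table()) {
  stopifnot(all(ph >= 0), all(ph <= 14))
  pka <- pka_table(pka)
  letters <- check_protein_letters(p)
  counts <- count_ionizable(letters, amidated, include_termini)
  charge_from_counts(counts, ph, pka)
}

#' Isoelectric point by bisection
#'
#' Finds the pH at which [net_charge()] is zero. The net charge is strictly
#' decreasing in pH, so bisection over `[0, 14]` converges; iteration stops
#' when the bracket is narrower than 1e-6 pH units, well inside the 0.001
#' resolution the result is reported at, and the returned pH satisfies
#' `|net charge| < 1e-3`.
#'
#' A peptide with no acidic group under the chosen settings (for example an
#' amidated peptide free of D/E/C/Y with termini excluded) is positive at
#' every pH; its pI is undefined and the sentinel 14 is returned with
#' attribute `status = "always_positive"`. Symmetrically, no basic group
#' returns 0 with `status = "always_negative"`. A defined pI carries
#' `status = "ok"`.
#'
#' @inheritParams net_charge
#' @return The pI as a double with a `status` attribute.
#' @examples
#' isoelectric_point("YGWPRMPRIPRKPRYPRYPRYPRWPRHPTIYA", amidated = TRUE)
#' @export
isoelectric_point <- function(p, amidated = FALSE, include_termini = TRUE,
                              pka = pka_table()) {
  pka <- pka_table(pka)
  letters <- check_protein_letters(p)
  counts <- count_ionizable(letters, amidated, include_termini)
  n_basic <- sum(counts[c("n_term", "K", "R", "H")])
  n_acidic <- sum(counts[c("c_term", "D", "E", "C", "Y")])
  if (n_acidic == 0 && n_basic == 0) {
    return(structure(NA_real_, status = "no_ionizable_groups"))
  }
  if (n_acidic == 0) {
    return(structure(14, status = "always_positive"))
  }
  if (n_basic == 0) {
    return(structure(0, status = "always_negative"))
  }
  lo <- 0
  hi <- 14
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (charge_from_counts(counts, mid, pka) > 0) lo <- mid else hi <- mid
  }
  structure((lo + hi) / 2, status = "ok")
}

#' Sliding-window statistics along a peptide
#'
#' Slides a fixed-length window along a peptide and evaluates one of two
#' statistics per window:
#'
#' * `"class_fraction"` — the summed fraction of a residue class (default
#'   `{R, P}`, the arginine/proline cationicity filter).
#' * `"side_chain_pi"` — the isoelectric point of the window computed from
#'   side chains only (`include_termini = FALSE`), because a window is an
#'   internal fragment, not a free peptide. Windows whose pI is undefined
#'   score a sentinel: 14 when always positive, 0 when always negative,
#'   7 (neutral) when the window has no ionizable side chain at all.
#'
#' A sequence shorter than the window yields a single window spanning the
#' whole sequence.
#'
#' @param p Amino-acid string.
#' @param window Window length in residues (>= 1).
#' @param statistic `"class_fraction"` or `"side_chain_pi"`.
#' @param residues Residue class for `"class_fraction"`.
#' @param pka [pka_table()] used by `"side_chain_pi"`.
#' @return A `window_scan` object: list with `window`, `statistic`, `values`
#'   (one per window start), `max_value` and `argmax_start` (1-based start
#'   of the best-scoring window). `tidy()` returns the per-window table.
#' @examples
#' window_scan("RPRPRPRPRPRPRPR", window = 15)$max_value
#' @export
window_scan <- function(p, window, statistic = c("class_fraction", "side_chain_pi"),
                        residues = c("R", "P"), pka = pka_table()) {
  statistic <- match.arg(statistic)
  stopifnot(window >= 1)
  if (nchar(p) == 0) {
    abort("cannot scan an empty sequence")
  }
  letters <- check_protein_letters(p)
  len <- length(letters)
  w <- min(window, len)
  starts <- seq_len(max(1, len - w + 1))
  values <- if (statistic == "class_fraction") {
    in_class <- as.numeric(letters %in% residues)
    cs <- c(0, cumsum(in_class))
    (cs[starts + w] - cs[starts]) / w
  } else {
    pka <- pka_table(pka)
    vapply(starts, function(s) {
      sub <- substr(p, s, s + w - 1)
      pi <- isoelectric_point(sub, include_termini = FALSE, pka = pka)
      # windows with no ionizable side chain are neutral, not cationic
      if (identical(attr(pi, "status"), "no_ionizable_groups")) 7 else
        as.numeric(pi)
    }, numeric(1))
  }
  structure(
    list(window = w, statistic = statistic,
         residues = if (statistic == "class_fraction") residues else NULL,
         values = values,
         max_value = max(values),
         argmax_start = starts[which.max(values)]),
    class = "window_scan"
  )
}

#' @export
print.window_scan <- function(x, ...) {
  cat("<window_scan> window", x$window, "statistic", x$statistic, "\n")
  cat("  windows:", length(x$values),
      " max:", format(x$max_value),
      " at start:", x$argmax_start, "\n")
  invisible(x)
}

#' @rdname window_scan
#' @param x A `window_scan`.
#' @param ... Unused.
#' @method tidy window_scan
#' @export
tidy.window_scan <- function(x, ...) {
  tibble(start = seq_along(x$values), value = x$values)
}

#' Physicochemical profile of a peptide table
#'
#' Computes, for every peptide in a table, the quantities the discovery
#' pipeline reports: length, isoelectric point (termini included, honoring
#' the amidation flag), net charge at pH 7, and the composition fractions
#' relevant to subfamily classification.
#'
#' @param peptides A data frame with columns `id`, `sequence` and optionally
#'   `amidated` (defaults to `FALSE`), e.g. from [read_fasta()] in protein
#'   mode.
#' @param pka A [pka_table()].
#' @return A tibble with columns `id`, `length`, `pi`, `pi_status`,
#'   `net_charge_ph7`, `frac_r`, `frac_p`, `frac_y`, `frac_w`, `frac_t`,
#'   `frac_de`, `amidated`.
#' @examples
#' tbl <- tibble::tibble(id = "A3",
#'   sequence = "YGWPRMPRIPRKPRYPRYPRYPRWPRHPTIYA", amidated = TRUE)
#' characterize_peptides(tbl)
#' @export
characterize_peptides <- function(peptides, pka = pka_table()) {
  pka <- pka_table(pka)
  stopifnot(all(c("id", "sequence") %in% names(peptides)))
  peptides <- as_tibble(peptides)
  if (!"amidated" %in% names(peptides)) {
    peptides$amidated <- FALSE
  }
  purrr::pmap_dfr(
    peptides[, c("id", "sequence", "amidated")],
    function(id, sequence, amidated) {
      comp <- composition(sequence)
      pi_obj <- isoelectric_point(sequence, amidated = amidated, pka = pka)
      tibble(
        id = id,
        length = comp$length,
        pi = as.numeric(pi_obj),
        pi_status = attr(pi_obj, "status"),
        net_charge_ph7 = net_charge(sequence, ph = 7, amidated = amidated,
                                    pka = pka),
        frac_r = comp$fractions[["R"]],
        frac_p = comp$fractions[["P"]],
        frac_y = comp$fractions[["Y"]],
        frac_w = comp$fractions[["W"]],
        frac_t = comp$fractions[["T"]],
        frac_de = comp$fractions[["D"]] + comp$fractions[["E"]],
        amidated = amidated
      )
    }
  )
}
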