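KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0
)

#' Predict a secretory signal peptide and its cleavage position
#'
#' A deliberately transparent stand-in for a full signal-peptide predictor,
#' built from the two classical determinants of cleaved signal sequences:
#'
#' 1. an N-terminal methionine followed by a hydrophobic core — some
#'    8-residue window starting at 0-based positions 2-20 with mean
#'    Kyte-Doolittle hydropathy >= 1.5;
#' 2. a von Heijne-style (-3, -1) cleavage site — scanning candidate signal
#'    lengths 15-30, the smallest length whose -1 residue (last of the
#'    signal) is small (`A/G/S`) and whose -3 residue is small or aliphatic
#'    (`A/G/S/T/V/C/I/L`).
#'
#' Predictions from an external tool can be injected through `overrides`
#' (see [read_signal_overrides()]); an override always wins and is reported
#' with `source = "external"`.
#'
#' @param p Protein sequence starting at its initiator residue.
#' @param id Optional protein id used to look up `overrides`.
#' @param overrides Optional named vector or data frame
#'   (`protein_id`, `cleavage_pos`) of externally computed signal lengths
#'   (number of signal residues, so the mature region starts at that 0-based
#'   index).
#' @return A list with `present`, `cleavage_pos` (number of signal residues;
#'   `NA` when absent), `score` (best hydrophobic-window mean hydropathy)
#'   and `source` (`"heuristic"` or `"external"`).
#' @examples
#' predict_signal_peptide(paste0("MKGAALLLLTIAAALCMIAECEG", "RPRIPRYPRYPRW"))
#' @export
predict_signal_peptide <- function(p, id = NULL, overrides = NULL) {
  if (!is.null(overrides) && !is.null(id)) {
    ov <- as_override_map(overrides)
    if (id %in% names(ov)) {
      return(list(present = TRUE, cleavage_pos = unname(ov[[id]]),
                  score = NA_real_, source = "external"))
    }
  }
  letters <- check_protein_letters(p)
  len <- length(letters)
  absent <- list(present = FALSE, cleavage_pos = NA_integer_,
                 score = NA_real_, source = "heuristic")
  if (len < 18) {
    return(absent)
  }
  if (letters[1] != "M") {
    return(absent)
  }
  kd <- KYTE_DOOLITTLE[letters]
  starts <- 3:min(21, len - 7)               # 0-based 2..20
  if (length(starts) == 0 || starts[1] > min(21, len - 7)) {
    return(absent)
  }
  window_means <- vapply(starts, function(s) mean(kd[s:(s + 7)]), numeric(1))
  score <- max(window_means)
  if (score < 1.5) {
    return(absent)
  }
  minus1 <- c("A", "G", "S")
  minus3 <- c("A", "G", "S", "T", "V", "C", "I", "L")
  for (pos in 15:30) {
    if (pos >= len) break                     # at least one mature residue
    if (letters[pos] %in% minus1 && letters[pos - 2] %in% minus3) {
      return(list(present = TRUE, cleavage_pos = pos, score = score,
                  source = "heuristic"))
    }
  }
  absent
}

as_override_map <- function(overrides) {
  if (is.data.frame(overrides)) {
    setNames(as.integer(overrides$cleavage_pos), overrides$protein_id)
  } else {
    overrides
  }
}

#' Read externally computed signal-peptide cleavage positions
#'
#' Reads a TSV with columns `protein_id` and `cleavage_pos` (the number of
#' signal residues, i.e. a 0-based index where the mature region starts),
#' such as positions exported from a dedicated signal-peptide predictor.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `protein_id`, `cleavage_pos`.
#' @export
read_signal_overrides <- function(path) {
  ov <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("protein_id", "cleavage_pos") %in% names(ov)))
  ov
}
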