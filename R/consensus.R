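#' 50% majority-rule consensus of an alignment
#'
#' Builds the per-column majority consensus of a set of equal-length aligned
#' sequences (gaps as `-`). In each column the most frequent symbol wins,
#' ties broken alphabetically (gap first); a winning gap at >= 50% support
#' drops the column, a winning residue at >= 50% support is emitted, and a
#' column whose winner falls below 50% support is masked as `X`.
#'
#' @param aligned Character vector of >= 2 aligned sequences of equal
#'   length, or a data frame with a `sequence` column.
#' @return A `consensus_result`: list with `consensus` (string over residues
#'   and `X`), `column_support` (winning fraction per kept column),
#'   `n_sequences`, and `dropped_columns` (1-based alignment columns removed
#'   as gap-majority). `tidy()` returns the per-column table over all
#'   alignment columns.
#' @examples
#' majority_consensus(c("MKTA", "MKTA", "MKSA", "MRSA"))$consensus
#' @export
majority_consensus <- function(aligned) {
  if (is.data.frame(aligned)) {
    aligned <- aligned$sequence
  }
  if (length(aligned) < 2) {
    abort("consensus requires at least 2 sequences")
  }
  lens <- nchar(aligned)
  if (length(unique(lens)) != 1) {
    abort("aligned sequences must have equal lengths")
  }
  mat <- do.call(rbind, strsplit(toupper(aligned), "", fixed = TRUE))
  bad <- setdiff(unique(as.vector(mat)), c(AA20, "X", "-"))
  if (length(bad) > 0) {
    abort(paste0("unexpected alignment symbol(s): ", paste(bad, collapse = ", ")))
  }
  n <- nrow(mat)
  cols <- purrr::map_dfr(seq_len(ncol(mat)), function(j) {
    counts <- table(mat[, j])
    counts <- counts[order(-as.integer(counts), names(counts), method = "radix")]
    winner <- names(counts)[1]
    support <- as.numeric(counts[1]) / n
    tibble(
      column = j, winner = winner, support = support,
      symbol = if (winner == "-" && support >= 0.5) NA_character_
               else if (support >= 0.5) winner else "X"
    )
  })
  kept <- cols[!is.na(cols$symbol), ]
  structure(
    list(consensus = paste(kept$symbol, collapse = ""),
         column_support = kept$support,
         n_sequences = n,
         dropped_columns = cols$column[is.na(cols$symbol)],
         columns = cols),
    class = "consensus_result"
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result> n =", x$n_sequences, "\n")
  cat(" ", x$consensus, "\n")
  invisible(x)
}

#' @rdname majority_consensus
#' @param x A `consensus_result`.
#' @param ... Unused.
#' @method tidy consensus_result
#' @export
tidy.consensus_result <- function(x, ...) {
  x$columns
}
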