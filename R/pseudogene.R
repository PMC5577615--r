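#' Screen virtual peptides for pseudogenizing stop codons
#'
#' A gene copy whose conceptual translation carries an internal stop (`*`)
#' cannot produce the full precursor and is called a pseudogene. Stops at
#' the final position (the normal terminator) do not count.
#'
#' @param proteins Data frame with `id` and `sequence` columns (stops
#'   allowed), or a character vector of sequences.
#' @return A tibble with `id`, `internal_stop_count` and `verdict`
#'   (`"pseudogene"` when at least one internal stop, else `"functional"`).
#' @examples
#' screen_pseudogenes(c(dpg1 = "WGRRWRV*IPSPPRIRPWPP*TWPRPKWPRSATINID"))
#' @export
screen_pseudogenes <- function(proteins) {
  if (is.character(proteins)) {
    ids <- names(proteins) %||% paste0("seq", seq_along(proteins))
    proteins <- tibble(id = ids, sequence = unname(proteins))
  }
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  counts <- vapply(proteins$sequence, function(s) {
    letters <- check_protein_letters(s, allow_stop = TRUE)
    sum(letters[-length(letters)] == "*")
  }, integer(1), USE.NAMES = FALSE)
  tibble(
    id = proteins$id,
    internal_stop_count = counts,
    verdict = ifelse(counts >= 1, "pseudogene", "functional")
  )
}
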