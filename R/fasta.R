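#' Read a FASTA file into a tibble
#'
#' Parses nucleotide or protein FASTA (wrapped lines are joined, lowercase
#' is uppercased). In nucleotide mode, `U` is mapped to `T` with a warning
#' and any letter outside `A/C/G/T/N/U` is an error. In protein mode a
#' trailing `-NH2` marker on a sequence denotes C-terminal amidation; it is
#' stripped from the sequence and recorded in the `amidated` column. Stop
#' characters (`*`) are accepted in protein mode so that virtual peptides of
#' candidate pseudogenes can be screened.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return A tibble with columns `id`, `description`, `sequence` and, in
#'   protein mode, `amidated`.
#' @examples
#' fa <- system.file("extdata", "myticalin_mature_peptides.fasta", package = "lcamp")
#' read_fasta(fa, "protein")
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    abort(paste0("no FASTA records in ", path))
  }
  headers <- names(set)
  if (any(!nzchar(trimws(headers)))) {
    abort("FASTA record with an empty header")
  }
  id <- sub("\\s.*$", "", trimws(headers))
  description <- ifelse(grepl("\\s", trimws(headers)),
                        sub("^\\S+\\s+", "", trimws(headers)), "")
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    abort(paste0("duplicate FASTA id(s): ", paste(dup, collapse = ", ")))
  }
  sequence <- unname(toupper(gsub("[[:space:]]", "", as.character(set))))
  out <- tibble(id = id, description = description, sequence = sequence)
  if (alphabet == "nucleotide") {
    if (any(grepl("U", out$sequence, fixed = TRUE))) {
      warn("RNA letters (U) found; mapping U -> T")
      out$sequence <- gsub("U", "T", out$sequence, fixed = TRUE)
    }
    bad <- grepl("[^ACGTN]", out$sequence)
    if (any(bad)) {
      abort(paste0("non-nucleotide letters in record(s): ",
                   paste(out$id[bad], collapse = ", ")))
    }
  } else {
    out$amidated <- grepl("-NH2$", out$sequence)
    out$sequence <- sub("-NH2$", "", out$sequence)
    bad_letters <- gsub(paste0("[", paste(AA20, collapse = ""), "X*]"), "",
                        out$sequence)
    if (any(nzchar(bad_letters))) {
      abort(paste0("non-protein letters in record(s): ",
                   paste(out$id[nzchar(bad_letters)], collapse = ", ")))
    }
  }
  if (any(!nzchar(out$sequence))) {
    abort("FASTA record with an empty sequence")
  }
  out
}

#' Write a tibble of sequences to FASTA
#'
#' The inverse of [read_fasta()]: writes `id`, `description` and `sequence`
#' columns as FASTA, re-attaching a `-NH2` marker for rows whose `amidated`
#' column is `TRUE`.
#'
#' @param x Data frame with `id` and `sequence` (optionally `description`,
#'   `amidated`).
#' @param path Output file path.
#' @param wrap Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, wrap = 60) {
  stopifnot(all(c("id", "sequence") %in% names(x)))
  desc <- if ("description" %in% names(x)) x$description else ""
  seqs <- x$sequence
  if ("amidated" %in% names(x)) {
    seqs <- ifelse(x$amidated, paste0(seqs, "-NH2"), seqs)
  }
  header <- ifelse(nzchar(desc), paste(x$id, desc), x$id)
  lines <- unlist(purrr::map2(header, seqs, function(h, s) {
    starts <- seq(1, nchar(s), by = wrap)
    c(paste0(">", h), substring(s, starts, pmin(starts + wrap - 1, nchar(s))))
  }))
  writeLines(lines, path)
  invisible(path)
}
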