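#' Translate a nucleotide sequence with the standard genetic code
#'
#' Translates codon by codon using the standard (NCBI table 1) genetic code.
#' Stop codons render `*`; any codon containing `N` renders `X` (ambiguous
#' codons are never resolved, even when all completions agree).
#'
#' @param codons Nucleotide string over `A/C/G/T/N`, length divisible by 3.
#' @return Amino-acid string of `nchar(codons) / 3` letters.
#' @examples
#' translate_dna("ATGAAATAA")
#' @export
translate_dna <- function(codons) {
  stopifnot(is.character(codons), length(codons) == 1)
  n <- nchar(codons)
  if (n %% 3 != 0) {
    abort("sequence length must be divisible by 3")
  }
  if (n == 0) {
    return("")
  }
  if (grepl("[^ACGTN]", codons)) {
    abort("translate_dna requires letters in {A, C, G, T, N}")
  }
  triplets <- substring(codons, seq(1, n, by = 3), seq(3, n, by = 3))
  aa <- unname(Biostrings::GENETIC_CODE[triplets])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

reverse_complement <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(x, function(s) {
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
         }, character(1), USE.NAMES = FALSE))
}

# ORFs on one strand of one sequence; coordinates local to that strand.
scan_strand_orfs <- function(seq, require_stop) {
  n <- nchar(seq)
  out <- list()
  for (frame in 0:2) {
    usable <- n - frame
    n_codons <- usable %/% 3
    if (n_codons < 1) next
    prot <- translate_dna(substr(seq, frame + 1, frame + 3 * n_codons))
    aa <- strsplit(prot, "", fixed = TRUE)[[1]]
    stops <- which(aa == "*")
    seg_start <- 1
    bounds <- c(stops, if (length(stops) == 0 || max(stops) < n_codons) n_codons + 1)
    for (b in bounds) {
      terminal_stop <- b <= n_codons
      seg <- if (seg_start <= b - 1) seg_start:(b - 1) else integer(0)
      seg_start <- b + 1
      if (length(seg) == 0) next
      m <- seg[which(aa[seg] == "M")[1]]
      if (is.na(m)) next
      if (!terminal_stop && require_stop) next
      protein <- paste(aa[m:(b - 1)], collapse = "")
      out[[length(out) + 1]] <- list(
        frame = frame,
        local_start = frame + (m - 1) * 3,          # 0-based on this strand
        local_end = frame + (b - 1) * 3 + if (terminal_stop) 3 else 0,
        protein = protein,
        codon_length = b - 1 - m + 1,
        has_stop_codon = terminal_stop
      )
    }
  }
  out
}

#' Extract open reading frames from transcripts
#'
#' Scans all six frames (both strands) of each transcript. An ORF starts at
#' an `ATG` and runs to the first in-frame stop; nested downstream `ATG`s
#' within the same stop segment are not reported separately (longest-per-stop
#' convention). ORFs that run off the transcript end without a stop are kept
#' unless `require_stop = TRUE` (assembled contigs are often 3'-incomplete).
#' Only ORFs strictly longer than `min_codons` and strictly shorter than
#' `max_codons` (codons counted as amino acids, excluding the stop) are
#' returned.
#'
#' Coordinates are 0-based half-open on the forward strand of the
#' transcript; when a terminal stop is present, `end` includes its codon.
#' Frames are numbered 0-2 as the offset on the strand the ORF was read
#' from.
#'
#' @param transcripts A data frame with columns `id` and `sequence`
#'   (nucleotide), e.g. from [read_fasta()], or a single nucleotide string.
#' @param min_codons,max_codons Strict length bounds in codons; the default
#'   (50, 120) targets precursor-sized products, keeping 51-119-codon ORFs.
#' @param require_stop Drop ORFs lacking a terminal stop codon?
#' @return A tibble with columns `transcript_id`, `strand`, `frame`,
#'   `start`, `end`, `codon_length`, `has_stop_codon`, `protein`, sorted by
#'   `(transcript_id, start, strand)`.
#' @examples
#' extract_orfs("ATGAAATAA", min_codons = 1, max_codons = 10)
#' @export
extract_orfs <- function(transcripts, min_codons = 50, max_codons = 120,
                         require_stop = FALSE) {
  stopifnot(min_codons >= 1, max_codons > min_codons)
  if (is.character(transcripts)) {
    transcripts <- tibble(id = paste0("seq", seq_along(transcripts)),
                          sequence = transcripts)
  }
  stopifnot(all(c("id", "sequence") %in% names(transcripts)))
  empty <- tibble(
    transcript_id = character(), strand = character(), frame = integer(),
    start = integer(), end = integer(), codon_length = integer(),
    has_stop_codon = logical(), protein = character()
  )
  rows <- purrr::map2_dfr(transcripts$id, transcripts$sequence, function(id, seq) {
    n <- nchar(seq)
    fwd <- scan_strand_orfs(seq, require_stop)
    rev <- scan_strand_orfs(reverse_complement(seq), require_stop)
    mk <- function(orf, strand) {
      tibble(
        transcript_id = id, strand = strand, frame = orf$frame,
        start = if (strand == "+") orf$local_start else n - orf$local_end,
        end = if (strand == "+") orf$local_end else n - orf$local_start,
        codon_length = orf$codon_length,
        has_stop_codon = orf$has_stop_codon,
        protein = orf$protein
      )
    }
    bind_rows(purrr::map_dfr(fwd, mk, strand = "+"),
              purrr::map_dfr(rev, mk, strand = "-"))
  })
  if (nrow(rows) == 0) {
    return(empty)
  }
  rows |>
    filter(.data$codon_length > min_codons, .data$codon_length < max_codons) |>
    arrange(.data$transcript_id, .data$start, .data$strand)
}

#' Write an ORF table as TSV
#'
#' @param orfs Tibble from [extract_orfs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orf_report <- function(orfs, path) {
  readr::write_tsv(orfs, path)
  invisible(path)
}
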