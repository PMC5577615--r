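#' Locate dibasic convertase cleavage motifs
#'
#' Finds every occurrence of the four dibasic pairs (`KR`, `RR`, `RK`, `KK`)
#' recognized by proprotein convertases, including overlapping occurrences
#' (`RRR` reports sites at both offsets).
#'
#' @param p Protein sequence.
#' @param search_from 0-based index at which the search starts (e.g. the
#'   signal cleavage position).
#' @return A tibble with columns `motif`, `start` (0-based index of the
#'   first basic residue) and `tail_start` (index just after the motif),
#'   in order of `start`.
#' @examples
#' find_dibasic_sites("AAAKRAAA")
#' @export
find_dibasic_sites <- function(p, search_from = 0) {
  letters <- check_protein_letters(p)
  len <- length(letters)
  stopifnot(search_from < len)
  first <- which(letters %in% c("K", "R"))
  first <- first[first >= search_from + 1 & first < len]
  first <- first[letters[first + 1] %in% c("K", "R")]
  tibble(
    motif = paste0(letters[first], letters[first + 1]),
    start = as.integer(first - 1),
    tail_start = as.integer(first + 1)
  )
}

#' Annotate the four-region precursor architecture
#'
#' Decomposes a candidate precursor into signal peptide, mature core,
#' dibasic convertase site and C-terminal propeptide tail. Among dibasic
#' sites downstream of the signal whose mature core is at least
#' `min_mature` residues and whose tail is at least `min_tail` residues,
#' the first site whose tail carries a negative side-chain net charge at
#' pH 7 (the anionic propeptide signature) is selected.
#'
#' All region coordinates are 0-based half-open on the precursor.
#'
#' @param p Protein sequence (the precursor).
#' @param signal A signal prediction from [predict_signal_peptide()] with
#'   `present = TRUE`.
#' @param id Protein id carried into the annotation.
#' @param min_mature Minimum mature-core length (residues).
#' @param min_tail Minimum tail length (residues).
#' @param pka [pka_table()] used for the tail-charge test.
#' @return A `precursor_annotation` object. `$accepted` indicates success;
#'   on rejection, `$reason` is one of `"no_dibasic"`, `"mature_too_short"`
#'   (no site leaves both a long-enough core and tail) or
#'   `"tail_not_anionic"`.
#' @export
annotate_precursor <- function(p, signal, id = NA_character_,
                               min_mature = 10, min_tail = 5,
                               pka = pka_table()) {
  if (!isTRUE(signal$present)) {
    abort("annotate_precursor requires a present signal peptide")
  }
  pka <- pka_table(pka)
  len <- nchar(p)
  cut <- signal$cleavage_pos
  reject <- function(reason) {
    structure(list(protein_id = id, protein = p, signal = signal,
                   accepted = FALSE, reason = reason),
              class = "precursor_annotation")
  }
  sites <- find_dibasic_sites(p, search_from = cut)
  if (nrow(sites) == 0) {
    return(reject("no_dibasic"))
  }
  core_len <- sites$start - cut
  tail_len <- len - sites$tail_start
  geom_ok <- core_len >= min_mature & tail_len >= min_tail
  if (!any(geom_ok)) {
    return(reject("mature_too_short"))
  }
  for (i in which(geom_ok)) {
    tail <- substr(p, sites$tail_start[i] + 1, len)
    q <- net_charge(tail, ph = 7, include_termini = FALSE, pka = pka)
    if (q < 0) {
      tail_comp <- composition(tail)
      ann <- list(
        protein_id = id, protein = p, signal = signal, accepted = TRUE,
        site = as.list(sites[i, ]),
        regions = list(signal_end = cut,
                       core_start = cut, core_end = sites$start[i],
                       tail_start = sites$tail_start[i], tail_end = len),
        core = substr(p, cut + 1, sites$start[i]),
        tail = tail,
        tail_net_charge_ph7 = q,
        tail_de_fraction = tail_comp$fractions[["D"]] + tail_comp$fractions[["E"]]
      )
      return(structure(ann, class = "precursor_annotation"))
    }
  }
  reject("tail_not_anionic")
}

#' @export
print.precursor_annotation <- function(x, ...) {
  if (!x$accepted) {
    cat("<precursor_annotation> rejected:", x$reason, "\n")
    return(invisible(x))
  }
  r <- x$regions
  cat("<precursor_annotation>", x$protein_id %||% "", "\n")
  cat("  signal [0,", r$signal_end, ") core [", r$core_start, ",",
      r$core_end, ") site", x$site$motif, "tail [", r$tail_start, ",",
      r$tail_end, ")\n")
  cat("  tail net charge pH 7:", format(x$tail_net_charge_ph7),
      " D+E fraction:", format(x$tail_de_fraction), "\n")
  invisible(x)
}

process_peptide <- function(peptide, trace = character(), amidated = FALSE) {
  # an amidated C-terminus has no free carboxylate: neither CPE nor PAM
  # can act, so an already-amidated peptide is a fixed point
  if (amidated) {
    return(list(sequence = peptide, amidated = TRUE, trace = trace))
  }
  repeat {
    last <- substr(peptide, nchar(peptide), nchar(peptide))
    if (nchar(peptide) > 0 && last %in% c("K", "R")) {
      trace <- c(trace, paste0("cpe_removed:", last))
      peptide <- substr(peptide, 1, nchar(peptide) - 1)
    } else {
      break
    }
  }
  if (nchar(peptide) > 0 &&
      substr(peptide, nchar(peptide), nchar(peptide)) == "G") {
    peptide <- substr(peptide, 1, nchar(peptide) - 1)
    amidated <- TRUE
    trace <- c(trace, "pam_amidation")
  }
  if (nchar(peptide) == 0) {
    abort("mature peptide empty after processing")
  }
  list(sequence = peptide, amidated = amidated, trace = trace)
}

#' Mature peptide from an annotated precursor
#'
#' Applies the secretory maturation model to an accepted precursor
#' annotation. The proprotein convertase cleaves immediately after the
#' second basic residue of the dibasic site, so the released intermediate is
#' the mature core plus the dibasic pair. Carboxypeptidase E (CPE) then
#' iteratively removes C-terminal Lys/Arg residues, and if the exposed
#' C-terminal residue is a glycine, peptidylglycine alpha-amidating
#' monooxygenase (PAM) removes that single glycine and leaves the preceding
#' residue C-terminally amidated.
#'
#' @param a An accepted `precursor_annotation` from [annotate_precursor()].
#' @return A `mature_peptide`: list with `sequence`, `amidated`, `trace`
#'   (ordered processing events) and `protein_id`.
#' @export
mature_from_annotation <- function(a) {
  stopifnot(inherits(a, "precursor_annotation"))
  if (!a$accepted) {
    abort("cannot mature a rejected annotation")
  }
  released <- paste0(a$core, a$site$motif)
  res <- process_peptide(released, trace = "convertase_cut")
  structure(
    list(sequence = res$sequence, amidated = res$amidated,
         trace = res$trace, protein_id = a$protein_id),
    class = "mature_peptide"
  )
}

#' @export
print.mature_peptide <- function(x, ...) {
  cat("<mature_peptide>", x$sequence,
      if (x$amidated) "-NH2" else "", "\n")
  cat("  trace:", paste(x$trace, collapse = " -> "), "\n")
  invisible(x)
}
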