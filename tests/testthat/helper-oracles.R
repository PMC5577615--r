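# Independent oracles and small generators used across the suite.

random_transcript <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

random_peptide <- function(len, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# Brute-force ORF enumerator: every ATG..stop span in all six frames via
# seqinr translation, reduced to the longest span per (strand, frame, stop),
# then length-filtered. Shares no code with extract_orfs().
oracle_orfs <- function(seq, min_codons = 50, max_codons = 120,
                        require_stop = FALSE) {
  n <- nchar(seq)
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp_chr(seq)
    for (frame in 0:2) {
      ncod <- (n - frame) %/% 3
      if (ncod < 1) next
      aa <- seqinr::translate(seqinr::s2c(s), frame = frame)
      aa <- aa[seq_len(ncod)]
      for (i in seq_len(ncod)) {
        if (aa[i] != "M") next
        stop_at <- NA_integer_
        j <- i
        while (j <= ncod) {
          if (aa[j] == "*") {
            stop_at <- j
            break
          }
          j <- j + 1
        }
        if (!is.na(stop_at)) {
          if (stop_at == i) next
          prot <- paste(aa[i:(stop_at - 1)], collapse = "")
          local_start <- frame + (i - 1) * 3
          local_end <- frame + stop_at * 3
          has_stop <- TRUE
        } else {
          if (require_stop) next
          prot <- paste(aa[i:ncod], collapse = "")
          local_start <- frame + (i - 1) * 3
          local_end <- frame + ncod * 3
          has_stop <- FALSE
        }
        hits[[length(hits) + 1]] <- data.frame(
          strand = strand, frame = frame,
          start = if (strand == "+") local_start else n - local_end,
          end = if (strand == "+") local_end else n - local_start,
          codon_length = nchar(prot), has_stop_codon = has_stop,
          protein = prot, local_start = local_start
        )
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(strand = character(), frame = integer(),
                      start = integer(), end = integer(),
                      codon_length = integer(), has_stop_codon = logical(),
                      protein = character()))
  }
  df <- do.call(rbind, hits)
  # longest-per-stop: smallest local start per (strand, frame, span end)
  key <- paste(df$strand, df$frame, ifelse(df$strand == "+", df$end, df$start))
  keep <- unlist(lapply(split(seq_len(nrow(df)), key), function(idx) {
    idx[which.min(df$local_start[idx])]
  }))
  df <- df[keep, setdiff(names(df), "local_start")]
  df <- df[df$codon_length > min_codons & df$codon_length < max_codons, ]
  df <- df[order(df$start, df$strand), ]
  rownames(df) <- NULL
  df
}

# pH-grid scan oracle for the isoelectric point (step 0.0005).
oracle_pi <- function(p, amidated = FALSE, include_termini = TRUE,
                      pka = pka_table()) {
  grid <- seq(0, 14, by = 0.0005)
  z <- net_charge(p, grid, amidated = amidated,
                  include_termini = include_termini, pka = pka)
  grid[which.min(abs(z))]
}

# Double-loop scan for dibasic pairs; start is 0-based.
oracle_dibasic <- function(p, from = 0) {
  ch <- strsplit(p, "", fixed = TRUE)[[1]]
  out <- data.frame(motif = character(), start = integer())
  for (i in seq_len(length(ch) - 1)) {
    if ((i - 1) >= from && ch[i] %in% c("K", "R") &&
        ch[i + 1] %in% c("K", "R")) {
      out <- rbind(out, data.frame(motif = paste0(ch[i], ch[i + 1]),
                                   start = i - 1))
    }
  }
  out
}

# Per-column counting oracle for the 50% majority consensus.
oracle_consensus <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  out <- character(0)
  for (j in seq_len(ncol(mat))) {
    tab <- table(mat[, j])
    best <- max(tab)
    winner <- sort(names(tab)[tab == best], method = "radix")[1]
    if (winner == "-" && best / nrow(mat) >= 0.5) next
    out <- c(out, if (best / nrow(mat) >= 0.5 && winner != "-") winner else "X")
  }
  paste(out, collapse = "")
}

myticalin_functional <- function() {
  read_fasta(system.file("extdata", "myticalin_mature_peptides.fasta",
                         package = "lcamp"), "protein")
}

myticalin_virtual <- function() {
  read_fasta(system.file("extdata", "myticalin_virtual_peptides.fasta",
                         package = "lcamp"), "protein")
}

consensus_signal_A <- function() {
  gsub("X", "A", "MKGXXLLLLTIXXALCMIXECEG")
}

write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
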