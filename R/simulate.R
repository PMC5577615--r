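SIGNAL_TEMPLATE <- "MKGXXLLLLTIXXALCMIXECEG"

# sample() semantics without the length-1 surprise
resample <- function(x, n = 1, ...) {
  x[sample.int(length(x), n, ...)]
}

#' Configuration of the synthetic-transcriptome generator
#'
#' Defines the study conditions the generator emulates: precursor-sized
#' transcripts carrying planted AMP precursors (consensus-derived signal
#' peptide, subfamily-typed cationic mature core of 23-42 residues, dibasic
#' convertase site, anionic propeptide tail of 35-75 residues with ~30%
#' Asp/Glu) among adversarial decoys, each decoy violating exactly one
#' discovery gate.
#'
#' @param n_planted Number of planted precursors.
#' @param n_decoys Number of decoys (classes assigned by cycling through
#'   `decoy_classes`).
#' @param seed Integer seed; identical `(config, seed)` gives byte-identical
#'   output.
#' @param mature_length_range Inclusive range of mature-peptide lengths.
#' @param tail_length_range Inclusive range of tail lengths; the upper end
#'   is additionally capped per precursor so the whole product stays inside
#'   the ORF length gate of [filter_config()].
#' @param tail_de_fraction Target Asp+Glu fraction of the tail.
#' @param subfamily_mix Named probabilities over subfamilies A, B, C, D.
#' @param utr_length_range Inclusive range of UTR lengths (each side).
#' @param amidation_prob Probability that a planted core carries the
#'   Gly-Lys-Arg C-terminus that matures into an amidated peptide.
#' @param flip_prob Probability a transcript is emitted on the reverse
#'   strand.
#' @param decoy_classes Decoy classes to cycle through: `"no_signal"`,
#'   `"no_dibasic"`, `"low_cationicity"`, `"cationic_but_basic_tail"`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_planted = 50, n_decoys = 500, seed = 42,
                       mature_length_range = c(23, 42),
                       tail_length_range = c(35, 75),
                       tail_de_fraction = 0.30,
                       subfamily_mix = c(A = 0.25, B = 0.25, C = 0.25, D = 0.25),
                       utr_length_range = c(30, 120),
                       amidation_prob = 0.7,
                       flip_prob = 0.5,
                       decoy_classes = c("no_signal", "no_dibasic",
                                         "low_cationicity",
                                         "cationic_but_basic_tail")) {
  stopifnot(abs(sum(subfamily_mix) - 1) < 1e-9,
            all(names(subfamily_mix) %in% c("A", "B", "C", "D")),
            mature_length_range[1] <= mature_length_range[2],
            tail_length_range[1] <= tail_length_range[2],
            utr_length_range[1] >= 3)
  structure(
    list(n_planted = n_planted, n_decoys = n_decoys, seed = seed,
         mature_length_range = mature_length_range,
         tail_length_range = tail_length_range,
         tail_de_fraction = tail_de_fraction,
         subfamily_mix = subfamily_mix,
         utr_length_range = utr_length_range,
         amidation_prob = amidation_prob, flip_prob = flip_prob,
         decoy_classes = decoy_classes),
    class = "sim_config"
  )
}

#' Read a generator configuration from JSON
#'
#' @param path JSON file whose fields override [sim_config()] defaults.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$subfamily_mix)) {
    cfg$subfamily_mix <- unlist(cfg$subfamily_mix)
  }
  do.call(sim_config, cfg)
}

sample_signal <- function() {
  letters <- strsplit(SIGNAL_TEMPLATE, "", fixed = TRUE)[[1]]
  x_pos <- which(letters == "X")
  letters[x_pos] <- sample(c("A", "L", "S", "V"), length(x_pos), replace = TRUE)
  # up to two extra substitutions, reverted if they disturb the
  # hydrophobic core or move the (-3,-1) cleavage position
  n_sub <- sample(0:2, 1)
  if (n_sub > 0) {
    cand <- letters
    pos <- sample(setdiff(2:19, c(1)), n_sub)
    cand[pos] <- sample(c("A", "L", "S", "V", "I", "T"), n_sub, replace = TRUE)
    probe <- paste0(paste(cand, collapse = ""), "RPRIPRYPRW")
    sp <- predict_signal_peptide(probe)
    if (sp$present && sp$cleavage_pos == length(letters)) {
      letters <- cand
    }
  }
  paste(letters, collapse = "")
}

# Shuffle residue letters under the core constraints: no two adjacent basic
# residues (which would create an internal convertase site) and a last
# residue outside {K, R, G} (so CPE/PAM never eat into the planted mature).
arrange_core <- function(letters, max_tries = 1000) {
  is_basic <- letters %in% c("K", "R")
  basics <- letters[is_basic]
  others <- letters[!is_basic]
  k <- length(basics)
  len <- length(letters)
  if (k > ceiling(len / 2)) {
    abort("too many basic residues to avoid adjacency")
  }
  for (i in seq_len(max_tries)) {
    out <- character(len)
    if (k > 0) {
      # uniform non-adjacent placement: choose k of len-k+1 slots, spread out
      pos <- sort(resample(seq_len(len - k + 1), k)) + seq_len(k) - 1
      out[pos] <- resample(basics, k)
      out[-pos] <- resample(others, length(others))
    } else {
      out <- resample(others, length(others))
    }
    if (out[len] %in% c("K", "R", "G")) next
    return(paste(out, collapse = ""))
  }
  abort("could not arrange a core satisfying the planting constraints")
}

core_letters <- function(subfamily, len) {
  filler <- c("G", "S", "I", "V", "A", "L", "N", "Q")
  need <- switch(subfamily,
    A = c(R = ceiling(0.15 * len), P = ceiling(0.15 * len),
          Y = ceiling(0.15 * len)),
    B = c(R = ceiling(0.15 * len), P = ceiling(0.15 * len),
          T = ceiling(0.15 * len)),
    C = c(R = ceiling(0.30 * len)),
    D = c(R = ceiling(0.15 * len), P = ceiling(0.15 * len),
          W = ceiling(0.08 * len)),
    abort(paste0("unknown subfamily: ", subfamily))
  )
  if (subfamily == "C") {
    filler <- c(filler, "T")                 # anything but Pro
  }
  fixed <- rep(names(need), need)
  c(fixed, sample(filler, len - length(fixed), replace = TRUE))
}

sample_tail <- function(len, de_fraction) {
  n_de <- round(de_fraction * len)
  acidic <- sample(c("D", "E"), n_de, replace = TRUE)
  filler <- sample(c("S", "T", "G", "A", "N", "Q", "I", "V", "L"),
                   len - n_de, replace = TRUE)
  paste(sample(c(acidic, filler)), collapse = "")
}

#' Simulate one planted precursor
#'
#' Draws a precursor of the canonical architecture for one subfamily:
#' consensus-derived signal peptide, mature core whose composition
#' guarantees the subfamily's classification rule, optional Gly amide donor,
#' Lys-Arg convertase site, and anionic tail. Uses the current RNG state;
#' seed via [simulate_transcriptome()] or `set.seed()`.
#'
#' @param subfamily `"A"`, `"B"`, `"C"` or `"D"`.
#' @param config A [sim_config()].
#' @return A list with `precursor`, `mature` (the expected product of the
#'   maturation model), `amidated` and `subfamily`.
#' @export
simulate_precursor <- function(subfamily, config = sim_config()) {
  signal <- sample_signal()
  len <- resample(config$mature_length_range[1]:config$mature_length_range[2])
  mature <- arrange_core(core_letters(subfamily, len))
  amidated <- runif(1) < config$amidation_prob
  core <- if (amidated) paste0(mature, "G") else mature
  # keep the full product strictly below the ORF gate's upper bound
  budget <- (120 - 1) - nchar(signal) - nchar(core) - 2
  tail_hi <- min(config$tail_length_range[2], budget)
  tail_len <- resample(config$tail_length_range[1]:tail_hi)
  tail <- sample_tail(tail_len, config$tail_de_fraction)
  list(
    precursor = paste0(signal, core, "KR", tail),
    mature = mature, amidated = amidated, subfamily = subfamily
  )
}

CODON_CHOICES <- split(names(Biostrings::GENETIC_CODE),
                       unname(Biostrings::GENETIC_CODE))

reverse_translate <- function(protein, add_stop = TRUE) {
  letters <- strsplit(protein, "", fixed = TRUE)[[1]]
  codons <- vapply(letters, function(aa) {
    choices <- CODON_CHOICES[[aa]]
    choices[sample.int(length(choices), 1)]
  }, character(1), USE.NAMES = FALSE)
  if (add_stop) {
    stops <- CODON_CHOICES[["*"]]
    codons <- c(codons, stops[sample.int(length(stops), 1)])
  }
  paste(codons, collapse = "")
}

random_nt <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

wrap_in_transcript <- function(protein, config) {
  cds <- reverse_translate(protein)
  utr_range <- config$utr_length_range[1]:config$utr_length_range[2]
  utr5 <- random_nt(resample(utr_range))
  # in-frame stop immediately upstream of the start codon, so no upstream
  # ATG can extend the planted ORF under the longest-per-stop convention
  substr(utr5, nchar(utr5) - 2, nchar(utr5)) <- "TAA"
  utr3 <- random_nt(resample(utr_range))
  transcript <- paste0(utr5, cds, utr3)
  if (runif(1) < config$flip_prob) {
    transcript <- reverse_complement(transcript)
  }
  transcript
}

simulate_decoy <- function(class, config) {
  signal_like <- function() sample_signal()
  protein <- switch(class,
    no_signal = {
      len <- resample(60:110)
      paste0("M", paste(sample(c("D", "E", "N", "Q", "K", "R", "S", "T", "G", "P"),
                               len - 1, replace = TRUE), collapse = ""))
    },
    no_dibasic = {
      core <- arrange_core(core_letters("C", resample(25:35)))
      tail <- sample_tail(resample(30:45), config$tail_de_fraction)
      paste0(signal_like(), core, tail)
    },
    low_cationicity = {
      len <- resample(50:70)
      region <- paste(sample(c("D", "E", "S", "T", "G", "A", "I", "V", "L",
                               "N", "Q"),
                             len, replace = TRUE,
                             prob = c(0.1, 0.1, rep(0.8 / 9, 9))),
                      collapse = "")
      paste0(signal_like(), region)
    },
    cationic_but_basic_tail = {
      core <- arrange_core(core_letters("C", resample(25:35)))
      tail_len <- resample(30:45)
      tail <- paste(sample(c("K", "S", "T", "G", "N", "Q"), tail_len,
                           replace = TRUE,
                           prob = c(0.3, rep(0.14, 5))), collapse = "")
      paste0(signal_like(), core, "KR", tail)
    },
    abort(paste0("unknown decoy class: ", class))
  )
  protein
}

#' Simulate a transcriptome with planted precursors and decoys
#'
#' Reverse-translates planted precursors and decoys with uniform synonymous
#' codon choice, wraps them in random UTRs, flips strands at random, and
#' returns the transcripts with a ground-truth table. Each decoy class
#' violates exactly one discovery gate (no signal peptide, no dibasic site,
#' sub-threshold cationicity, or a basic rather than anionic tail), so
#' specificity can be audited per gate. Output is byte-identical for the
#' same configuration and seed.
#'
#' @param config A [sim_config()].
#' @return A list with `transcripts` (tibble: `id`, `description`,
#'   `sequence`), `truth` (tibble: `transcript_id`, `precursor`, `mature`,
#'   `amidated`, `subfamily`) and `decoys` (tibble: `transcript_id`,
#'   `class`).
#' @examples
#' sim <- simulate_transcriptome(sim_config(n_planted = 2, n_decoys = 4, seed = 1))
#' sim$truth
#' @export
simulate_transcriptome <- function(config = sim_config()) {
  set.seed(config$seed)
  truth <- list()
  transcripts <- list()
  if (config$n_planted > 0) {
    mix <- config$subfamily_mix
    labels <- sample(names(mix), config$n_planted, replace = TRUE, prob = mix)
    for (i in seq_len(config$n_planted)) {
      plant <- simulate_precursor(labels[i], config)
      id <- sprintf("plant_%04d", i)
      truth[[i]] <- tibble(
        transcript_id = id, precursor = plant$precursor,
        mature = plant$mature, amidated = plant$amidated,
        subfamily = plant$subfamily
      )
      transcripts[[length(transcripts) + 1]] <- tibble(
        id = id, description = "planted precursor",
        sequence = wrap_in_transcript(plant$precursor, config)
      )
    }
  }
  decoys <- list()
  if (config$n_decoys > 0) {
    classes <- rep_len(config$decoy_classes, config$n_decoys)
    for (i in seq_len(config$n_decoys)) {
      id <- sprintf("decoy_%04d", i)
      protein <- simulate_decoy(classes[i], config)
      decoys[[i]] <- tibble(transcript_id = id, class = classes[i],
                            protein = protein)
      transcripts[[length(transcripts) + 1]] <- tibble(
        id = id, description = paste("decoy", classes[i]),
        sequence = wrap_in_transcript(protein, config)
      )
    }
  }
  list(
    transcripts = if (length(transcripts) > 0) bind_rows(transcripts) else
      tibble(id = character(), description = character(),
             sequence = character()),
    truth = if (length(truth) > 0) bind_rows(truth) else
      tibble(transcript_id = character(), precursor = character(),
             mature = character(), amidated = logical(),
             subfamily = character()),
    decoys = if (length(decoys) > 0) bind_rows(decoys) else
      tibble(transcript_id = character(), class = character(),
             protein = character())
  )
}

#' Score pipeline recovery against planted ground truth
#'
#' @param reports Candidate table from [screen_transcriptome()] (an
#'   `amp_screen` or its `$candidates` tibble).
#' @param truth Truth table from [simulate_transcriptome()].
#' @return A one-row tibble: `sensitivity` (planted transcripts recovered /
#'   planted), `precision` (reports on planted transcripts / reports; `NA`
#'   with `precision_defined = FALSE` when nothing was reported),
#'   `exact_mature_match_rate` (planted whose mature sequence and amidation
#'   are reproduced byte-identically / planted), plus the underlying counts.
#' @export
evaluate_recovery <- function(reports, truth) {
  if (inherits(reports, "amp_screen")) {
    reports <- reports$candidates
  }
  if (anyDuplicated(truth$transcript_id)) {
    abort("duplicate transcript ids in truth table")
  }
  n_planted <- nrow(truth)
  n_reported <- nrow(reports)
  recovered <- truth$transcript_id %in% reports$transcript_id
  exact <- vapply(seq_len(n_planted), function(i) {
    hits <- reports[reports$transcript_id == truth$transcript_id[i], ]
    any(hits$mature == truth$mature[i] & hits$amidated == truth$amidated[i])
  }, logical(1))
  tibble(
    sensitivity = if (n_planted > 0) mean(recovered) else NA_real_,
    precision = if (n_reported > 0) {
      mean(reports$transcript_id %in% truth$transcript_id)
    } else NA_real_,
    precision_defined = n_reported > 0,
    exact_mature_match_rate = if (n_planted > 0) mean(exact) else NA_real_,
    n_planted = n_planted, n_reported = n_reported
  )
}

#' Write the ground-truth table as TSV
#'
#' @param truth Truth tibble from [simulate_transcriptome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}
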