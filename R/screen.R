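#' Discovery-filter configuration
#'
#' Bundles every tunable threshold of [screen_transcriptome()]:
#'
#' * `min_codons`, `max_codons` — strict ORF length gate (51-119 codons by
#'   default, the usual size of secreted AMP precursors).
#' * `require_stop` — drop ORFs lacking a terminal stop codon.
#' * `window`, `rp_fraction_threshold`, `window_pi_threshold`,
#'   `filter_mode` — the cationicity filter: a candidate passes when some
#'   `window`-residue window of the post-signal region has an Arg/Pro
#'   fraction above `rp_fraction_threshold` (combined `{R, P}` class by
#'   default; `"either_R_or_P"` tests each residue alone) or a side-chain
#'   isoelectric point above `window_pi_threshold`.
#' * `window_region` — scan the `"post_signal"` region (default; signal
#'   peptides are hydrophobic, not cationic) or the `"full"` precursor.
#' * `min_mature`, `min_tail` — architecture geometry for
#'   [annotate_precursor()].
#' * `mature_length_range`, `pi_flag_threshold`, `arg_flag_threshold` —
#'   reporting flags on the mature peptide (length within 23-42, pI above
#'   11, Arg above 10%).
#'
#' @param min_codons,max_codons Strict codon-length bounds for ORFs.
#' @param require_stop Require a terminal stop codon.
#' @param window Sliding-window length in residues.
#' @param rp_fraction_threshold Arg/Pro window-fraction threshold.
#' @param window_pi_threshold Window side-chain pI threshold.
#' @param filter_mode `"combined_RP"` or `"either_R_or_P"`.
#' @param window_region `"post_signal"` or `"full"`.
#' @param min_mature,min_tail Minimum mature-core and tail lengths.
#' @param mature_length_range Reported-length flag range (inclusive).
#' @param pi_flag_threshold,arg_flag_threshold Reported physicochemical
#'   flag thresholds.
#' @param pka A [pka_table()] (or built-in table name).
#' @param rules Subfamily rule table.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_codons = 50, max_codons = 120,
                          require_stop = FALSE,
                          window = 15, rp_fraction_threshold = 0.30,
                          window_pi_threshold = 8.0,
                          filter_mode = c("combined_RP", "either_R_or_P"),
                          window_region = c("post_signal", "full"),
                          min_mature = 10, min_tail = 5,
                          mature_length_range = c(23, 42),
                          pi_flag_threshold = 11.0,
                          arg_flag_threshold = 0.10,
                          pka = pka_table(),
                          rules = default_subfamily_rules()) {
  stopifnot(window >= 1, rp_fraction_threshold > 0, window_pi_threshold > 0,
            min_codons >= 1, max_codons > min_codons)
  structure(
    list(min_codons = min_codons, max_codons = max_codons,
         require_stop = require_stop,
         window = window, rp_fraction_threshold = rp_fraction_threshold,
         window_pi_threshold = window_pi_threshold,
         filter_mode = match.arg(filter_mode),
         window_region = match.arg(window_region),
         min_mature = min_mature, min_tail = min_tail,
         mature_length_range = mature_length_range,
         pi_flag_threshold = pi_flag_threshold,
         arg_flag_threshold = arg_flag_threshold,
         pka = pka_table(pka), rules = rules),
    class = "filter_config"
  )
}

window_filter_pass <- function(region, config) {
  if (config$filter_mode == "combined_RP") {
    rp_max <- window_scan(region, config$window, "class_fraction",
                          residues = c("R", "P"))$max_value
  } else {
    rp_max <- max(
      window_scan(region, config$window, "class_fraction", residues = "R")$max_value,
      window_scan(region, config$window, "class_fraction", residues = "P")$max_value
    )
  }
  if (rp_max > config$rp_fraction_threshold) {
    return(list(pass = TRUE, rp_max = rp_max, pi_max = NA_real_))
  }
  pi_max <- window_scan(region, config$window, "side_chain_pi",
                        pka = config$pka)$max_value
  list(pass = pi_max > config$window_pi_threshold, rp_max = rp_max,
       pi_max = pi_max)
}

screen_one_orf <- function(orf_row, config, overrides) {
  protein_id <- paste0(orf_row$transcript_id, "|", orf_row$strand,
                       orf_row$frame, "|", orf_row$start)
  signal <- predict_signal_peptide(orf_row$protein,
                                   id = orf_row$transcript_id,
                                   overrides = overrides)
  if (!signal$present) {
    return(list(outcome = "no_signal"))
  }
  region <- if (config$window_region == "post_signal") {
    substr(orf_row$protein, signal$cleavage_pos + 1, nchar(orf_row$protein))
  } else {
    orf_row$protein
  }
  if (nchar(region) == 0) {
    return(list(outcome = "window_filter"))
  }
  wf <- window_filter_pass(region, config)
  if (!wf$pass) {
    return(list(outcome = "window_filter"))
  }
  ann <- annotate_precursor(orf_row$protein, signal, id = protein_id,
                            min_mature = config$min_mature,
                            min_tail = config$min_tail, pka = config$pka)
  if (!ann$accepted) {
    return(list(outcome = ann$reason))
  }
  mature <- tryCatch(mature_from_annotation(ann),
                     error = function(e) NULL)
  if (is.null(mature)) {
    return(list(outcome = "maturation_failed"))
  }
  phys <- characterize_peptides(
    tibble(id = protein_id, sequence = mature$sequence,
           amidated = mature$amidated),
    pka = config$pka
  )
  call <- classify_subfamily(mature$sequence, rules = config$rules)
  mature_seq <- mature$sequence
  mature_amidated <- mature$amidated
  mature_trace <- paste(mature$trace, collapse = ";")
  row <- tibble(
    transcript_id = orf_row$transcript_id,
    strand = orf_row$strand, frame = orf_row$frame,
    orf_start = orf_row$start, orf_end = orf_row$end,
    protein = orf_row$protein,
    signal_end = signal$cleavage_pos, signal_source = signal$source,
    core_start = ann$regions$core_start, core_end = ann$regions$core_end,
    motif = ann$site$motif, tail_start = ann$regions$tail_start,
    tail_net_charge_ph7 = ann$tail_net_charge_ph7,
    tail_de_fraction = ann$tail_de_fraction,
    window_rp_max = wf$rp_max, window_pi_max = wf$pi_max,
    mature = mature_seq,
    amidated = mature_amidated,
    trace = mature_trace,
    length = phys$length, pi = phys$pi, pi_status = phys$pi_status,
    net_charge_ph7 = phys$net_charge_ph7,
    frac_r = phys$frac_r, frac_p = phys$frac_p, frac_y = phys$frac_y,
    frac_w = phys$frac_w, frac_t = phys$frac_t, frac_de = phys$frac_de,
    subfamily = call$label,
    pi_gt_threshold = phys$pi > config$pi_flag_threshold,
    arg_gt_threshold = phys$frac_r > config$arg_flag_threshold,
    length_in_range = phys$length >= config$mature_length_range[1] &
      phys$length <= config$mature_length_range[2]
  )
  list(outcome = "candidate", row = row)
}

#' Screen a transcriptome for linear cationic AMP precursors
#'
#' Runs the full discovery chain on assembled transcripts:
#'
#' 1. six-frame ORF extraction with the precursor-size gate
#'    ([extract_orfs()]);
#' 2. signal-peptide gate ([predict_signal_peptide()], optionally driven by
#'    external predictions via `overrides`);
#' 3. sliding-window cationicity filter on the post-signal region;
#' 4. precursor architecture: dibasic convertase site plus anionic tail
#'    ([annotate_precursor()]);
#' 5. maturation ([mature_from_annotation()]), physicochemical profiling,
#'    and subfamily classification.
#'
#' Every ORF that enters the chain is recorded with its outcome (the stage
#' that rejected it, or `"candidate"`), so specificity can be audited per
#' gate.
#'
#' @param transcripts Data frame with `id` and `sequence` nucleotide
#'   columns (e.g. from [read_fasta()]), or a path to a nucleotide FASTA.
#' @param config A [filter_config()].
#' @param overrides Optional external signal predictions
#'   ([read_signal_overrides()]), keyed by transcript id.
#' @return An `amp_screen` object: `$candidates` (one row per surviving
#'   candidate with architecture, mature sequence, physicochemistry,
#'   subfamily and flags), `$orfs` (every gated ORF with its `outcome`),
#'   `$config`, `$n_transcripts`. `tidy()` returns the candidate table,
#'   `glance()` the per-stage counts, `autoplot()` the rejection funnel.
#' @export
screen_transcriptome <- function(transcripts, config = filter_config(),
                                 overrides = NULL) {
  if (is.character(transcripts) && length(transcripts) == 1 &&
      file.exists(transcripts)) {
    transcripts <- read_fasta(transcripts, "nucleotide")
  }
  orfs <- extract_orfs(transcripts,
                       min_codons = config$min_codons,
                       max_codons = config$max_codons,
                       require_stop = config$require_stop)
  outcomes <- character(nrow(orfs))
  rows <- list()
  for (i in seq_len(nrow(orfs))) {
    res <- screen_one_orf(orfs[i, ], config, overrides)
    outcomes[i] <- res$outcome
    if (res$outcome == "candidate") {
      rows[[length(rows) + 1]] <- res$row
    }
  }
  orfs$outcome <- outcomes
  candidates <- if (length(rows) > 0) bind_rows(rows) else tibble(
    transcript_id = character(), strand = character(), frame = integer(),
    orf_start = integer(), orf_end = integer(), protein = character(),
    signal_end = integer(), signal_source = character(),
    core_start = integer(), core_end = integer(), motif = character(),
    tail_start = integer(), tail_net_charge_ph7 = numeric(),
    tail_de_fraction = numeric(), window_rp_max = numeric(),
    window_pi_max = numeric(), mature = character(), amidated = logical(),
    trace = character(), length = integer(), pi = numeric(),
    pi_status = character(), net_charge_ph7 = numeric(),
    frac_r = numeric(), frac_p = numeric(), frac_y = numeric(),
    frac_w = numeric(), frac_t = numeric(), frac_de = numeric(),
    subfamily = character(), pi_gt_threshold = logical(),
    arg_gt_threshold = logical(), length_in_range = logical()
  )
  structure(
    list(candidates = candidates, orfs = orfs, config = config,
         n_transcripts = if (is.data.frame(transcripts)) nrow(transcripts)
                         else NA_integer_),
    class = "amp_screen"
  )
}

screen_stage_levels <- c("candidate", "no_signal", "window_filter",
                         "no_dibasic", "mature_too_short",
                         "tail_not_anionic", "maturation_failed")

#' @export
print.amp_screen <- function(x, ...) {
  cat("<amp_screen>", x$n_transcripts, "transcripts,",
      nrow(x$orfs), "gated ORFs,", nrow(x$candidates), "candidates\n")
  print(glance(x))
  invisible(x)
}

#' @rdname screen_transcriptome
#' @param x An `amp_screen`.
#' @param ... Unused.
#' @method tidy amp_screen
#' @export
tidy.amp_screen <- function(x, ...) {
  x$candidates
}

#' @rdname screen_transcriptome
#' @method glance amp_screen
#' @export
glance.amp_screen <- function(x, ...) {
  counts <- table(factor(x$orfs$outcome, levels = screen_stage_levels))
  as_tibble(c(list(n_transcripts = x$n_transcripts, n_orfs = nrow(x$orfs)),
              setNames(as.list(as.integer(counts)),
                       paste0("n_", names(counts)))))
}

#' Write the candidate report and run summary
#'
#' `write_candidate_report()` writes the candidate table as TSV (fractions
#' also reported as percentages truncated to one decimal).
#' `write_run_summary()` writes a JSON summary sufficient to reproduce the
#' run: the configuration echo, per-stage ORF counts, and optionally the
#' seed and input file hash.
#'
#' @param screen An `amp_screen`.
#' @param path Output path.
#' @param seed Optional seed to echo.
#' @param input Optional input file path; its MD5 hash is recorded.
#' @return `path`, invisibly.
#' @export
write_candidate_report <- function(screen, path) {
  cand <- screen$candidates
  for (col in c("frac_r", "frac_p", "frac_y", "frac_w", "frac_t", "frac_de")) {
    cand[[sub("frac", "pct", col)]] <- pct_floor(cand[[col]], digits = 1)
  }
  readr::write_tsv(cand, path)
  invisible(path)
}

#' @rdname write_candidate_report
#' @export
write_run_summary <- function(screen, path, seed = NULL, input = NULL) {
  cfg <- screen$config
  cfg$pka <- list(name = cfg$pka$name,
                  side_chain = as.list(cfg$pka$side_chain),
                  n_terminus = cfg$pka$n_terminus,
                  c_terminus = cfg$pka$c_terminus)
  summary <- list(
    config = cfg[setdiff(names(cfg), "rules")],
    n_transcripts = screen$n_transcripts,
    n_orfs = nrow(screen$orfs),
    outcomes = as.list(table(factor(screen$orfs$outcome,
                                    levels = screen_stage_levels))),
    n_candidates = nrow(screen$candidates),
    seed = seed,
    input = if (!is.null(input)) {
      list(path = input, md5 = unname(tools::md5sum(input)))
    }
  )
  jsonlite::write_json(summary, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
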