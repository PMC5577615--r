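#' Plot a sliding-window scan
#'
#' @param object A `window_scan` from [window_scan()].
#' @param threshold Optional horizontal reference line (e.g. the filter
#'   threshold).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot window_scan
#' @export
autoplot.window_scan <- function(object, threshold = NULL, ...) {
  df <- tidy(object)
  lab <- if (object$statistic == "class_fraction") {
    paste0("{", paste(object$residues, collapse = ","), "} window fraction")
  } else {
    "window side-chain pI"
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$start, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = df[df$start == object$argmax_start, ], color = "red"
    ) +
    ggplot2::labs(x = "window start (residue)", y = lab) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' Plot the rejection funnel of a transcriptome screen
#'
#' Shows how many gated ORFs were rejected at each stage of the discovery
#' chain and how many survived as candidates.
#'
#' @param object An `amp_screen` from [screen_transcriptome()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot amp_screen
#' @export
autoplot.amp_screen <- function(object, ...) {
  df <- object$orfs |>
    dplyr::count(outcome = factor(.data$outcome,
                                  levels = rev(screen_stage_levels)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "ORFs") +
    ggplot2::theme_minimal()
}

#' Plot per-column consensus support
#'
#' @param object A `consensus_result` from [majority_consensus()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot consensus_result
#' @export
autoplot.consensus_result <- function(object, ...) {
  df <- tidy(object)
  df$kept <- !is.na(df$symbol)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$support,
                                   fill = .data$kept)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "alignment column", y = "winning-symbol support",
                  fill = "kept") +
    ggplot2::theme_minimal()
}

#' Titration curve of a peptide
#'
#' Plots Henderson-Hasselbalch net charge against pH and marks the
#' isoelectric point.
#'
#' @inheritParams net_charge
#' @param n Number of pH grid points.
#' @return A ggplot.
#' @export
plot_charge_curve <- function(p, amidated = FALSE, include_termini = TRUE,
                              pka = pka_table(), n = 200) {
  ph <- seq(0, 14, length.out = n)
  df <- tibble(ph = ph,
               charge = net_charge(p, ph, amidated = amidated,
                                   include_termini = include_termini,
                                   pka = pka))
  pi <- isoelectric_point(p, amidated = amidated,
                          include_termini = include_termini, pka = pka)
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ph, y = .data$charge)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "pH", y = "net charge") +
    ggplot2::theme_minimal()
  if (identical(attr(pi, "status"), "ok")) {
    g <- g + ggplot2::annotate("point", x = as.numeric(pi), y = 0,
                               color = "red") +
      ggplot2::annotate("text", x = as.numeric(pi), y = 0,
                        label = sprintf("pI = %.2f", as.numeric(pi)),
                        hjust = -0.1, vjust = -0.5)
  }
  g
}
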