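#' Default subfamily rule table
#'
#' Compositional rules separating the four myticalin subfamilies, evaluated
#' in order with the first match winning:
#'
#' * **A** — rich in Arg, Pro and Tyr (each > 10%);
#' * **B** — rich in Pro, Arg and Thr (each > 10%) without the Tyr/Trp
#'   signatures of A or D;
#' * **D** — rich in Pro and Arg plus Trp (> 5%) or Thr (> 10%);
#' * **C** — rich in Arg (> 10%) but nearly devoid of Pro (<= 5%).
#'
#' B is evaluated before D because its Thr signature is a subset of D's
#' alternative condition; explicit Tyr/Trp guards keep the two disjoint.
#' Anything matching no rule is `unclassified`.
#'
#' The structure (a list of rules, each with a `label`, an `all` list of
#' conditions that must all hold, and an optional `any` list of which at
#' least one must hold; each condition is `list(metric, op, value)` with
#' metrics `frac_r/frac_p/frac_y/frac_w/frac_t` and ops `>`, `>=`, `<`,
#' `<=`) can be serialized to JSON and customized via
#' [read_subfamily_rules()].
#'
#' @return The rule list.
#' @export
default_subfamily_rules <- function() {
  cond <- function(metric, op, value) list(metric = metric, op = op, value = value)
  list(
    list(label = "A",
         all = list(cond("frac_r", ">", 0.10), cond("frac_p", ">", 0.10),
                    cond("frac_y", ">", 0.10))),
    list(label = "B",
         all = list(cond("frac_r", ">", 0.10), cond("frac_p", ">", 0.10),
                    cond("frac_t", ">", 0.10), cond("frac_y", "<=", 0.10),
                    cond("frac_w", "<=", 0.05))),
    list(label = "D",
         all = list(cond("frac_r", ">", 0.10), cond("frac_p", ">", 0.10)),
         any = list(cond("frac_w", ">", 0.05), cond("frac_t", ">", 0.10))),
    list(label = "C",
         all = list(cond("frac_r", ">", 0.10), cond("frac_p", "<=", 0.05)))
  )
}

#' Read a subfamily rule table from JSON
#'
#' @param path JSON file holding a rule list shaped like
#'   [default_subfamily_rules()].
#' @return The rule list.
#' @export
read_subfamily_rules <- function(path) {
  rules <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (rule in rules) {
    stopifnot(is.character(rule$label), length(rule$all) >= 1)
  }
  rules
}

eval_condition <- function(cond, metrics) {
  observed <- metrics[[cond$metric]]
  passed <- switch(cond$op,
    ">" = observed > cond$value,
    ">=" = observed >= cond$value,
    "<" = observed < cond$value,
    "<=" = observed <= cond$value,
    abort(paste0("unknown operator: ", cond$op))
  )
  tibble(metric = cond$metric, op = cond$op, threshold = cond$value,
         observed = observed, passed = passed)
}

#' Classify a mature peptide into a subfamily
#'
#' Evaluates the rule table against the peptide's composition fractions and
#' returns the first matching label together with the full evaluation trace,
#' so a call can always be re-derived from its record. Classification
#' depends only on composition, never on residue order.
#'
#' @param m A mature peptide: a plain sequence string or a `mature_peptide`
#'   from [mature_from_annotation()].
#' @param rules A rule table, by default [default_subfamily_rules()].
#' @return A `subfamily_call`: list with `label` (`"A"`, `"B"`, `"C"`,
#'   `"D"` or `"unclassified"`) and `trace` (a tibble of every evaluated
#'   condition with `rule`, `part`, `metric`, `op`, `threshold`, `observed`,
#'   `passed`).
#' @examples
#' classify_subfamily("GRRRRYRYWRRGYRSWRRGVTIQERSKSSTLNTED")$label
#' @export
classify_subfamily <- function(m, rules = default_subfamily_rules()) {
  seqstr <- if (inherits(m, "mature_peptide")) m$sequence else m
  comp <- composition(seqstr)
  metrics <- list(
    frac_r = comp$fractions[["R"]], frac_p = comp$fractions[["P"]],
    frac_y = comp$fractions[["Y"]], frac_w = comp$fractions[["W"]],
    frac_t = comp$fractions[["T"]]
  )
  trace <- list()
  label <- "unclassified"
  for (rule in rules) {
    all_tr <- purrr::map_dfr(rule$all, eval_condition, metrics = metrics)
    all_tr$part <- "all"
    any_tr <- NULL
    matched <- all(all_tr$passed)
    if (!is.null(rule$any) && length(rule$any) > 0) {
      any_tr <- purrr::map_dfr(rule$any, eval_condition, metrics = metrics)
      any_tr$part <- "any"
      matched <- matched && any(any_tr$passed)
    }
    tr <- bind_rows(all_tr, any_tr)
    tr$rule <- rule$label
    trace[[length(trace) + 1]] <- tr
    if (matched) {
      label <- rule$label
      break
    }
  }
  structure(
    list(label = label,
         trace = bind_rows(trace)[, c("rule", "part", "metric", "op",
                                      "threshold", "observed", "passed")]),
    class = "subfamily_call"
  )
}

#' @export
print.subfamily_call <- function(x, ...) {
  cat("<subfamily_call>", x$label, "\n")
  print(x$trace)
  invisible(x)
}

#' Classify a table of peptides
#'
#' @param peptides Data frame with `id` and `sequence` columns.
#' @param rules A rule table, by default [default_subfamily_rules()].
#' @return A tibble with `id`, `subfamily`.
#' @export
classify_peptides <- function(peptides, rules = default_subfamily_rules()) {
  stopifnot(all(c("id", "sequence") %in% names(peptides)))
  tibble(
    id = peptides$id,
    subfamily = vapply(peptides$sequence,
                       function(s) classify_subfamily(s, rules)$label,
                       character(1), USE.NAMES = FALSE)
  )
}
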