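# Likelihood-ratio diagnostics: per-symptom LR+ / LR- against each
# disorder, threshold panels, and pre-test to post-test updating.

#' Likelihood-ratio table
#'
#' One entry per influence arc: the positive likelihood ratio
#' `LR+ = q / baseline` and the negative likelihood ratio
#' `LR- = (1 - q) / (1 - baseline)`, where `q` is the elicited probability
#' of the arc's target (deviant) state given the disorder alone and the
#' baseline is that state's prevalence in the absence of any disorder. For
#' graded symptoms, "test positive" means the arc's target tail state and
#' the baseline is that tail's. Ratios are computed from the stored
#' unrounded fractions.
#'
#' @param ps a parameter set.
#' @return data.frame with columns `symptom`, `state`, `disorder`, `q`,
#'   `baseline`, `lr_plus`, `lr_minus`.
#' @examples
#' lr <- likelihood_ratio_table(builtin_cluster_b())
#' subset(lr, symptom == "DSM-BDL-09" & disorder == "BDL")$lr_plus  # 6.36
#' @export
likelihood_ratio_table <- function(ps) {
  rep_ <- validate_parameter_set(ps)
  if (nrow(rep_)) stop_pdnet("invalid parameter set; run validate_parameter_set()")
  out <- ps$arcs
  out$state <- ifelse(out$direction == "present", "present", out$direction)
  out$baseline <- vapply(seq_len(nrow(out)), function(i)
    baseline_of(ps, out$symptom[i], out$state[i]), numeric(1))
  if (any(out$baseline == 0)) stop_pdnet("LR+ undefined: baseline 0")
  if (any(out$baseline == 1)) stop_pdnet("LR- undefined: baseline 1")
  out$lr_plus <- out$q / out$baseline
  out$lr_minus <- (1 - out$q) / (1 - out$baseline)
  out[, c("symptom", "state", "disorder", "q", "baseline",
          "lr_plus", "lr_minus")]
}

#' Select a diagnostic panel
#'
#' Filters the likelihood-ratio table into a confirmatory panel
#' (`lr_plus >= threshold`, for confirming a suspected disorder in the
#' clinical population) or a screening panel (`lr_minus <= threshold`, for
#' ruling a disorder out in the general population). Thresholding uses the
#' unrounded ratios and the boundary is included. Entries are sorted by
#' diagnostic strength (descending `lr_plus` resp. ascending `lr_minus`)
#' with ties broken by symptom id.
#'
#' @param entries a [likelihood_ratio_table()].
#' @param mode `"confirmatory"` or `"screening"`.
#' @param threshold cut-off; defaults to 5 (confirmatory) or 0.2
#'   (screening).
#' @return object of class `pd_panel`: the filtered, sorted data.frame with
#'   attributes `mode` and `threshold`.
#' @export
select_panel <- function(entries, mode = c("confirmatory", "screening"),
                         threshold = NULL) {
  mode <- match.arg(mode)
  if (nrow(entries) == 0) stop_pdnet("empty likelihood-ratio table")
  threshold <- threshold %||% if (mode == "confirmatory") 5 else 0.2
  if (mode == "confirmatory") {
    keep <- entries$lr_plus >= threshold
    sel <- entries[keep, ]
    sel <- sel[order(-sel$lr_plus, sel$symptom), ]
  } else {
    keep <- entries$lr_minus <= threshold
    sel <- entries[keep, ]
    sel <- sel[order(sel$lr_minus, sel$symptom), ]
  }
  structure(sel, mode = mode, threshold = threshold,
            class = c("pd_panel", "data.frame"))
}

#' @export
print.pd_panel <- function(x, digits = 2, ...) {
  mode <- attr(x, "mode")
  cat(sprintf("%s panel (%s %s %.3g): %d entries\n",
              if (mode == "confirmatory") "Confirmatory" else "Screening",
              if (mode == "confirmatory") "LR+" else "LR-",
              if (mode == "confirmatory") ">=" else "<=",
              attr(x, "threshold"), nrow(x)))
  for (d in unique(x$disorder)) {
    sel <- x[x$disorder == d, ]
    lr <- if (mode == "confirmatory") sel$lr_plus else sel$lr_minus
    cat(sprintf("  %s: %s\n", d,
                paste(sprintf("%s (%.*f)", sel$symptom, digits, lr),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Post-test probability from a likelihood ratio
#'
#' Odds-form Bayes update: converts a pre-test probability to post-test via
#' `post = pretest * lr / (1 - pretest + pretest * lr)`.
#'
#' @param pretest prior probability, strictly inside (0, 1).
#' @param lr likelihood ratio of the observed test result (>= 0).
#' @return the post-test probability.
#' @examples
#' posttest_probability(0.035, 6.36)  # ~0.1875
#' @export
posttest_probability <- function(pretest, lr) {
  if (any(pretest <= 0 | pretest >= 1)) {
    stop_pdnet("degenerate prior: pretest must be inside (0,1)")
  }
  if (any(lr < 0)) stop_pdnet("likelihood ratio must be nonnegative")
  pretest * lr / (1 - pretest + pretest * lr)
}
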