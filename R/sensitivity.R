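# Strength-of-influence and finding-impact analyses.

distribution_distance <- function(p, q, distance) {
  switch(distance,
    euclidean = sqrt(sum((p - q)^2)),
    hellinger = sqrt(0.5 * sum((sqrt(p) - sqrt(q))^2)),
    absolute  = max(abs(p - q)),
    stop_pdnet("unknown distance '", distance, "'"))
}

#' Strength of influence of one arc
#'
#' For every configuration of the child's other parents, the child's
#' conditional distributions across the arc parent's states are compared
#' (maximum pairwise distance when the parent has more than two states);
#' the per-configuration values are aggregated by unweighted average or by
#' maximum. A strength of zero means the child is independent of the parent
#' in every context.
#'
#' @param model a `bn2o` model.
#' @param from parent node id.
#' @param to child node id.
#' @param metric aggregation over the other-parent configurations:
#'   `"average"` (default) or `"maximum"`.
#' @param distance distribution distance: `"euclidean"` (default),
#'   `"hellinger"` or `"absolute"` (maximum absolute difference).
#' @return object of class `pd_arc_strength`: list with the arc, metric,
#'   distance, aggregated `value` and the per-configuration values.
#' @export
arc_strength <- function(model, from, to,
                         metric = c("average", "maximum"),
                         distance = c("euclidean", "hellinger", "absolute")) {
  metric <- match.arg(metric)
  distance <- match.arg(distance)
  cpt <- model$cpts[[to]]
  if (is.null(cpt) || !from %in% cpt$parents) {
    stop_pdnet("no arc ", from, " -> ", to, " in the model")
  }
  others <- setdiff(cpt$parents, from)
  octx <- parent_configurations(cpt$parent_states[others])
  fstates <- cpt$parent_states[[from]]
  per <- apply(octx, 1, function(ctx) {
    ctx <- if (length(others)) setNames(as.character(ctx), others) else character(0)
    dists <- lapply(fstates, function(s) {
      cpt_distribution(cpt, c(ctx, setNames(s, from)))
    })
    pairs <- utils::combn(length(fstates), 2)
    max(apply(pairs, 2, function(ij)
      distribution_distance(dists[[ij[1]]], dists[[ij[2]]], distance)))
  })
  value <- if (metric == "average") mean(per) else max(per)
  structure(list(arc = c(from = from, to = to), metric = metric,
                 distance = distance, value = value, per_context = per),
            class = "pd_arc_strength")
}

#' @export
print.pd_arc_strength <- function(x, ...) {
  cat(sprintf("Strength of influence %s -> %s: %.4f (%s %s over %d contexts)\n",
              x$arc[["from"]], x$arc[["to"]], x$value, x$metric, x$distance,
              length(x$per_context)))
  invisible(x)
}

#' Strength of influence of every arc into symptom nodes
#'
#' Convenience wrapper over [arc_strength()] for the disorder-to-symptom
#' layer, ranked by strength.
#'
#' @inheritParams arc_strength
#' @return data.frame with columns `from`, `to`, `value`, sorted descending.
#' @export
arc_strength_table <- function(model, metric = "average",
                               distance = "euclidean") {
  sym <- model$nodes$id[model$nodes$role == "symptom"]
  rows <- do.call(rbind, lapply(sym, function(s) {
    do.call(rbind, lapply(model$parents[[s]], function(d) {
      data.frame(from = d, to = s,
                 value = arc_strength(model, d, s, metric, distance)$value)
    }))
  }))
  rows[order(-rows$value), ]
}

#' Impact of candidate findings on a target
#'
#' For each unobserved candidate observable, computes by exact inference
#' the posterior of the target's deviant state under every possible single
#' finding on that candidate (added to the current evidence) and reports
#' the maximum absolute change from the current posterior. This ranks the
#' observables that contribute most to a diagnosis (or, with a distress
#' target, the most promising therapeutic probes).
#'
#' @param model a `bn2o` model.
#' @param target unobserved node id whose deviant-state posterior is
#'   tracked (`present` for binary nodes; the last state otherwise).
#' @param candidates candidate observable node ids (default: all unobserved
#'   symptom nodes other than the target).
#' @param evidence current evidence, or `NULL`.
#' @return object of class `pd_impact`: data.frame with columns `candidate`,
#'   `impact`, `best_state` (the finding achieving the maximum), ranked
#'   descending; attribute `baseline` holds the current posterior.
#' @export
finding_impact <- function(model, target, candidates = NULL,
                           evidence = NULL) {
  ev <- as_evidence(model, evidence)
  if (target %in% names(ev)) stop_pdnet("target is observed: '", target, "'")
  if (is.null(candidates)) {
    candidates <- setdiff(model$nodes$id[model$nodes$role == "symptom"],
                          c(names(ev), target))
  }
  dev_state <- function(id) {
    st <- model$states[[id]]
    if ("present" %in% st) "present" else st[length(st)]
  }
  pdev <- function(e) {
    posterior_marginals(model, e, target)$posteriors[[target]][[dev_state(target)]]
  }
  base <- pdev(ev)
  rows <- do.call(rbind, lapply(candidates, function(cand) {
    deltas <- vapply(model$states[[cand]], function(s) {
      abs(pdev(c(ev, setNames(s, cand))) - base)
    }, numeric(1))
    data.frame(candidate = cand, impact = max(deltas),
               best_state = names(deltas)[which.max(deltas)])
  }))
  rows <- rows[order(-rows$impact, rows$candidate), ]
  rownames(rows) <- NULL
  structure(rows, baseline = base, target = target,
            class = c("pd_impact", "data.frame"))
}

#' @export
print.pd_impact <- function(x, n = 10, ...) {
  cat(sprintf("Finding impact on %s (current posterior %.4f)\n",
              attr(x, "target"), attr(x, "baseline")))
  print.data.frame(utils::head(x, n), row.names = FALSE)
  if (nrow(x) > n) cat("  ...", nrow(x) - n, "more candidates\n")
  invisible(x)
}
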