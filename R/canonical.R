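# Conditional probability tables (CPTs) under independence of causal
# influence: leaky noisy-OR for binary symptoms, leaky noisy-MAX for graded
# symptoms whose neutral state is the lowest, and an additive evidence-
# weighting model for graded traits whose neutral state is the middle one.

#' Construct a conditional probability table
#'
#' @param variable child node id.
#' @param states child state labels, in order.
#' @param parents parent node ids, in order.
#' @param parent_states named list of state labels per parent.
#' @param prob numeric matrix, one row per parent configuration (rows
#'   enumerate configurations with the *last* parent varying fastest), one
#'   column per child state.
#' @return an object of class `cpt`.
#' @export
new_cpt <- function(variable, states, parents, parent_states, prob) {
  stopifnot(length(parents) == length(parent_states),
            nrow(prob) == prod(lengths(parent_states)) || length(parents) == 0,
            ncol(prob) == length(states))
  if (length(parents) == 0 && nrow(prob) != 1) stop_pdnet("root CPT needs 1 row")
  colnames(prob) <- states
  structure(list(variable = variable, states = states, parents = parents,
                 parent_states = setNames(parent_states, parents), prob = prob),
            class = "cpt")
}

#' @export
print.cpt <- function(x, ...) {
  cat(sprintf("CPT for '%s' (%s) given {%s}: %d rows\n", x$variable,
              paste(x$states, collapse = "/"),
              paste(x$parents, collapse = ", "), nrow(x$prob)))
  cfg <- parent_configurations(x$parent_states)
  out <- cbind(cfg, round(x$prob, 4))
  print(utils::head(out, 16), row.names = FALSE)
  if (nrow(out) > 16) cat("  ...", nrow(out) - 16, "more rows\n")
  invisible(x)
}

#' Enumerate parent configurations in CPT row order
#'
#' Row order places the last parent's states varying fastest, i.e. rows are
#' in row-major order over the parents as declared.
#'
#' @param parent_states named list of state labels per parent.
#' @return data.frame, one row per configuration.
#' @export
parent_configurations <- function(parent_states) {
  if (length(parent_states) == 0) return(data.frame(row.names = 1))
  g <- expand.grid(rev(parent_states), stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, rev(seq_along(g)), drop = FALSE]
  names(g) <- names(parent_states)
  g
}

# Row index of a parent configuration (named character vector).
cpt_row_index <- function(cpt, config) {
  if (length(cpt$parents) == 0) return(1L)
  idx <- 1L
  stride <- 1L
  for (i in rev(seq_along(cpt$parents))) {
    p <- cpt$parents[i]
    st <- match(config[[p]], cpt$parent_states[[i]])
    if (is.na(st)) stop_pdnet("invalid state for parent '", p, "'")
    idx <- idx + (st - 1L) * stride
    stride <- stride * length(cpt$parent_states[[i]])
  }
  idx
}

# Distribution over the child's states for a given parent configuration.
cpt_distribution <- function(cpt, config) {
  cpt$prob[cpt_row_index(cpt, config), ]
}

#' Calibrate a noisy-OR/MAX link strength
#'
#' Converts an elicited single-cause presence probability `q` and the leak
#' `l` (the baseline probability of the target state when every modelled
#' cause is absent) into the link strength `c = (q - l) / (1 - l)`. This is
#' the unique value for which the resulting leaky noisy-OR/MAX reproduces
#' `q` exactly when that cause alone is present.
#'
#' @param q single-cause probability of the target state, in \[0, 1\].
#' @param l leak probability, in \[0, 1).
#' @return the link strength in \[0, 1\].
#' @examples
#' calibrate_link(0.643, 0.364)  # ~0.4387
#' @export
calibrate_link <- function(q, l) {
  if (any(l >= 1)) stop_pdnet("calibration undefined: leak = 1")
  if (any(q < l)) stop_pdnet("calibration error: arc weaker than leak (q < l)")
  (q - l) / (1 - l)
}

#' Leaky noisy-OR conditional probability table
#'
#' For a binary symptom with binary (absent/present) disorder parents:
#' \deqn{P(present \mid config) = 1 - (1 - l)\prod_{i \in present}(1 - c_i)}
#' with link strengths calibrated by [calibrate_link()] so that each single-
#' cause row reproduces the elicited probability exactly, and the all-absent
#' row equals the leak.
#'
#' @param variable child node id.
#' @param q named vector of elicited single-cause probabilities, one per
#'   parent disorder (names are the parent ids, in parent order).
#' @param leak baseline probability of `present` with all parents absent.
#' @return a [new_cpt()] object with states `absent`/`present`.
#' @export
leaky_or_cpt <- function(variable, q, leak) {
  cs <- calibrate_link(q, leak)
  parents <- names(q)
  pstates <- rep(list(BINARY_STATES), length(parents))
  cfg <- parent_configurations(setNames(pstates, parents))
  p_present <- apply(cfg, 1, function(row) {
    on <- row == "present"
    1 - (1 - leak) * prod(1 - cs[on])
  })
  new_cpt(variable, BINARY_STATES, parents, pstates,
          cbind(1 - p_present, p_present))
}

#' Leaky noisy-MAX conditional probability table
#'
#' For a graded (low/medium/high) symptom whose neutral state is the lowest
#' and whose arcs all point toward `high`. Each cause contributes an
#' independent graded effect with mass `c_i` on `high` and the remainder on
#' `low` (a configurable `medium_split` fraction of the remainder may be
#' diverted to `medium`); the leak contributes an effect with mass `leak` on
#' `high`. The child takes the ordinal maximum of all effects, so the
#' single-cause rows reproduce the elicited probabilities and the all-absent
#' row reproduces the baseline.
#'
#' @param variable child node id.
#' @param q named vector of elicited single-cause probabilities of `high`.
#' @param leak baseline probability of `high` with all parents absent.
#' @param medium_split fraction of each effect's non-`high` mass placed on
#'   `medium` (default 0: two-point effects).
#' @return a [new_cpt()] object with states `low`/`medium`/`high`.
#' @export
leaky_max_cpt <- function(variable, q, leak, medium_split = 0) {
  cs <- calibrate_link(q, leak)
  parents <- names(q)
  pstates <- rep(list(BINARY_STATES), length(parents))
  cfg <- parent_configurations(setNames(pstates, parents))
  # cumulative distribution of one graded effect with top mass p
  cum_low <- function(p) (1 - p) * (1 - medium_split)   # P(effect = low)
  cum_med <- function(p) 1 - p                          # P(effect <= medium)
  prob <- t(apply(cfg, 1, function(row) {
    on <- cs[row == "present"]
    eff <- c(on, leak)                                  # active effects + leak
    p_le_low <- prod(cum_low(eff))
    p_le_med <- prod(cum_med(eff))
    c(p_le_low, p_le_med - p_le_low, 1 - p_le_med)
  }))
  new_cpt(variable, GRADED_STATES, parents, pstates, prob)
}

#' Evidence-weighting conditional probability table for graded traits
#'
#' Canonical model for graded (low/medium/high) traits whose neutral state
#' is the middle one and whose causes may push toward either tail. Each arc
#' carries a log-odds weight \eqn{w_i = logit(q_i) - logit(b)} against the
#' baseline of its target tail; for a parent configuration, the raw tail
#' probabilities are
#' \deqn{p_{high} = \sigma(logit(b_{high}) + \sum_{\uparrow} w_i - \sum_{\downarrow} w_i)}
#' and symmetrically for the low tail, so evidence toward one tail counts
#' against the other. When the two tails together would exceed
#' \eqn{1 - \epsilon} they are rescaled proportionally and the middle state
#' keeps the floor \eqn{\epsilon}. With exactly one cause present the target
#' tail reproduces the elicited probability exactly. A probit link (latent
#' normal threshold reading) is available as an option.
#'
#' @param variable child node id.
#' @param q_up,q_down named vectors of single-cause probabilities for arcs
#'   toward `high` resp. `low`; names are parent ids. Either may be empty.
#' @param b_high,b_low tail baselines (must sum below 1).
#' @param epsilon middle-state floor used when the tails overflow.
#' @param link `"logit"` (default) or `"probit"`.
#' @param parents optional parent ordering (defaults to the union of the
#'   names of `q_up` and `q_down`, in that order).
#' @return a [new_cpt()] object with states `low`/`medium`/`high`.
#' @export
evidence_cpt <- function(variable, q_up = numeric(), q_down = numeric(),
                         b_high, b_low, epsilon = 0.01,
                         link = c("logit", "probit"), parents = NULL) {
  link <- match.arg(link)
  if (b_high + b_low >= 1) stop_pdnet("baseline error: b_high + b_low >= 1")
  if (epsilon <= 0 || epsilon >= 1) stop_pdnet("epsilon outside (0,1)")
  if (any(q_up <= b_high)) {
    stop_pdnet("calibration error: arc weaker than its target-tail baseline")
  }
  if (any(q_down <= b_low)) {
    stop_pdnet("calibration error: arc weaker than its target-tail baseline")
  }
  lk <- if (link == "logit") logit else stats::qnorm
  ilk <- if (link == "logit") expit else stats::pnorm
  w_up <- lk(q_up) - lk(b_high)      # weights of arcs toward the high tail
  w_down <- lk(q_down) - lk(b_low)   # weights of arcs toward the low tail
  parents <- parents %||% union(names(q_up), names(q_down))
  pstates <- rep(list(BINARY_STATES), length(parents))
  cfg <- parent_configurations(setNames(pstates, parents))
  prob <- t(apply(cfg, 1, function(row) {
    on <- parents[row == "present"]
    su <- sum(w_up[intersect(on, names(q_up))])
    sd_ <- sum(w_down[intersect(on, names(q_down))])
    p_high <- ilk(lk(b_high) + su - sd_)
    p_low <- ilk(lk(b_low) + sd_ - su)
    tot <- p_high + p_low
    if (tot > 1 - epsilon) {
      scale <- (1 - epsilon) / tot
      p_high <- p_high * scale
      p_low <- p_low * scale
    }
    c(p_low, 1 - p_low - p_high, p_high)
  }))
  new_cpt(variable, GRADED_STATES, parents, pstates, prob)
}

# Build the CPT of one symptom from a parameter set, dispatching on the
# canonical model its framework dictates. Parent order follows ps$disorders.
symptom_cpt <- function(ps, id, epsilon = 0.01, medium_split = 0,
                        link = "logit") {
  fw <- ps$symptoms$framework[match(id, ps$symptoms$id)]
  arcs <- ps$arcs[ps$arcs$symptom == id, ]
  arcs <- arcs[order(match(arcs$disorder, ps$disorders)), ]
  b <- ps$baselines[match(id, ps$baselines$symptom), ]
  model <- framework_model(fw)
  if (model == "leaky_or") {
    leaky_or_cpt(id, setNames(arcs$q, arcs$disorder), b$b_present)
  } else if (model == "leaky_max") {
    if (any(arcs$direction != "high")) {
      stop_pdnet("model-choice error: leaky-MAX symptom '", id,
                 "' has an arc toward 'low'; use the evidence model")
    }
    leaky_max_cpt(id, setNames(arcs$q, arcs$disorder), b$b_high,
                  medium_split = medium_split)
  } else {
    up <- arcs[arcs$direction == "high", ]
    down <- arcs[arcs$direction == "low", ]
    evidence_cpt(id,
                 q_up = setNames(up$q, up$disorder),
                 q_down = setNames(down$q, down$disorder),
                 b_high = b$b_high, b_low = b$b_low,
                 epsilon = epsilon, link = link,
                 parents = arcs$disorder)
  }
}

# Noisy-OR CPT of a distress node over (possibly graded) symptom parents:
# each parent contributes its pd link when in one of its trigger states;
# the leak is zero.
distress_cpt <- function(id, parents, parent_states, pd, triggers) {
  cfg <- parent_configurations(setNames(parent_states, parents))
  p_present <- apply(cfg, 1, function(row) {
    active <- mapply(function(p, st) st %in% triggers[[p]], parents, row)
    1 - prod(1 - pd[active])
  })
  new_cpt(id, BINARY_STATES, parents, parent_states,
          cbind(1 - p_present, p_present))
}
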