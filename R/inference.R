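# Exact inference on the three-layer network.
#
# The BN2O layering makes exact inference by enumeration of the disorder
# configurations (2^5 = 32 for the built-in model) both simple and fast:
# given a disorder configuration, the symptoms are conditionally
# independent, so the likelihood of the evidence factors over the observed
# symptom nodes, and an observed distress node contributes a factor that
# itself factorizes over its (clamped or marginalized) symptom parents
# because its zero-leak noisy-OR "absent" probability is a product of
# independent per-parent terms. All accumulation is in log space with a
# single final normalization.

#' Coerce and validate evidence
#'
#' Evidence is a named character vector (or list) mapping observed node ids
#' to one of their state labels; at most one finding per node.
#'
#' @param model a `bn2o` model.
#' @param evidence named character vector or list, or `NULL` for none.
#' @return a named character vector.
#' @export
as_evidence <- function(model, evidence = NULL) {
  if (is.null(evidence) || length(evidence) == 0) {
    return(setNames(character(0), character(0)))
  }
  ev <- unlist(evidence)
  if (is.null(names(ev)) || any(!nzchar(names(ev)))) {
    stop_pdnet("evidence must be named by node id")
  }
  if (anyDuplicated(names(ev))) {
    stop_pdnet("at most one finding per node: duplicated '",
               names(ev)[duplicated(names(ev))][1], "'")
  }
  for (id in names(ev)) {
    if (!id %in% model$nodes$id) stop_pdnet("evidence on unknown node '", id, "'")
    if (!ev[[id]] %in% model$states[[id]]) {
      stop_pdnet("'", ev[[id]], "' is not a state of node '", id, "'")
    }
  }
  ev
}

# Probability that distress node g is present given a disorder
# configuration, with observed symptom parents clamped and unobserved ones
# marginalized; `clamp` optionally overrides one parent's state.
distress_present_prob <- function(model, g, config, ev, clamp = NULL) {
  links <- model$distress_links[[g]]
  p_absent <- 1
  for (p in names(links$pd)) {
    trig <- links$triggers[[p]]
    if (!is.null(clamp) && p == names(clamp)) {
      act <- as.numeric(clamp[[1]] %in% trig)
    } else if (p %in% names(config)) {          # disorder parent
      act <- as.numeric(config[[p]] %in% trig)
    } else if (p %in% names(ev)) {              # clamped symptom parent
      act <- as.numeric(ev[[p]] %in% trig)
    } else {                                    # marginalized symptom parent
      d <- cpt_distribution(model$cpts[[p]], config)
      act <- sum(d[trig])
    }
    p_absent <- p_absent * (1 - links$pd[[p]] * act)
  }
  1 - p_absent
}

# Enumerate disorder configurations consistent with the evidence and return
# their log prior + log likelihood weights.
config_weights <- function(model, ev) {
  dis <- names(model$priors)
  free <- setdiff(dis, names(ev))
  grid <- parent_configurations(
    setNames(rep(list(BINARY_STATES), length(free)), free))
  n <- max(nrow(grid), 1L)
  role <- setNames(model$nodes$role, model$nodes$id)
  obs_sym <- names(ev)[role[names(ev)] == "symptom"]
  obs_dis <- names(ev)[role[names(ev)] == "distress"]
  configs <- vector("list", n)
  logw <- numeric(n)
  for (i in seq_len(n)) {
    config <- setNames(character(length(dis)), dis)
    for (d in dis) {
      config[[d]] <- if (d %in% names(ev)) ev[[d]] else grid[i, d]
    }
    lw <- sum(log(ifelse(config == "present", model$priors, 1 - model$priors)))
    for (s in obs_sym) {
      lw <- lw + log(cpt_distribution(model$cpts[[s]], config)[[ev[[s]]]])
    }
    for (g in obs_dis) {
      pp <- distress_present_prob(model, g, config, ev)
      lw <- lw + log(if (ev[[g]] == "present") pp else 1 - pp)
    }
    configs[[i]] <- config
    logw[i] <- lw
  }
  list(configs = configs, logw = logw)
}

# Posterior distribution of one target node given a weighted configuration
# enumeration.
target_posterior <- function(model, target, cw, ev, w) {
  role <- model$nodes$role[match(target, model$nodes$id)]
  states <- model$states[[target]]
  post <- setNames(numeric(length(states)), states)
  if (role == "disorder") {
    for (i in seq_along(cw$configs)) {
      st <- cw$configs[[i]][[target]]
      post[[st]] <- post[[st]] + w[i]
    }
    return(post)
  }
  if (role == "symptom") {
    # distress child observed? then the finding couples with the target
    grp <- names(model$distress_links)[vapply(model$distress_links,
      function(l) target %in% names(l$pd), logical(1))]
    grp <- intersect(grp, names(ev))
    for (i in seq_along(cw$configs)) {
      config <- cw$configs[[i]]
      base <- cpt_distribution(model$cpts[[target]], config)
      if (length(grp)) {
        for (g in grp) {
          f <- vapply(states, function(s) {
            pp <- distress_present_prob(model, g, config, ev,
                                        clamp = setNames(list(s), target))
            if (ev[[g]] == "present") pp else 1 - pp
          }, numeric(1))
          base <- base * f
        }
        base <- base / sum(base)
      }
      post <- post + w[i] * base
    }
    return(post)
  }
  for (i in seq_along(cw$configs)) {   # distress target
    pp <- distress_present_prob(model, target, cw$configs[[i]], ev)
    post <- post + w[i] * c(absent = 1 - pp, present = pp)
  }
  post
}

#' Exact posterior marginals
#'
#' Computes the exact posterior distribution of the target nodes given the
#' evidence, by enumeration of the disorder configurations with factored
#' likelihoods (see the module header). Unobserved leaf symptoms contribute
#' a likelihood factor of 1; unobserved symptoms with an observed distress
#' child are marginalized exactly.
#'
#' @param model a `bn2o` model.
#' @param evidence named character vector of findings (node id to state
#'   label); `NULL` for none.
#' @param targets node ids to query (default: the disorder roots). A target
#'   may not be observed.
#' @return an object of class `pd_posterior`: list with `posteriors` (named
#'   list of per-target distributions), `evidence` and `population`.
#' @examples
#' net <- build_network(builtin_cluster_b())
#' posterior_marginals(net, c("DSM-BDL-03" = "present"))
#' @export
posterior_marginals <- function(model, evidence = NULL,
                                targets = names(model$priors)) {
  ev <- as_evidence(model, evidence)
  bad <- intersect(targets, names(ev))
  if (length(bad)) stop_pdnet("target is observed: '", bad[1], "'")
  missing <- setdiff(targets, model$nodes$id)
  if (length(missing)) stop_pdnet("unknown target node '", missing[1], "'")
  cw <- config_weights(model, ev)
  z <- log_sum_exp(cw$logw)
  if (!is.finite(z)) stop_pdnet("zero-probability evidence")
  w <- exp(cw$logw - z)
  posteriors <- lapply(setNames(targets, targets), function(t) {
    p <- target_posterior(model, t, cw, ev, w)
    p / sum(p)
  })
  structure(list(posteriors = posteriors, evidence = ev,
                 population = model$population),
            class = "pd_posterior")
}

#' @export
print.pd_posterior <- function(x, ...) {
  cat(sprintf("Posterior marginals (%s population)\n", x$population))
  if (length(x$evidence)) {
    cat("  evidence:", paste(names(x$evidence), x$evidence, sep = "=",
                             collapse = ", "), "\n")
  } else cat("  evidence: none\n")
  for (t in names(x$posteriors)) {
    p <- x$posteriors[[t]]
    cat(sprintf("  %-28s %s\n", t,
                paste(sprintf("%s %.4f", names(p), p), collapse = "  ")))
  }
  invisible(x)
}

#' @export
as.data.frame.pd_posterior <- function(x, ...) {
  do.call(rbind, lapply(names(x$posteriors), function(t) {
    data.frame(node = t, state = names(x$posteriors[[t]]),
               probability = as.numeric(x$posteriors[[t]]))
  }))
}

#' Posterior probabilities from a fitted network
#'
#' `predict` on a `bn2o` model returns, for each target node, the posterior
#' probability of its deviant reference state given the evidence:
#' `present` for disorders and distress nodes.
#'
#' @param object a `bn2o` model.
#' @param newdata evidence (named character vector of findings), or `NULL`.
#' @param type `"disorder"` (default) or `"distress"`, selecting the target
#'   layer; ignored when `targets` is given.
#' @param targets explicit target node ids.
#' @param ... unused.
#' @return named numeric vector of posterior probabilities.
#' @export
predict.bn2o <- function(object, newdata = NULL,
                         type = c("disorder", "distress"), targets = NULL,
                         ...) {
  type <- match.arg(type)
  if (is.null(targets)) {
    targets <- setdiff(object$nodes$id[object$nodes$role == type],
                       names(as_evidence(object, newdata)))
  }
  rep_ <- posterior_marginals(object, newdata, targets)
  vapply(rep_$posteriors, function(p) {
    if ("present" %in% names(p)) p[["present"]] else p[[length(p)]]
  }, numeric(1))
}

#' Unnormalized probability of one disorder configuration
#'
#' Returns `prior(config) * likelihood(evidence | config)`, the weight this
#' configuration contributes to the enumeration; summing it over all
#' configurations and normalizing reproduces [posterior_marginals()].
#'
#' @param model a `bn2o` model.
#' @param config named character vector assigning a state
#'   (`absent`/`present`) to every disorder root.
#' @param evidence named character vector of findings, or `NULL`.
#' @return a probability.
#' @export
joint_configuration_probability <- function(model, config, evidence = NULL) {
  ev <- as_evidence(model, evidence)
  dis <- names(model$priors)
  if (!setequal(names(config), dis)) {
    stop_pdnet("config must assign every disorder root")
  }
  if (!all(unlist(config) %in% BINARY_STATES)) {
    stop_pdnet("config states must be 'absent' or 'present'")
  }
  ev2 <- c(ev[setdiff(names(ev), dis)], unlist(config))
  cw <- config_weights(model, ev2)
  exp(cw$logw[1])
}

#' Posterior distress profile
#'
#' Exact posterior of every psychological-distress node given the evidence:
#' observed symptom parents are clamped, unobserved ones marginalized under
#' the disorder posterior. Used to rank therapeutic targets.
#'
#' @param model a `bn2o` model.
#' @param evidence named character vector of findings, or `NULL`.
#' @return a `pd_posterior` over all unobserved distress nodes.
#' @export
distress_profile <- function(model, evidence = NULL) {
  ev <- as_evidence(model, evidence)
  targets <- setdiff(model$nodes$id[model$nodes$role == "distress"],
                     names(ev))
  posterior_marginals(model, evidence, targets)
}

#' Read an evidence file
#'
#' Tab-separated text with two columns, `node` and `state`, one finding per
#' row. Symptom labels may use the published spellings.
#'
#' @param model a `bn2o` model (used to resolve labels and validate states).
#' @param path file path.
#' @return a named character vector of findings.
#' @export
read_evidence <- function(model, path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", fileEncoding = "UTF-8")
  if (!all(c("node", "state") %in% names(tab))) {
    stop_pdnet("evidence file needs 'node' and 'state' columns")
  }
  ids <- vapply(tab$node, function(x) {
    if (x %in% model$nodes$id) x else match_symptom(model$parameters, x)
  }, character(1), USE.NAMES = FALSE)
  as_evidence(model, setNames(tab$state, ids))
}
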