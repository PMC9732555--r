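#' Assemble the three-layer diagnostic network
#'
#' Builds the augmented BN2O model from an elicited parameter set: binary
#' disorder roots with priors taken from the selected population's
#' prevalence column, one symptom node per catalogue entry with a CPT
#' generated by the canonical model its framework dictates (leaky noisy-OR
#' for DSM criteria and defense mechanisms, leaky noisy-MAX for the
#' level-of-personality-functioning scales, the evidence-weighting model for
#' five-factor traits and biosocial polarities), and a binary
#' psychological-distress layer attached by [attach_distress_layer()].
#'
#' @param ps a parameter set (see [builtin_cluster_b()]).
#' @param population `"clinical"` or `"general"`; selects the prevalence
#'   column used as disorder priors.
#' @param distress attach the distress layer (default `TRUE`).
#' @param epsilon middle-state floor of the evidence-weighting model.
#' @param medium_split medium share of leaky noisy-MAX effects.
#' @param link link function of the evidence-weighting model
#'   (`"logit"` or `"probit"`).
#' @return an object of class `bn2o`: a list with elements `nodes`
#'   (data.frame of `id`, `role`), `states`, `parents`, `priors`, `cpts`,
#'   `triggers` (deviant states that activate distress links), `population`,
#'   `parameters` and `options`.
#' @examples
#' net <- build_network(builtin_cluster_b(), population = "clinical")
#' net
#' predict(net)["BDL"]  # prior recovery: 0.193
#' @export
build_network <- function(ps, population = c("clinical", "general"),
                          distress = TRUE, epsilon = 0.01, medium_split = 0,
                          link = c("logit", "probit")) {
  population <- match.arg(population)
  link <- match.arg(link)
  report <- validate_parameter_set(ps)
  if (nrow(report)) {
    stop_pdnet("invalid parameter set (", nrow(report), " violations), e.g.: ",
               report$item[1], ": ", report$message[1])
  }
  disorders <- ps$disorders
  priors <- setNames(ps$prevalence[[population]],
                     ps$prevalence$disorder)[disorders]
  nodes <- data.frame(id = disorders, role = "disorder")
  states <- setNames(rep(list(BINARY_STATES), length(disorders)), disorders)
  parents <- setNames(rep(list(character()), length(disorders)), disorders)
  cpts <- list()
  triggers <- list()
  for (id in ps$symptoms$id) {
    cpt <- symptom_cpt(ps, id, epsilon = epsilon,
                       medium_split = medium_split, link = link)
    nodes <- rbind(nodes, data.frame(id = id, role = "symptom"))
    states[[id]] <- cpt$states
    parents[[id]] <- cpt$parents
    cpts[[id]] <- cpt
    arcs <- ps$arcs[ps$arcs$symptom == id, ]
    triggers[[id]] <- unique(ifelse(arcs$direction == "present",
                                    "present", arcs$direction))
  }
  model <- structure(
    list(nodes = nodes, states = states, parents = parents, priors = priors,
         cpts = cpts, triggers = triggers, population = population,
         parameters = ps,
         options = list(epsilon = epsilon, medium_split = medium_split,
                        link = link)),
    class = "bn2o")
  if (distress) model <- attach_distress_layer(model, ps)
  model
}

#' Attach the psychological-distress layer
#'
#' Adds one binary distress node per symptom group: a leaky noisy-OR child
#' of the group's symptom nodes with zero leak, each link strength being
#' that symptom's elicited distress probability. A graded parent activates
#' its link from any deviant state targeted by one of its arcs. A final
#' general-distress node is a zero-leak noisy-OR child of the disorder roots
#' with the disorder-level distress probabilities as link strengths.
#'
#' @param model a `bn2o` model without (or with a stale) distress layer.
#' @param ps the parameter set the distress links are read from.
#' @return the model with distress nodes appended.
#' @export
attach_distress_layer <- function(model, ps) {
  model$nodes <- model$nodes[model$nodes$role != "distress", , drop = FALSE]
  model$distress_links <- list()
  groups <- unique(ps$distress$group)
  for (g in groups) {
    members <- ps$distress[ps$distress$group == g, ]
    if (nrow(members) == 0) stop_pdnet("structure error: empty distress group ", g)
    missing <- setdiff(members$source, model$nodes$id)
    if (length(missing)) {
      stop_pdnet("structure error: distress link from unknown node ",
                 missing[1])
    }
    pid <- members$source
    cpt <- distress_cpt(g, pid, model$states[pid],
                        setNames(members$pd, pid), model$triggers[pid])
    model$nodes <- rbind(model$nodes, data.frame(id = g, role = "distress"))
    model$states[[g]] <- BINARY_STATES
    model$parents[[g]] <- pid
    model$cpts[[g]] <- cpt
    model$distress_links[[g]] <- list(pd = setNames(members$pd, pid),
                                      triggers = model$triggers[pid])
  }
  g <- "PD-General"
  dis <- ps$disorders
  cpt <- distress_cpt(g, dis, rep(list(BINARY_STATES), length(dis)),
                      setNames(ps$prevalence$pd, ps$prevalence$disorder)[dis],
                      setNames(rep(list("present"), length(dis)), dis))
  model$nodes <- rbind(model$nodes, data.frame(id = g, role = "distress"))
  model$states[[g]] <- BINARY_STATES
  model$parents[[g]] <- dis
  model$cpts[[g]] <- cpt
  model$distress_links[[g]] <- list(
    pd = setNames(ps$prevalence$pd, ps$prevalence$disorder)[dis],
    triggers = setNames(rep(list("present"), length(dis)), dis))
  model
}

#' Validate an assembled network
#'
#' Structural and numerical checks: three-layer acyclic topology (edges only
#' from disorders to symptoms and from symptoms or disorders into distress
#' nodes), priors in (0, 1), CPT rows normalized to 1 within 1e-12, CPT
#' dimensions consistent with the declared parent state spaces. Violations
#' are reported, never raised; an empty report means the model is valid.
#'
#' @param model a `bn2o` model.
#' @return data.frame with columns `rule`, `item`, `message`.
#' @export
validate_network <- function(model) {
  bad <- list()
  note <- function(rule, item, message) {
    bad[[length(bad) + 1L]] <<- data.frame(rule = rule, item = item,
                                           message = message)
  }
  role <- setNames(model$nodes$role, model$nodes$id)
  for (id in model$nodes$id) {
    for (p in model$parents[[id]]) {
      if (!p %in% model$nodes$id) {
        note("dangling-parent", id, paste0("parent '", p, "' undeclared"))
        next
      }
      ok <- switch(role[[id]],
        disorder = FALSE,
        symptom  = role[[p]] == "disorder",
        distress = role[[p]] %in% c("symptom", "disorder"))
      if (!ok) {
        note("layering", id,
             sprintf("edge %s (%s) -> %s (%s) violates layering",
                     p, role[[p]], id, role[[id]]))
      }
    }
  }
  for (d in names(model$priors)) {
    if (is.na(model$priors[[d]]) || model$priors[[d]] <= 0 ||
        model$priors[[d]] >= 1) {
      note("prior-range", d, "prior outside (0,1)")
    }
  }
  for (id in names(model$cpts)) {
    cpt <- model$cpts[[id]]
    rs <- rowSums(cpt$prob)
    if (any(abs(rs - 1) > 1e-12)) {
      note("normalization", id,
           sprintf("CPT row sums deviate from 1 by up to %.3g",
                   max(abs(rs - 1))))
    }
    if (any(cpt$prob < -1e-15)) note("negative-probability", id,
                                     "CPT has negative entries")
    if (nrow(cpt$prob) != prod(lengths(cpt$parent_states))) {
      note("cpt-shape", id, "CPT row count does not match parent state space")
    }
    if (!identical(cpt$parents, model$parents[[id]])) {
      note("cpt-parents", id, "CPT parents disagree with graph parents")
    }
  }
  if (length(bad)) do.call(rbind, bad)
  else data.frame(rule = character(), item = character(), message = character())
}

#' @export
print.bn2o <- function(x, ...) {
  census <- table(factor(x$nodes$role, c("disorder", "symptom", "distress")))
  cat("Augmented BN2O diagnostic network\n")
  cat(sprintf("  %d nodes: %d disorders, %d symptoms, %d distress\n",
              nrow(x$nodes), census[["disorder"]], census[["symptom"]],
              census[["distress"]]))
  cat(sprintf("  population: %s; priors: %s\n", x$population,
              paste(sprintf("%s %.3f", names(x$priors), x$priors),
                    collapse = ", ")))
  invisible(x)
}

#' @export
summary.bn2o <- function(object, ...) {
  edges <- sum(lengths(object$parents))
  sym <- object$nodes$id[object$nodes$role == "symptom"]
  fan <- lengths(object$parents[sym])
  out <- list(
    nodes = table(factor(object$nodes$role,
                         c("disorder", "symptom", "distress"))),
    edges = edges,
    population = object$population,
    priors = object$priors,
    symptom_parent_counts = table(fan),
    options = object$options)
  class(out) <- "summary.bn2o"
  out
}

#' @export
print.summary.bn2o <- function(x, ...) {
  cat("Augmented BN2O diagnostic network\n")
  cat("  node census: ", paste(sprintf("%s %d", names(x$nodes), x$nodes),
                               collapse = ", "), "\n", sep = "")
  cat("  directed edges:", x$edges, "\n")
  cat("  population:", x$population, "\n")
  cat("  priors:\n")
  print(round(x$priors, 4))
  cat("  symptom in-degree distribution:\n")
  print(x$symptom_parent_counts)
  invisible(x)
}

#' Forward-sample complete cases from the network
#'
#' Ancestral sampling: disorders from their priors, then symptoms and
#' distress nodes from their CPTs.
#'
#' @param object a `bn2o` model.
#' @param nsim number of cases.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data.frame of sampled states, one row per case, one column per
#'   node.
#' @export
simulate.bn2o <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  order <- model_topological_order(object)
  out <- matrix(NA_character_, nrow = nsim, ncol = length(order),
                dimnames = list(NULL, order))
  for (i in seq_len(nsim)) {
    case <- character(0)
    for (id in order) {
      if (id %in% names(object$priors)) {
        p <- object$priors[[id]]
        case[[id]] <- sample(BINARY_STATES, 1, prob = c(1 - p, p))
      } else {
        d <- cpt_distribution(object$cpts[[id]], case)
        case[[id]] <- sample(object$states[[id]], 1, prob = d)
      }
    }
    out[i, ] <- case[order]
  }
  as.data.frame(out)
}

model_topological_order <- function(model) {
  r <- model$nodes$role
  c(model$nodes$id[r == "disorder"], model$nodes$id[r == "symptom"],
    model$nodes$id[r == "distress"])
}

#' Plot the layered network
#'
#' Simple base-graphics rendering of the three layers (disorders on top,
#' symptoms in the middle, distress nodes at the bottom) with the directed
#' edges between them.
#'
#' @param x a `bn2o` model.
#' @param label_cex label size; labels are dropped when a layer is crowded.
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.bn2o <- function(x, label_cex = 0.5, ...) {
  roles <- c("disorder", "symptom", "distress")
  ys <- c(disorder = 3, symptom = 2, distress = 1)
  pos <- do.call(rbind, lapply(roles, function(r) {
    ids <- x$nodes$id[x$nodes$role == r]
    if (!length(ids)) return(NULL)
    data.frame(id = ids, x = seq(0, 1, length.out = length(ids) + 2)[-c(1, length(ids) + 2)],
               y = ys[[r]])
  }))
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0.5, 3.5), axes = FALSE,
                 xlab = "", ylab = "", ...)
  for (id in x$nodes$id) {
    for (p in x$parents[[id]]) {
      a <- pos[pos$id == p, ]; b <- pos[pos$id == id, ]
      graphics::segments(a$x, a$y, b$x, b$y, col = "grey70")
    }
  }
  cols <- c(disorder = "gold", symptom = "steelblue1", distress = "tomato")
  graphics::points(pos$x, pos$y, pch = 21,
                   bg = cols[x$nodes$role[match(pos$id, x$nodes$id)]])
  if (nrow(pos) <= 40) {
    graphics::text(pos$x, pos$y + 0.12, pos$id, cex = label_cex, srt = 45)
  }
  invisible(x)
}
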