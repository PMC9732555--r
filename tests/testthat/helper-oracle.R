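# Independent oracles and small fixtures shared across tests.

# Full-joint enumeration oracle: builds the complete joint table of a model
# by brute force (own row lookup, own enumeration) and computes marginals.
# Kept deliberately independent of the package's inference engine.
oracle_joint <- function(model) {
  ids <- c(model$nodes$id[model$nodes$role == "disorder"],
           model$nodes$id[model$nodes$role == "symptom"],
           model$nodes$id[model$nodes$role == "distress"])
  grid <- expand.grid(model$states[ids], stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  p <- rep(1, nrow(grid))
  for (id in ids) {
    if (id %in% names(model$priors)) {
      pr <- model$priors[[id]]
      p <- p * ifelse(grid[[id]] == "present", pr, 1 - pr)
    } else {
      cpt <- model$cpts[[id]]
      cfg <- parent_configurations(cpt$parent_states)
      key <- do.call(paste, c(cfg, sep = "\r"))
      row <- match(do.call(paste, c(grid[cpt$parents], sep = "\r")), key)
      p <- p * cpt$prob[cbind(row, match(grid[[id]], cpt$states))]
    }
  }
  list(grid = grid, p = p)
}

oracle_posterior <- function(model, evidence, target) {
  jt <- oracle_joint(model)
  keep <- rep(TRUE, nrow(jt$grid))
  for (id in names(evidence)) keep <- keep & jt$grid[[id]] == evidence[[id]]
  w <- jt$p[keep]
  states <- model$states[[target]]
  post <- vapply(states, function(s)
    sum(w[jt$grid[[target]][keep] == s]), numeric(1))
  post / sum(post)
}

# Brute-force noisy-OR oracle: enumerate independent inhibitor variables.
oracle_noisy_or <- function(c_on, leak) {
  # P(present) for active causes with strengths c_on plus a leak cause
  cs <- c(c_on, leak)
  n <- length(cs)
  total <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    pr <- prod(ifelse(bits, cs, 1 - cs))
    if (any(bits)) total <- total + pr   # effect fires if any cause succeeds
  }
  total
}

# Two-node toy knowledge base: one disorder (prior set at build), one
# binary symptom with q = 0.8, baseline 0.1.
toy_parameter_set <- function(prior_clinical = 0.2) {
  parameter_set(
    symptoms = data.frame(id = "S1", framework = "DSM"),
    arcs = data.frame(symptom = "S1", disorder = "D1",
                      direction = "present", q = 0.8),
    baselines = data.frame(symptom = "S1", b_present = 0.1,
                           b_high = NA_real_, b_low = NA_real_),
    distress = data.frame(source = character(), pd = numeric(),
                          group = character()),
    prevalence = data.frame(disorder = "D1", clinical = prior_clinical,
                            general = 0.02, pd = 0.5))
}

# A shared built-in parameter set and clinical network (built once per run).
builtin_ps <- builtin_cluster_b()
builtin_net <- build_network(builtin_ps, population = "clinical")
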