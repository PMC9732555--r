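# Seeded synthetic parameter-set generator, used for property-based
# testing of the canonical models and the inference engine on networks
# small enough for full-joint enumeration.

#' Generate a random, valid parameter set
#'
#' Draws a reproducible random knowledge base honouring every structural
#' invariant (arcs strictly stronger than their target-state baselines,
#' graded tail baselines summing below one, every symptom with at least one
#' arc, clinical prevalence above general). Frameworks are sampled so that
#' all three canonical CPT models are exercised: binary symptoms use the
#' leaky noisy-OR, graded ones split between the leaky noisy-MAX (neutral
#' low) and the evidence-weighting model (neutral medium). The ranges mirror
#' the elicited cluster-B tables (baselines 0.05-0.45, arc strengths up to
#' 0.95, distress links 0.2-0.9, clinical prevalences 0.05-0.25).
#'
#' @param seed integer seed; identical seeds give identical sets. The
#'   caller's RNG state is left untouched.
#' @param n_disorders,n_symptoms sizes (>= 1).
#' @param graded_fraction expected fraction of graded (three-state)
#'   symptoms.
#' @param with_distress include distress links and groups.
#' @return a [parameter_set()] that passes [validate_parameter_set()].
#' @export
generate_fixture <- function(seed, n_disorders = 2, n_symptoms = 4,
                             graded_fraction = 0.5, with_distress = TRUE) {
  if (n_disorders < 1 || n_symptoms < 1) {
    stop_pdnet("infeasible constraints: sizes must be >= 1")
  }
  if (graded_fraction < 0 || graded_fraction > 1) {
    stop_pdnet("infeasible constraints: graded_fraction outside [0,1]")
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  disorders <- sprintf("D%d", seq_len(n_disorders))
  clinical <- stats::runif(n_disorders, 0.05, 0.25)
  prevalence <- data.frame(
    disorder = disorders,
    clinical = clinical,
    general = clinical * stats::runif(n_disorders, 0.1, 0.5),
    pd = stats::runif(n_disorders, 0.3, 0.9))

  symptoms <- arcs <- baselines <- distress <- NULL
  for (i in seq_len(n_symptoms)) {
    id <- sprintf("S%d", i)
    graded <- stats::runif(1) < graded_fraction
    fw <- if (!graded) "DSM" else sample(c("LPF", "FFM"), 1)
    symptoms <- rbind(symptoms, data.frame(id = id, framework = fw))
    if (fw == "DSM") {
      b <- data.frame(symptom = id, b_present = stats::runif(1, 0.05, 0.45),
                      b_high = NA_real_, b_low = NA_real_)
    } else if (fw == "LPF") {
      b <- data.frame(symptom = id, b_present = NA_real_,
                      b_high = stats::runif(1, 0.05, 0.30), b_low = NA_real_)
    } else {
      b <- data.frame(symptom = id, b_present = NA_real_,
                      b_high = stats::runif(1, 0.05, 0.40),
                      b_low = stats::runif(1, 0.05, 0.40))
      while (b$b_high + b$b_low >= 0.95) b$b_low <- b$b_low / 2
    }
    baselines <- rbind(baselines, b)
    k <- sample(seq_len(min(3, n_disorders)), 1)
    for (d in sort(sample(disorders, k))) {
      dir <- switch(fw, DSM = "present", LPF = "high",
                    FFM = sample(c("high", "low"), 1))
      bl <- switch(dir, present = b$b_present, high = b$b_high, low = b$b_low)
      arcs <- rbind(arcs, data.frame(
        symptom = id, disorder = d, direction = dir,
        q = stats::runif(1, min(bl + 0.05, 0.94), 0.95)))
    }
    if (with_distress) {
      distress <- rbind(distress, data.frame(
        source = id, pd = stats::runif(1, 0.2, 0.9),
        group = paste0("PD-", fw)))
    }
  }
  if (is.null(distress)) {
    distress <- data.frame(source = character(), pd = numeric(),
                           group = character())
  }
  parameter_set(symptoms, arcs, baselines, distress, prevalence,
                disorders = disorders)
}
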