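#' @keywords internal
"_PACKAGE"

# Canonical disorder codes of the cluster-B model, in table column order.
CLUSTER_B_DISORDERS <- c("ATS", "BDL", "NAR", "HST", "PAG")

# Framework tags and the state space / canonical model each one dictates.
FRAMEWORKS <- c("DSM", "DEFENSE", "LPF", "FFM", "BIOSOCIAL")

BINARY_STATES <- c("absent", "present")
GRADED_STATES <- c("low", "medium", "high")

framework_neutral <- function(framework) {
  switch(framework,
    DSM = "absent", DEFENSE = "absent",
    LPF = "low",
    FFM = "medium", BIOSOCIAL = "medium",
    stop("unknown framework: ", framework)
  )
}

framework_states <- function(framework) {
  if (framework %in% c("DSM", "DEFENSE")) BINARY_STATES else GRADED_STATES
}

# Canonical model used for a symptom's CPT, decided by its framework.
framework_model <- function(framework) {
  switch(framework,
    DSM = "leaky_or", DEFENSE = "leaky_or",
    LPF = "leaky_max",
    FFM = "evidence", BIOSOCIAL = "evidence",
    stop("unknown framework: ", framework)
  )
}

logit <- function(p) stats::qlogis(p)
expit <- function(x) stats::plogis(x)

# log(sum(exp(x))) without overflow; -Inf-safe.
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pdnet <- function(...) stop(..., call. = FALSE)

# Normalize a printed symptom label ("DSM - BDL 03", "LPF Empathy",
# "MD - Acting out") to the package's slug form ("DSM-BDL-03", ...).
normalize_symptom_id <- function(x) {
  s <- trimws(x)
  s <- gsub("[[:space:]]*-[[:space:]]*", "-", s)
  s <- gsub("[[:space:]]+", "-", s)
  # zero-pad bare DSM item numbers ("DSM-BDL-3" -> "DSM-BDL-03")
  s <- sub("^((DSM)-[A-Z]{3})-([0-9])$", "\\1-0\\3", s)
  s
}

# Aliases for spellings used in the published LR tables.
SYMPTOM_ALIASES <- c(
  "MD-Passive-aggressive" = "MD-Passive-aggression"
)

#' Resolve a symptom label to its canonical identifier
#'
#' Accepts the package's slug identifiers (`"DSM-BDL-03"`, `"LPF-Empathy"`)
#' as well as the spellings used in the published tables
#' (`"DSM - BDL 03"`, `"LPF Empathy"`, `"MD - Acting out"`). Matching is
#' case-insensitive on the normalized slug.
#'
#' @param ps a parameter set (see [builtin_cluster_b()]).
#' @param x character vector of symptom labels.
#' @return character vector of canonical symptom ids.
#' @export
match_symptom <- function(ps, x) {
  ids <- ps$symptoms$id
  out <- vapply(x, function(lab) {
    slug <- normalize_symptom_id(lab)
    if (slug %in% names(SYMPTOM_ALIASES)) slug <- SYMPTOM_ALIASES[[slug]]
    hit <- ids[tolower(ids) == tolower(slug)]
    if (length(hit) != 1L) stop_pdnet("unknown symptom label: '", lab, "'")
    hit
  }, character(1), USE.NAMES = FALSE)
  out
}
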