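#' Construct a parameter set
#'
#' A parameter set is the elicited knowledge base from which the diagnostic
#' network is assembled: the symptom catalogue, the disorder-to-symptom
#' influence arcs with their single-cause presence probabilities, the
#' population baselines, the psychological-distress links and the disorder
#' prevalences. All probabilities are stored as fractions in \[0, 1\].
#'
#' @param symptoms data.frame with columns `id`, `framework`
#'   (one of `"DSM"`, `"DEFENSE"`, `"LPF"`, `"FFM"`, `"BIOSOCIAL"`).
#' @param arcs data.frame with columns `symptom`, `disorder`, `direction`
#'   (`"present"` for binary symptoms, `"high"` or `"low"` for graded ones)
#'   and `q`, the elicited probability of the target state given that
#'   disorder alone.
#' @param baselines data.frame with columns `symptom`, `b_present`,
#'   `b_high`, `b_low` (`NA` where not applicable). Binary symptoms use
#'   `b_present`; graded symptoms use the two tail baselines.
#' @param distress data.frame with columns `source` (symptom id), `pd`
#'   (probability that the symptom causes clinically significant distress)
#'   and `group` (identifier of the distress node it feeds).
#' @param prevalence data.frame with columns `disorder`, `clinical`,
#'   `general` and `pd` (disorder-level distress probability).
#' @param disorders character vector of disorder codes, in display order.
#' @return an object of class `pd_parameters`.
#' @seealso [builtin_cluster_b()], [load_parameter_set()],
#'   [validate_parameter_set()]
#' @export
parameter_set <- function(symptoms, arcs, baselines, distress, prevalence,
                          disorders = prevalence$disorder) {
  ps <- structure(
    list(
      symptoms   = as.data.frame(symptoms),
      arcs       = as.data.frame(arcs),
      baselines  = as.data.frame(baselines),
      distress   = as.data.frame(distress),
      prevalence = as.data.frame(prevalence),
      disorders  = as.character(disorders)
    ),
    class = "pd_parameters"
  )
  ps
}

#' @export
print.pd_parameters <- function(x, ...) {
  cat("Elicited parameter set\n")
  cat(sprintf("  disorders: %s\n", paste(x$disorders, collapse = ", ")))
  tab <- table(factor(x$symptoms$framework, levels = FRAMEWORKS))
  cat(sprintf("  symptoms:  %d (%s)\n", nrow(x$symptoms),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  influence arcs: %d\n", nrow(x$arcs)))
  cat(sprintf("  distress links: %d in %d groups (+1 general)\n",
              nrow(x$distress), length(unique(x$distress$group))))
  invisible(x)
}

symptom_states <- function(ps, id) {
  fw <- ps$symptoms$framework[match(id, ps$symptoms$id)]
  framework_states(fw)
}

symptom_neutral <- function(ps, id) {
  fw <- ps$symptoms$framework[match(id, ps$symptoms$id)]
  framework_neutral(fw)
}

# Baseline probability of a given deviant state of a symptom.
baseline_of <- function(ps, id, state) {
  b <- ps$baselines[match(id, ps$baselines$symptom), ]
  switch(state,
    present = b$b_present,
    high    = b$b_high,
    low     = b$b_low,
    stop_pdnet("no baseline for state '", state, "'")
  )
}

# ---------------------------------------------------------------------------
# Tabular file layout ("cluster-b" dialect):
# one tab-separated file per framework table with header
#   symptom  ATS  BDL  NAR  HST  PAG  norm  norm_low  pd  pd_group
# plus prevalence.tsv with header  disorder  clinical  general  pd.
# All probabilities are percentages; empty cells mean "no arc" / "no link";
# graded-symptom arc cells carry a "+" (toward high) or "-" (toward low)
# prefix. For FFM tables the single norm cell is the baseline of BOTH tails;
# biosocial tables may print separate high (norm) and low (norm_low) tails,
# a missing low tail defaulting to the high value.
# ---------------------------------------------------------------------------

FRAMEWORK_FILES <- c(DSM = "dsm.tsv", DEFENSE = "defense.tsv",
                     LPF = "lpf.tsv", FFM = "ffm.tsv",
                     BIOSOCIAL = "biosocial.tsv")

read_tsv_file <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, na.strings = "",
                    colClasses = "character", check.names = FALSE,
                    fileEncoding = "UTF-8")
}

parse_pct <- function(x, file, row, field) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) {
    stop_pdnet(sprintf("load error in %s, row %d, field '%s': '%s' is not a number",
                       basename(file), row, field, x))
  }
  if (v < 0 || v > 100) {
    stop_pdnet(sprintf("load error in %s, row %d, field '%s': %s outside [0,100]",
                       basename(file), row, field, x))
  }
  v / 100
}

#' Load a parameter set from tabular files
#'
#' Reads the documented tab-separated layout: one file per framework table
#' (`dsm.tsv`, `defense.tsv`, `lpf.tsv`, `ffm.tsv`, `biosocial.tsv`) plus
#' `prevalence.tsv`, all under `path`. Percentages are converted to
#' fractions on load; every subsequent computation is on the \[0, 1\] scale.
#'
#' @param path directory containing the parameter files.
#' @param dialect tabular layout name; only `"cluster-b"` is defined.
#' @return a validated [parameter_set()].
#' @export
load_parameter_set <- function(path, dialect = "cluster-b") {
  dialect <- match.arg(dialect)
  symptoms <- arcs <- baselines <- distress <- NULL
  for (fw in names(FRAMEWORK_FILES)) {
    file <- file.path(path, FRAMEWORK_FILES[[fw]])
    if (!file.exists(file)) {
      stop_pdnet("load error: missing table file ", file)
    }
    tab <- read_tsv_file(file)
    need <- c("symptom", CLUSTER_B_DISORDERS, "norm", "norm_low", "pd", "pd_group")
    if (!identical(names(tab), need)) {
      stop_pdnet("load error in ", basename(file), ": malformed header row")
    }
    graded <- !(fw %in% c("DSM", "DEFENSE"))
    for (i in seq_len(nrow(tab))) {
      id <- tab$symptom[i]
      if (is.na(id) || !nzchar(id)) {
        stop_pdnet(sprintf("load error in %s, row %d, field 'symptom': empty id",
                           basename(file), i))
      }
      symptoms <- rbind(symptoms, data.frame(id = id, framework = fw))
      for (d in CLUSTER_B_DISORDERS) {
        cellv <- tab[[d]][i]
        if (is.na(cellv)) next
        dir <- "present"
        if (graded) {
          dir <- if (fw == "LPF") "high"
                 else if (startsWith(cellv, "-")) "low"
                 else "high"
          cellv <- sub("^[+-]", "", cellv)
        }
        arcs <- rbind(arcs, data.frame(
          symptom = id, disorder = d, direction = dir,
          q = parse_pct(cellv, file, i, d)))
      }
      norm <- parse_pct(tab$norm[i], file, i, "norm")
      if (!graded) {
        baselines <- rbind(baselines, data.frame(
          symptom = id, b_present = norm, b_high = NA_real_, b_low = NA_real_))
      } else if (fw == "LPF") {
        baselines <- rbind(baselines, data.frame(
          symptom = id, b_present = NA_real_, b_high = norm, b_low = NA_real_))
      } else {
        lo <- if (is.na(tab$norm_low[i])) norm
              else parse_pct(tab$norm_low[i], file, i, "norm_low")
        baselines <- rbind(baselines, data.frame(
          symptom = id, b_present = NA_real_, b_high = norm, b_low = lo))
      }
      if (!is.na(tab$pd[i])) {
        grp <- tab$pd_group[i]
        if (is.na(grp) || !nzchar(grp)) {
          stop_pdnet(sprintf("load error in %s, row %d, field 'pd_group': %s",
                             basename(file), i, "distress link without a group"))
        }
        distress <- rbind(distress, data.frame(
          source = id, pd = parse_pct(tab$pd[i], file, i, "pd"), group = grp))
      }
    }
  }
  if (is.null(symptoms)) stop_pdnet("load error: no symptom rows")

  pfile <- file.path(path, "prevalence.tsv")
  ptab <- read_tsv_file(pfile)
  if (!identical(names(ptab), c("disorder", "clinical", "general", "pd"))) {
    stop_pdnet("load error in prevalence.tsv: malformed header row")
  }
  unknown <- setdiff(ptab$disorder, CLUSTER_B_DISORDERS)
  if (length(unknown)) {
    stop_pdnet("load error in prevalence.tsv: unknown disorder label ",
               paste(unknown, collapse = ", "))
  }
  prevalence <- data.frame(
    disorder = ptab$disorder,
    clinical = vapply(seq_len(nrow(ptab)), function(i)
      parse_pct(ptab$clinical[i], pfile, i, "clinical"), numeric(1)),
    general = vapply(seq_len(nrow(ptab)), function(i)
      parse_pct(ptab$general[i], pfile, i, "general"), numeric(1)),
    pd = vapply(seq_len(nrow(ptab)), function(i)
      parse_pct(ptab$pd[i], pfile, i, "pd"), numeric(1)))

  parameter_set(symptoms, arcs, baselines, distress, prevalence,
                disorders = prevalence$disorder)
}

#' Write a parameter set back to the tabular layout
#'
#' Inverse of [load_parameter_set()]: emits the same file set (values on the
#' percentage scale) so that a load/write cycle round-trips field for field.
#'
#' @param ps a parameter set.
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(ps, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(p) {
    ifelse(is.na(p), "", sub("\\.?0+$", "", sprintf("%.6f", p * 100)))
  }
  for (fw in names(FRAMEWORK_FILES)) {
    ids <- ps$symptoms$id[ps$symptoms$framework == fw]
    rows <- lapply(ids, function(id) {
      cells <- setNames(rep("", length(CLUSTER_B_DISORDERS)), CLUSTER_B_DISORDERS)
      sel <- ps$arcs[ps$arcs$symptom == id, ]
      for (j in seq_len(nrow(sel))) {
        sign <- if (fw %in% c("FFM", "BIOSOCIAL")) {
          if (sel$direction[j] == "low") "-" else "+"
        } else ""
        cells[[sel$disorder[j]]] <- paste0(sign, fmt(sel$q[j]))
      }
      b <- ps$baselines[ps$baselines$symptom == id, ]
      norm <- if (fw %in% c("DSM", "DEFENSE")) fmt(b$b_present) else fmt(b$b_high)
      norm_low <- if (fw == "BIOSOCIAL") fmt(b$b_low) else ""
      if (fw == "FFM") norm_low <- ""  # single printed value covers both tails
      di <- ps$distress[ps$distress$source == id, ]
      pd <- if (nrow(di)) fmt(di$pd) else ""
      grp <- if (nrow(di)) di$group else ""
      c(id, cells, norm, norm_low, pd, grp)
    })
    m <- do.call(rbind, rows)
    colnames(m) <- c("symptom", CLUSTER_B_DISORDERS, "norm", "norm_low",
                     "pd", "pd_group")
    utils::write.table(m, file.path(path, FRAMEWORK_FILES[[fw]]),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  pm <- cbind(disorder = ps$prevalence$disorder,
              clinical = fmt(ps$prevalence$clinical),
              general = fmt(ps$prevalence$general),
              pd = fmt(ps$prevalence$pd))
  utils::write.table(pm, file.path(path, "prevalence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' The built-in cluster-B knowledge base
#'
#' Returns the packaged transcription of the full elicited knowledge base
#' for the five dramatic/emotional personality disorders: 86 symptom
#' variables (40 DSM criteria, 10 defense mechanisms, 4 level-of-personality-
#' functioning scales, 26 five-factor-model traits, 6 biosocial polarities),
#' their influence arcs and baselines, the distress links and the clinical
#' and general-population prevalences.
#'
#' @return a [parameter_set()].
#' @examples
#' ps <- builtin_cluster_b()
#' nrow(ps$symptoms)  # 86
#' @export
builtin_cluster_b <- function() {
  load_parameter_set(system.file("extdata", "cluster_b", package = "pdnet"))
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the knowledge base and reports all
#' violations; it never raises. An empty report means the set is valid.
#' Checked: probabilities in range, arcs strictly stronger than the baseline
#' of their target state (required by canonical-model calibration), graded
#' tail baselines summing below one, dangling references, exactly one
#' baseline per symptom, direction/state-space agreement, and clinical
#' prevalence exceeding general prevalence.
#'
#' @param ps a parameter set.
#' @return data.frame with columns `rule`, `item`, `message`; zero rows if
#'   and only if `ps` is valid.
#' @export
validate_parameter_set <- function(ps) {
  bad <- list()
  note <- function(rule, item, message) {
    bad[[length(bad) + 1L]] <<- data.frame(rule = rule, item = item,
                                           message = message)
  }
  ids <- ps$symptoms$id
  if (anyDuplicated(ids)) {
    note("unique-symptoms", ids[duplicated(ids)][1], "duplicated symptom id")
  }
  for (i in seq_len(nrow(ps$symptoms))) {
    if (!ps$symptoms$framework[i] %in% FRAMEWORKS) {
      note("framework", ids[i],
           paste0("unknown framework '", ps$symptoms$framework[i], "'"))
    }
  }
  # baselines: one per symptom, proper tails
  for (id in ids) {
    b <- ps$baselines[ps$baselines$symptom == id, ]
    if (nrow(b) != 1L) {
      note("baseline-count", id,
           sprintf("symptom has %d baseline records, expected 1", nrow(b)))
      next
    }
    fw <- ps$symptoms$framework[match(id, ids)]
    if (fw %in% c("DSM", "DEFENSE")) {
      if (is.na(b$b_present) || b$b_present < 0 || b$b_present >= 1)
        note("baseline-range", id, "binary baseline missing or outside [0,1)")
    } else if (fw == "LPF") {
      if (is.na(b$b_high) || b$b_high < 0 || b$b_high >= 1)
        note("baseline-range", id, "high-tail baseline missing or outside [0,1)")
    } else {
      if (is.na(b$b_high) || is.na(b$b_low))
        note("baseline-range", id, "graded symptom missing a tail baseline")
      else if (b$b_high + b$b_low >= 1)
        note("baseline-tails", id,
             sprintf("tail baselines sum to %.3f >= 1", b$b_high + b$b_low))
    }
  }
  orphan <- setdiff(ps$baselines$symptom, ids)
  for (id in orphan) note("dangling-baseline", id, "baseline for unknown symptom")
  # arcs
  for (i in seq_len(nrow(ps$arcs))) {
    a <- ps$arcs[i, ]
    tag <- paste0(a$disorder, "->", a$symptom)
    if (!a$symptom %in% ids) {
      note("dangling-arc", tag, "arc references unknown symptom")
      next
    }
    if (!a$disorder %in% ps$disorders) {
      note("dangling-arc", tag, "arc references unknown disorder")
      next
    }
    fw <- ps$symptoms$framework[match(a$symptom, ids)]
    okdir <- if (fw %in% c("DSM", "DEFENSE")) "present"
             else if (fw == "LPF") "high" else c("high", "low")
    if (!a$direction %in% okdir) {
      note("arc-direction", tag,
           sprintf("direction '%s' not allowed for %s symptom", a$direction, fw))
      next
    }
    if (is.na(a$q) || a$q < 0 || a$q > 1) {
      note("arc-range", tag, "arc probability outside [0,1]")
      next
    }
    bl <- baseline_of(ps, a$symptom, a$direction)
    if (!is.na(bl) && a$q <= bl) {
      note("arc-weaker-than-baseline", tag,
           sprintf("arc weaker than baseline (q=%.3f <= %.3f)", a$q, bl))
    }
  }
  for (id in setdiff(ids, ps$arcs$symptom)) {
    note("isolated-symptom", id, "symptom has no influence arc")
  }
  # distress links
  for (i in seq_len(nrow(ps$distress))) {
    d <- ps$distress[i, ]
    if (!d$source %in% ids) {
      note("dangling-distress", d$source, "distress link from unknown symptom")
    }
    if (is.na(d$pd) || d$pd < 0 || d$pd > 1) {
      note("distress-range", d$source, "distress probability outside [0,1]")
    }
    if (is.na(d$group) || !nzchar(d$group)) {
      note("distress-group", d$source, "distress link without a group")
    }
  }
  # prevalence
  for (i in seq_len(nrow(ps$prevalence))) {
    p <- ps$prevalence[i, ]
    vals <- c(p$clinical, p$general, p$pd)
    if (any(is.na(vals)) || any(vals <= 0) || any(vals >= 1)) {
      note("prevalence-range", p$disorder, "prevalence values outside (0,1)")
    } else if (p$clinical <= p$general) {
      note("prevalence-order", p$disorder,
           "clinical prevalence not above general prevalence")
    }
  }
  if (length(bad)) do.call(rbind, bad)
  else data.frame(rule = character(), item = character(), message = character())
}

#' Summary statistics of the elicited probabilities
#'
#' Mean and sample standard deviation, on the percentage scale, of (i) all
#' arc presence probabilities (one value per disorder-column cell of the
#' parameter tables), (ii) all baseline values (one per printed norm cell;
#' biosocial tails count separately), and (iii) all symptom-level distress
#' probabilities.
#'
#' @param ps a parameter set.
#' @return a list with components `arcs`, `baselines`, `distress`, each a
#'   named vector `c(n, mean, sd)` in percent.
#' @export
elicitation_summary <- function(ps) {
  if (nrow(ps$arcs) == 0) stop_pdnet("empty parameter set")
  msd <- function(v) {
    v <- v[!is.na(v)] * 100
    c(n = length(v), mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0)
  }
  base_vals <- unlist(lapply(seq_len(nrow(ps$baselines)), function(i) {
    b <- ps$baselines[i, ]
    fw <- ps$symptoms$framework[match(b$symptom, ps$symptoms$id)]
    switch(fw,
      DSM = b$b_present, DEFENSE = b$b_present,
      LPF = b$b_high,
      FFM = b$b_high,                  # one printed value covers both tails
      BIOSOCIAL = if (isTRUE(all.equal(b$b_high, b$b_low))) b$b_high
                  else c(b$b_high, b$b_low))
  }))
  list(arcs = msd(ps$arcs$q),
       baselines = msd(base_vals),
       distress = msd(ps$distress$pd))
}

#' Dump or restore a parameter set as a structured-text document
#'
#' Serializes the full knowledge base to a single YAML document (nested
#' key/value), suitable for provenance records; `read_parameter_yaml()`
#' restores it field for field.
#'
#' @param ps a parameter set.
#' @param path file to write / read.
#' @return `write_parameter_yaml()` returns `path` invisibly;
#'   `read_parameter_yaml()` returns a [parameter_set()].
#' @export
write_parameter_yaml <- function(ps, path) {
  doc <- list(disorders = ps$disorders,
              symptoms = ps$symptoms, arcs = ps$arcs,
              baselines = ps$baselines, distress = ps$distress,
              prevalence = ps$prevalence)
  yaml::write_yaml(rapply(doc, as.list, classes = "data.frame", how = "replace"),
                   path, precision = 15)
  invisible(path)
}

#' @rdname write_parameter_yaml
#' @export
read_parameter_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  df <- function(x) as.data.frame(lapply(x, unlist), stringsAsFactors = FALSE)
  parameter_set(df(doc$symptoms), df(doc$arcs), df(doc$baselines),
                df(doc$distress), df(doc$prevalence),
                disorders = unlist(doc$disorders))
}
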