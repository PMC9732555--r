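# XMLBIF interchange (vendor-neutral Bayesian-network format).
#
# Conventions: one VARIABLE element per node with its ordered OUTCOME
# labels; one DEFINITION per node with GIVEN parents in declared order and
# the TABLE flattened with the child's outcomes innermost and the parent
# configurations in row-major order (first parent slowest, last fastest) —
# the same row order as the package's CPT matrices. Probabilities are
# serialized with 17 significant digits, so a write/read cycle reproduces
# every double exactly.

fmt_prob <- function(x) sprintf("%.17g", x)

#' Export a network to XMLBIF
#'
#' @param model a `bn2o` model.
#' @param path output file.
#' @param name network name recorded in the file.
#' @return `path`, invisibly.
#' @export
export_xmlbif <- function(model, path, name = "pdnet") {
  doc <- xml2::xml_new_root("BIF", VERSION = "0.3")
  net <- xml2::xml_add_child(doc, "NETWORK")
  xml2::xml_add_child(net, "NAME", name)
  for (id in model$nodes$id) {
    v <- xml2::xml_add_child(net, "VARIABLE", TYPE = "nature")
    xml2::xml_add_child(v, "NAME", id)
    for (s in model$states[[id]]) xml2::xml_add_child(v, "OUTCOME", s)
  }
  for (id in model$nodes$id) {
    d <- xml2::xml_add_child(net, "DEFINITION")
    xml2::xml_add_child(d, "FOR", id)
    for (p in model$parents[[id]]) xml2::xml_add_child(d, "GIVEN", p)
    tab <- if (id %in% names(model$priors)) {
      c(1 - model$priors[[id]], model$priors[[id]])
    } else {
      as.vector(t(model$cpts[[id]]$prob))
    }
    xml2::xml_add_child(d, "TABLE", paste(fmt_prob(tab), collapse = " "))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a network from XMLBIF
#'
#' Reads a file written by [export_xmlbif()] (or any XMLBIF 0.3 document
#' using the same table convention) back into node, state, parent and table
#' structures.
#'
#' @param path XMLBIF file.
#' @return list with `name`, `nodes` (character vector), `states` (named
#'   list), `parents` (named list) and `tables` (named list of matrices,
#'   rows = parent configurations, columns = child states).
#' @export
import_xmlbif <- function(path) {
  doc <- xml2::read_xml(path)
  net <- xml2::xml_find_first(doc, ".//NETWORK")
  name <- xml2::xml_text(xml2::xml_find_first(net, "./NAME"))
  states <- list()
  for (v in xml2::xml_find_all(net, "./VARIABLE")) {
    id <- xml2::xml_text(xml2::xml_find_first(v, "./NAME"))
    states[[id]] <- xml2::xml_text(xml2::xml_find_all(v, "./OUTCOME"))
  }
  parents <- list()
  tables <- list()
  for (d in xml2::xml_find_all(net, "./DEFINITION")) {
    id <- xml2::xml_text(xml2::xml_find_first(d, "./FOR"))
    par <- xml2::xml_text(xml2::xml_find_all(d, "./GIVEN"))
    vals <- as.numeric(strsplit(trimws(
      xml2::xml_text(xml2::xml_find_first(d, "./TABLE"))), "[[:space:]]+")[[1]])
    ns <- length(states[[id]])
    tab <- matrix(vals, ncol = ns, byrow = TRUE)
    colnames(tab) <- states[[id]]
    parents[[id]] <- par
    tables[[id]] <- tab
  }
  list(name = name, nodes = names(states), states = states,
       parents = parents, tables = tables)
}
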