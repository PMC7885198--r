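#' Load an is-a ontology from TSV files
#'
#' The term file has columns `term_id`, `term_name`, `parent_id` (empty for
#' roots; a term with several parents repeats its row). The optional mapping
#' file has columns `term_id`, `target_kind` (`event` or `assay`),
#' `target_id`. Cyclic term graphs are rejected at load. Richer formats
#' (OBO/OWL) are a documented extension point, not implemented.
#'
#' @param termPath Path to the term TSV.
#' @param mappingPath Optional path to the mapping TSV.
#' @return An [EventOntology()].
#' @export
loadOntology <- function(termPath, mappingPath = NULL) {
  tsv <- utils::read.delim(termPath, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("term_id", "term_name", "parent_id")
  if (!all(need %in% names(tsv)))
    stop("term TSV needs columns: ", paste(need, collapse = ", "))
  terms <- unique(tsv[, c("term_id", "term_name")])
  names(terms) <- c("id", "name")
  hasParent <- !is.na(tsv$parent_id) & nzchar(tsv$parent_id)
  parents <- data.frame(id = tsv$term_id[hasParent],
                        parent = tsv$parent_id[hasParent],
                        stringsAsFactors = FALSE)
  mapping <- NULL
  if (!is.null(mappingPath)) {
    m <- utils::read.delim(mappingPath, stringsAsFactors = FALSE,
                           colClasses = "character")
    needm <- c("term_id", "target_kind", "target_id")
    if (!all(needm %in% names(m)))
      stop("mapping TSV needs columns: ", paste(needm, collapse = ", "))
    mapping <- data.frame(term = m$term_id, kind = m$target_kind,
                          target = m$target_id, stringsAsFactors = FALSE)
  }
  EventOntology(terms, parents, mapping)
}

#' Descendant closure of an ontology term
#'
#' All terms reachable downwards through is-a links (children, their
#' children, ...), excluding the term itself.
#'
#' @param ontology An [EventOntology()].
#' @param term A term id.
#' @return Sorted character vector of term ids.
#' @export
ontologyDescendants <- function(ontology, term) {
  terms <- ontologyTerms(ontology)
  if (!term %in% terms$id) stop("unknown term id: ", term)
  p <- ontologyParents(ontology)
  if (!nrow(p)) return(character(0))
  # edges child -> parent; descendants follow them backwards
  g <- igraph::graph_from_data_frame(p, directed = TRUE, vertices = terms$id)
  sort(setdiff(names(igraph::subcomponent(g, term, mode = "in")), term))
}

termTargets <- function(ontology, term, kind) {
  m <- ontologyMapping(ontology)
  below <- c(term, ontologyDescendants(ontology, term))
  sort(unique(m$target[m$kind == kind & m$term %in% below]))
}

#' Key events or assays selected by an ontology term
#'
#' The union of the direct mappings of the term and of all its descendants:
#' selecting "receptor binding" selects every subtype binding event mapped
#' below it. Results for a parent term are therefore always supersets of its
#' children's.
#'
#' @param ontology An [EventOntology()].
#' @param term A term id.
#' @return Sorted character vector of event ids / assay ids.
#' @export
eventsForTerm <- function(ontology, term) termTargets(ontology, term, "event")

#' @rdname eventsForTerm
#' @export
assaysForTerm <- function(ontology, term) termTargets(ontology, term, "assay")
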