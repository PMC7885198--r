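#' @import methods
NULL

## Controlled vocabularies ----------------------------------------------------

#' Controlled vocabularies of the reasoning framework
#'
#' The calculus is deliberately coarse: argument strength takes exactly five
#' ordered values, argument grades (convincingness of an argument, reliability
#' or consistency of its evidence) exactly three, and per-event conclusions in
#' the categorical paradigms exactly three. Organization levels are the six
#' swim lanes used to display key events; assay tiers order evidence by
#' biological complexity.
#'
#' @return A character vector of the vocabulary, in ascending order where the
#'   vocabulary is ordered.
#' @examples
#' strengthLevels()
#' grades()
#' @export
strengthLevels <- function() c("VeryLow", "Low", "Medium", "High", "VeryHigh")

#' @rdname strengthLevels
#' @export
grades <- function() c("Small", "Medium", "Large")

#' @rdname strengthLevels
#' @export
organizationLevels <- function()
  c("molecular", "cellular", "tissue", "organ", "individual", "population")

#' @rdname strengthLevels
#' @export
eventRoles <- function() c("MIE", "KE", "AO")

#' @rdname strengthLevels
#' @export
concernStates <- function() c("Concern", "NoConcern", "Unknown")

#' @rdname strengthLevels
#' @export
assayTiers <- function()
  c("in_silico", "in_chemico", "in_vitro", "in_vivo", "human_observation")

#' Default tier precedence for the assay-overrules-prediction paradigm
#'
#' Human observation outranks in vivo, which outranks the two cell-free and
#' cell-based tiers (ranked equally), which outrank in silico prediction.
#' The order is configurable in [tieredMerge()] because reasonable experts
#' disagree, e.g. on whether poorly reproducible human data should dominate.
#'
#' @return Named integer vector of ranks; larger rank overrules smaller.
#' @export
defaultTierRanks <- function()
  c(in_silico = 1L, in_chemico = 2L, in_vitro = 2L, in_vivo = 3L,
    human_observation = 4L)

levelIndex <- function(x) {
  i <- match(x, strengthLevels())
  if (anyNA(i))
    stop("unknown strength level: ", paste(unique(x[is.na(i)]), collapse = ", "))
  i
}

gradeIndex <- function(x) {
  i <- match(x, grades())
  if (anyNA(i))
    stop("unknown grade: ", paste(unique(x[is.na(i)]), collapse = ", "))
  i
}

## SignedStrength -------------------------------------------------------------

#' @rdname SignedStrength
#' @export
setClass("SignedStrength",
  representation(magnitude = "character", direction = "character"))

setValidity("SignedStrength", function(object) {
  m <- object@magnitude; d <- object@direction
  if (length(m) != 1L || length(d) != 1L)
    return("magnitude and direction must be length 1")
  if (!(d %in% c("For", "Against", "None")))
    return("direction must be For, Against or None")
  if (d == "None") {
    if (m != "Balanced") return("direction None requires magnitude Balanced")
  } else {
    if (!(m %in% strengthLevels()))
      return("signed magnitude must be a strength level")
  }
  TRUE
})

#' Signed conclusion of the argument calculus
#'
#' A signed strength is one of the eleven positions the evidence balance can
#' take: five levels of deflection for, five against, and perfectly balanced.
#'
#' @param magnitude One of [strengthLevels()], or `"Balanced"`.
#' @param direction `"For"`, `"Against"`, or `"None"` (iff balanced).
#' @return A `SignedStrength` object.
#' @examples
#' SignedStrength("Low", "For")
#' balanced()
#' @aliases SignedStrength-class
#' @export
SignedStrength <- function(magnitude, direction) {
  new("SignedStrength", magnitude = magnitude, direction = direction)
}

#' @rdname SignedStrength
#' @export
balanced <- function() SignedStrength("Balanced", "None")

#' @rdname SignedStrength
#' @param x A `SignedStrength`.
#' @export
isBalanced <- function(x) x@direction == "None"

#' All eleven signed-strength positions
#'
#' @return List of `SignedStrength` objects, ascending from Against/VeryHigh
#'   through Balanced to For/VeryHigh.
#' @export
signedStrengthCarrier <- function() {
  lev <- strengthLevels()
  c(lapply(rev(lev), SignedStrength, direction = "Against"),
    list(balanced()),
    lapply(lev, SignedStrength, direction = "For"))
}

setMethod("show", "SignedStrength", function(object) {
  if (isBalanced(object)) cat("SignedStrength: Balanced\n")
  else cat("SignedStrength:", object@direction, "/", object@magnitude, "\n")
})

## Network classes ------------------------------------------------------------

emptyDf <- function(...) {
  cols <- c(...)
  as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                stringsAsFactors = FALSE)
}

#' @rdname KeyEventNetwork
#' @export
setClass("KeyEventNetwork",
  representation(events = "data.frame", kers = "data.frame",
                 groups = "data.frame", assays = "data.frame",
                 assayEventLinks = "data.frame",
                 predictionBases = "data.frame",
                 predictionLinks = "data.frame",
                 calculusTables = "list"))

reqCols <- list(
  events = c("id", "name", "level", "role", "group"),
  kers = c("upstream", "downstream", "strength"),
  groups = c("id", "name", "parent"),
  assays = c("id", "name", "reliability", "tier"),
  assayEventLinks = c("assay", "measurement", "event", "convincingness"),
  predictionBases = c("model", "basis", "outcome_weight", "reliability"),
  predictionLinks = c("model", "basis", "kind", "target", "convincingness"))

setValidity("KeyEventNetwork", function(object) {
  for (slot in names(reqCols)) {
    missing <- setdiff(reqCols[[slot]], names(methods::slot(object, slot)))
    if (length(missing))
      return(sprintf("slot '%s' lacks column(s): %s", slot,
                     paste(missing, collapse = ", ")))
  }
  TRUE
})

#' Key event network
#'
#' The central container: key events (nodes, each with an organization level
#' and an MIE/KE/AO role), key event relationships (directed edges weighted by
#' an innate strength of evidence), collapsible event groups, assays linked to
#' events through typed measurements, and structure-activity prediction bases
#' (alerts) linked to events or assays. Structural soundness (resolvable
#' references, unique ids, acyclicity) is checked by [validateNetwork()];
#' [loadKnowledge()] refuses files that do not validate.
#'
#' @param events data.frame with columns `id`, `name`, `level` (one of
#'   [organizationLevels()]), `role` (one of [eventRoles()]), `group`
#'   (id of the containing event group, or `NA`).
#' @param kers data.frame with columns `upstream`, `downstream`, `strength`
#'   (one of [strengthLevels()]).
#' @param groups data.frame with columns `id`, `name`, `parent` (for nested
#'   groups; `NA` for top-level groups).
#' @param assays data.frame with columns `id`, `name`, `reliability` (one of
#'   [grades()]), `tier` (one of [assayTiers()]).
#' @param assayEventLinks data.frame with columns `assay`, `measurement`,
#'   `event`, `convincingness` — one row per measurement line between an
#'   assay and a key event.
#' @param predictionBases data.frame with columns `model`, `basis`,
#'   `outcome_weight` (a strength level weighting the prediction-event
#'   relationship), `reliability` (one of [grades()]).
#' @param predictionLinks data.frame with columns `model`, `basis`, `kind`
#'   (`"event"` or `"assay"`), `target`, `convincingness`.
#' @param calculusTables optional calculus-table override as returned by
#'   [loadCalculusTables()]; empty list means the packaged defaults.
#' @return A `KeyEventNetwork` object.
#' @seealso [validateNetwork()], [downstreamClosure()], [collapseGroup()],
#'   [propagate()]
#' @examples
#' net <- KeyEventNetwork(
#'   events = data.frame(id = c("a", "b"), name = c("A", "B"),
#'                       level = c("molecular", "organ"),
#'                       role = c("MIE", "AO"), group = NA),
#'   kers = data.frame(upstream = "a", downstream = "b", strength = "High"))
#' validateNetwork(net)
#' @aliases KeyEventNetwork-class
#' @export
KeyEventNetwork <- function(events = NULL, kers = NULL, groups = NULL,
                            assays = NULL, assayEventLinks = NULL,
                            predictionBases = NULL, predictionLinks = NULL,
                            calculusTables = list()) {
  fill <- function(df, cols) {
    if (is.null(df) || nrow(df) == 0L) return(emptyDf(cols))
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    for (col in setdiff(cols, names(df))) df[[col]] <- NA_character_
    df <- df[, cols, drop = FALSE]
    df[] <- lapply(df, as.character)
    rownames(df) <- NULL
    df
  }
  new("KeyEventNetwork",
      events = fill(events, reqCols$events),
      kers = fill(kers, reqCols$kers),
      groups = fill(groups, reqCols$groups),
      assays = fill(assays, reqCols$assays),
      assayEventLinks = fill(assayEventLinks, reqCols$assayEventLinks),
      predictionBases = fill(predictionBases, reqCols$predictionBases),
      predictionLinks = fill(predictionLinks, reqCols$predictionLinks),
      calculusTables = calculusTables)
}

setMethod("show", "KeyEventNetwork", function(object) {
  ev <- object@events
  cat("KeyEventNetwork with", nrow(ev), "key events (",
      sum(ev$role == "MIE"), "MIE,", sum(ev$role == "KE"), "KE,",
      sum(ev$role == "AO"), "AO ),", nrow(object@kers), "KERs,",
      nrow(object@groups), "groups,", nrow(object@assays), "assays,",
      nrow(object@predictionBases), "prediction bases\n")
})

#' @rdname NetworkView
#' @export
setClass("NetworkView",
  representation(network = "KeyEventNetwork", collapsed = "character"))

#' A network with some event groups collapsed
#'
#' A `NetworkView` keeps the full underlying network alongside the set of
#' currently collapsed group ids, so collapsing and expanding are exact
#' inverses. The displayed node/edge sets are computed by [viewEvents()] and
#' [viewKers()]: members of a collapsed group are replaced by a single group
#' node, boundary edges are re-homed to it, and parallel edges produced by the
#' merge keep the strongest KER strength (conservative display).
#'
#' @param network A [KeyEventNetwork()].
#' @param collapsed Character vector of collapsed group ids.
#' @return A `NetworkView`.
#' @seealso [collapseGroup()], [expandGroup()]
#' @aliases NetworkView-class
#' @export
NetworkView <- function(network, collapsed = character(0)) {
  new("NetworkView", network = network, collapsed = collapsed)
}

setMethod("show", "NetworkView", function(object) {
  cat("NetworkView:", nrow(viewEvents(object)), "visible nodes;",
      if (length(object@collapsed))
        paste("collapsed:", paste(object@collapsed, collapse = ", "))
      else "nothing collapsed", "\n")
})

## Evidence and results -------------------------------------------------------

#' @rdname CompoundEvidence
#' @export
setClass("CompoundEvidence",
  representation(compound = "character", calls = "data.frame",
                 predictions = "data.frame"))

#' Per-compound evidence record
#'
#' The assay calls and prediction outcomes recorded for one compound, ready
#' for propagation over a network. Calls use the normalized vocabulary
#' Positive/Negative/Conflicted; a `measurement` of `"overall_call"` marks the
#' assay-level aggregate. Prediction outcomes are `"fired"` (the basis fired,
#' a concerning prediction) or `"negative"` (an explicit negative prediction,
#' e.g. a no-alert negative with confidence); bases that are simply absent
#' contribute nothing, because the absence of an alert is not a negative
#' prediction.
#'
#' @param compound Compound identifier.
#' @param calls data.frame with columns `assay`, `measurement`, `call`.
#' @param predictions data.frame with columns `model`, `basis`, `outcome`.
#' @return A `CompoundEvidence` object.
#' @aliases CompoundEvidence-class
#' @export
CompoundEvidence <- function(compound, calls = NULL, predictions = NULL) {
  mk <- function(df, cols) {
    if (is.null(df) || nrow(df) == 0L) return(emptyDf(cols))
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    for (col in setdiff(cols, names(df))) df[[col]] <- NA_character_
    df[, cols, drop = FALSE]
  }
  new("CompoundEvidence", compound = compound,
      calls = mk(calls, c("assay", "measurement", "call")),
      predictions = mk(predictions, c("model", "basis", "outcome")))
}

setValidity("CompoundEvidence", function(object) {
  bad <- setdiff(object@calls$call, c("Positive", "Negative", "Conflicted"))
  if (length(bad))
    return(paste("unnormalized call value(s):", paste(bad, collapse = ", ")))
  badOut <- setdiff(object@predictions$outcome, c("fired", "negative"))
  if (length(badOut))
    return(paste("unknown prediction outcome(s):", paste(badOut, collapse = ", ")))
  TRUE
})

setMethod("show", "CompoundEvidence", function(object) {
  cat("CompoundEvidence for", object@compound, ":", nrow(object@calls),
      "calls,", nrow(object@predictions), "prediction outcomes\n")
})

#' @rdname PropagationResult
#' @export
setClass("PropagationResult",
  representation(paradigm = "character", states = "data.frame",
                 provenance = "list"))

#' Result of propagating evidence over a network
#'
#' One row per key event. Under the `conservative` and `tiered` paradigms the
#' `state` column holds a [concernStates()] value; under `calculus` the
#' `direction`/`magnitude` columns hold the signed strength of the resolved
#' conclusion. `provenance` lists, per event, the evidence items and upstream
#' contributions that entered the merge.
#'
#' @aliases PropagationResult-class
#' @seealso [propagate()], [propagationStates()]
#' @export
PropagationResult <- function(paradigm, states, provenance = list()) {
  new("PropagationResult", paradigm = paradigm, states = states,
      provenance = provenance)
}

setMethod("show", "PropagationResult", function(object) {
  cat("PropagationResult (", object@paradigm, " paradigm), ",
      nrow(object@states), " events\n", sep = "")
  if (object@paradigm == "calculus") {
    tab <- table(paste(object@states$direction, object@states$magnitude, sep = "/"))
  } else {
    tab <- table(object@states$state)
  }
  for (nm in names(tab)) cat("  ", nm, ": ", tab[[nm]], "\n", sep = "")
})

## Ontology -------------------------------------------------------------------

#' @rdname EventOntology
#' @export
setClass("EventOntology",
  representation(terms = "data.frame", parents = "data.frame",
                 mapping = "data.frame"))

#' Is-a ontology over key events and assays
#'
#' Terms form a DAG under is-a links (multiple parents allowed, e.g. a
#' receptor-subtype binding term sitting under both the subtype event and the
#' generic binding term). Terms may map to key events or assays; queries walk
#' the descendant closure so selecting a term selects everything mapped at or
#' below it.
#'
#' @param terms data.frame with columns `id`, `name`.
#' @param parents data.frame with columns `id`, `parent` (one row per is-a
#'   edge; repeat `id` for multiple parents).
#' @param mapping data.frame with columns `term`, `kind` (`"event"` or
#'   `"assay"`), `target`.
#' @return An `EventOntology`; construction fails on a cyclic term graph.
#' @seealso [ontologyDescendants()], [eventsForTerm()], [assaysForTerm()]
#' @aliases EventOntology-class
#' @export
EventOntology <- function(terms, parents = NULL, mapping = NULL) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  if (is.null(parents) || nrow(parents) == 0L)
    parents <- emptyDf(c("id", "parent"))
  if (is.null(mapping) || nrow(mapping) == 0L)
    mapping <- emptyDf(c("term", "kind", "target"))
  new("EventOntology", terms = terms,
      parents = as.data.frame(parents, stringsAsFactors = FALSE),
      mapping = as.data.frame(mapping, stringsAsFactors = FALSE))
}

setValidity("EventOntology", function(object) {
  p <- object@parents
  unknown <- setdiff(c(p$id, p$parent), object@terms$id)
  if (length(unknown))
    return(paste("is-a edge references unknown term(s):",
                 paste(unknown, collapse = ", ")))
  if (nrow(p)) {
    g <- igraph::graph_from_data_frame(p[, c("id", "parent")], directed = TRUE,
                                       vertices = object@terms$id)
    if (!igraph::is_dag(g)) return("term graph contains an is-a cycle")
  }
  if (anyDuplicated(object@terms$id)) return("duplicated term id")
  TRUE
})

setMethod("show", "EventOntology", function(object) {
  cat("EventOntology:", nrow(object@terms), "terms,", nrow(object@parents),
      "is-a edges,", nrow(object@mapping), "mappings\n")
})

## Fingerprint ----------------------------------------------------------------

#' @rdname Fingerprint
#' @export
setClass("Fingerprint",
  representation(bits = "integer", scheme = "character"))

#' Binary feature-set fingerprint
#'
#' A set of integer features identifying substructural (or alert-firing)
#' features of a compound, compared with the Tanimoto coefficient. The set is
#' deterministic for a given structure and scheme.
#'
#' @param bits Integer feature ids (stored sorted, unique).
#' @param scheme Scheme identifier (`"path_default"`, `"alert_based"`, or a
#'   plug-in name).
#' @return A `Fingerprint`.
#' @seealso [fingerprint()], [tanimoto()]
#' @aliases Fingerprint-class
#' @export
Fingerprint <- function(bits, scheme) {
  new("Fingerprint", bits = sort(unique(as.integer(bits))), scheme = scheme)
}

setMethod("show", "Fingerprint", function(object) {
  cat("Fingerprint (", object@scheme, "): ", length(object@bits),
      " features\n", sep = "")
})

#' @rdname Fingerprint
#' @param object A `Fingerprint`.
#' @export
fingerprintBits <- function(object) object@bits

#' @rdname Fingerprint
#' @export
fingerprintScheme <- function(object) object@scheme
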