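#' Accessors for KeyEventNetwork slots
#'
#' Accessor generics returning the component tables of a network (or of the
#' network underlying a view). Slots should not be reached into directly.
#'
#' @param x A [KeyEventNetwork()] or [NetworkView()].
#' @return A data.frame (see [KeyEventNetwork()] for the columns).
#' @name network-accessors
#' @examples
#' net <- aopFixture("skin_sensitization")
#' events(net)
#' kers(net)
NULL

#' @rdname network-accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @rdname network-accessors
#' @export
setGeneric("kers", function(x) standardGeneric("kers"))
#' @rdname network-accessors
#' @export
setGeneric("eventGroups", function(x) standardGeneric("eventGroups"))
#' @rdname network-accessors
#' @export
setGeneric("assays", function(x) standardGeneric("assays"))
#' @rdname network-accessors
#' @export
setGeneric("assayEventLinks", function(x) standardGeneric("assayEventLinks"))
#' @rdname network-accessors
#' @export
setGeneric("predictionBases", function(x) standardGeneric("predictionBases"))
#' @rdname network-accessors
#' @export
setGeneric("predictionLinks", function(x) standardGeneric("predictionLinks"))

#' @rdname network-accessors
setMethod("events", "KeyEventNetwork", function(x) x@events)
#' @rdname network-accessors
setMethod("kers", "KeyEventNetwork", function(x) x@kers)
#' @rdname network-accessors
setMethod("eventGroups", "KeyEventNetwork", function(x) x@groups)
#' @rdname network-accessors
setMethod("assays", "KeyEventNetwork", function(x) x@assays)
#' @rdname network-accessors
setMethod("assayEventLinks", "KeyEventNetwork", function(x) x@assayEventLinks)
#' @rdname network-accessors
setMethod("predictionBases", "KeyEventNetwork", function(x) x@predictionBases)
#' @rdname network-accessors
setMethod("predictionLinks", "KeyEventNetwork", function(x) x@predictionLinks)

#' @rdname network-accessors
setMethod("events", "NetworkView", function(x) x@network@events)
#' @rdname network-accessors
setMethod("kers", "NetworkView", function(x) x@network@kers)
#' @rdname network-accessors
setMethod("eventGroups", "NetworkView", function(x) x@network@groups)
#' @rdname network-accessors
setMethod("assays", "NetworkView", function(x) x@network@assays)
#' @rdname network-accessors
setMethod("assayEventLinks", "NetworkView", function(x) x@network@assayEventLinks)
#' @rdname network-accessors
setMethod("predictionBases", "NetworkView", function(x) x@network@predictionBases)
#' @rdname network-accessors
setMethod("predictionLinks", "NetworkView", function(x) x@network@predictionLinks)

#' @rdname PropagationResult
#' @param object A `PropagationResult`.
#' @export
propagationStates <- function(object) object@states

#' @rdname PropagationResult
#' @export
propagationParadigm <- function(object) object@paradigm

#' @rdname PropagationResult
#' @export
propagationProvenance <- function(object) object@provenance

#' @rdname CompoundEvidence
#' @param object A `CompoundEvidence`.
#' @export
evidenceCalls <- function(object) object@calls

#' @rdname CompoundEvidence
#' @export
evidencePredictions <- function(object) object@predictions

#' @rdname CompoundEvidence
#' @export
evidenceCompound <- function(object) object@compound

#' @rdname EventOntology
#' @param object An `EventOntology`.
#' @export
ontologyTerms <- function(object) object@terms

#' @rdname EventOntology
#' @export
ontologyParents <- function(object) object@parents

#' @rdname EventOntology
#' @export
ontologyMapping <- function(object) object@mapping

#' @rdname NetworkView
#' @param view A `NetworkView`.
#' @export
collapsedGroups <- function(view) view@collapsed

#' @rdname NetworkView
#' @export
viewNetwork <- function(view) view@network
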