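#' Suggest the most informative next assay
#'
#' For a compound with some recorded calls and a target event of interest,
#' candidate assays are those linked to events on pathways into (or at) the
#' target event for which the compound has no call yet — the grey nodes of
#' the evidence display. Each candidate is scored by the magnitude of its
#' call concordance ([phiCoefficient()]) with the assays linked to the target
#' event, computed over the compound's chemical similarity neighborhood and —
#' when enough similar compounds share them — conditioned on the compound's
#' existing calls. Conditioning filters are applied assay-by-assay (in assay
#' id order) and each filter is kept only while the conditioned subset
#' retains at least `minN` compounds. Candidates whose concordance is masked
#' everywhere fall back to pathway proximity: fewest KER hops from a linked
#' event to the target.
#'
#' @param net A [KeyEventNetwork()].
#' @param calls data.frame with columns `compound`, `assay`, `call` (overall
#'   calls for the historical dataset).
#' @param compound Id of the compound under study.
#' @param targetEvent Event id the user wants to discriminate.
#' @param compounds Optional data.frame `id`, `smiles` (or named fingerprint
#'   list) enabling the similarity filter; `NULL` uses the whole dataset.
#' @param cutoff Tanimoto cutoff for the neighborhood (used when `compounds`
#'   is supplied).
#' @param minN Minimum informative pairs before a phi is trusted, and minimum
#'   subset size for call conditioning (default 5).
#' @param scheme Fingerprint scheme.
#' @return data.frame ranked best-first with columns `assay`, `score`
#'   (|phi|, `NA` when masked), `n` (informative pairs behind the score),
#'   `hops` (KER distance to the target).
#' @examples
#' \donttest{
#' fx <- aopFixture("dihydroxyaniline_scenario")
#' suggestNext(fx$network, fx$calls, fx$query, "skin_sensitization",
#'             compounds = fx$compounds, cutoff = 0.3)
#' }
#' @export
suggestNext <- function(net, calls, compound, targetEvent, compounds = NULL,
                        cutoff = 0.3, minN = 5L, scheme = "path_default") {
  ev <- events(net)
  if (!targetEvent %in% ev$id) stop("unknown event id: ", targetEvent)
  myCalls <- calls[calls$compound == compound, , drop = FALSE]
  if (!nrow(myCalls)) stop("compound has no recorded calls: ", compound)

  ll <- assayEventLinks(net)
  pathEvents <- c(targetEvent, upstreamClosure(net, targetEvent))
  pathAssays <- sort(unique(ll$assay[ll$event %in% pathEvents]))
  measured <- unique(myCalls$assay)
  candidates <- setdiff(pathAssays, measured)
  if (!length(candidates))
    stop("no candidate assays: all pathway assays already measured for ",
         compound)
  targetAssays <- sort(unique(ll$assay[ll$event == targetEvent]))

  subset <- calls
  if (!is.null(compounds)) {
    query <- if (is.data.frame(compounds))
      compounds$smiles[compounds$id == compound][1] else NULL
    if (is.null(query) || is.na(query))
      stop("compound ", compound, " has no structure in `compounds`")
    subset <- similaritySubset(subset, compounds, query, cutoff, scheme)
  }
  # condition on the compound's own calls while enough neighbors remain
  for (a in sort(measured)) {
    myCall <- myCalls$call[myCalls$assay == a][1]
    tentative <- conditionSubset(subset, a, myCall)
    if (length(unique(tentative$compound)) >= minN) subset <- tentative
  }

  g <- kerGraph(net)
  hopsTo <- function(assay) {
    linked <- unique(ll$event[ll$assay == assay])
    d <- suppressWarnings(
      igraph::distances(g, v = linked, to = targetEvent, mode = "out"))
    m <- suppressWarnings(min(d))
    if (is.infinite(m)) NA_real_ else m
  }
  callVec <- function(a) {
    s <- subset[subset$assay == a, , drop = FALSE]
    stats::setNames(s$call, s$compound)
  }
  rows <- lapply(candidates, function(a) {
    best <- NA_real_; bestN <- 0L
    for (t in setdiff(targetAssays, a)) {
      cell <- phiCoefficient(callVec(a), callVec(t))
      if (!is.na(cell$phi) && cell$n >= minN) {
        if (is.na(best) || abs(cell$phi) > best ||
            (abs(cell$phi) == best && cell$n > bestN)) {
          best <- abs(cell$phi); bestN <- cell$n
        }
      }
    }
    data.frame(assay = a, score = best, n = bestN, hops = hopsTo(a),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  scored <- !is.na(out$score)
  out <- rbind(
    out[scored, , drop = FALSE][order(-out$score[scored], -out$n[scored],
                                      out$assay[scored]), , drop = FALSE],
    out[!scored, , drop = FALSE][order(out$hops[!scored], out$assay[!scored]),
                                 , drop = FALSE])
  rownames(out) <- NULL
  out
}
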