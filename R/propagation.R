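## Evidence items local to each event: assay overall calls reach an event via
## its assay-event links; prediction outcomes via event-kind prediction links.
## Measurement-level calls only stand in (conservatively merged) when no
## overall call was recorded, since only overall calls colour the display.
localEvidenceItems <- function(net, evidence) {
  ev <- events(net)
  ll <- assayEventLinks(net)
  aa <- assays(net)
  pb <- predictionBases(net)
  pl <- predictionLinks(net)
  calls <- evidenceCalls(evidence)
  preds <- evidencePredictions(evidence)

  badAssay <- setdiff(calls$assay, aa$id)
  if (length(badAssay))
    stop("evidence references unknown assay(s): ",
         paste(badAssay, collapse = ", "))
  declared <- paste(ll$assay, ll$measurement)
  badMeas <- !paste(calls$assay, calls$measurement) %in% declared
  if (any(badMeas))
    stop("evidence references undeclared measurement(s): ",
         paste(unique(paste(calls$assay[badMeas], calls$measurement[badMeas])),
               collapse = ", "))
  if (nrow(preds)) {
    badPred <- !paste(preds$model, preds$basis) %in% paste(pb$model, pb$basis)
    if (any(badPred))
      stop("evidence references unknown prediction basis/bases: ",
           paste(unique(paste(preds$model[badPred], preds$basis[badPred])),
                 collapse = ", "))
  }

  items <- stats::setNames(vector("list", nrow(ev)), ev$id)
  callToState <- c(Positive = "Concern", Negative = "NoConcern",
                   Conflicted = "Concern")
  callToDir <- c(Positive = "For", Negative = "Against", Conflicted = "For")

  for (e in ev$id) {
    rows <- ll[ll$event == e, , drop = FALSE]
    for (a in unique(rows$assay)) {
      aCalls <- calls[calls$assay == a, , drop = FALSE]
      if (!nrow(aCalls)) next
      overall <- aCalls$call[aCalls$measurement == "overall_call"]
      if (length(overall)) {
        call <- overallCall(overall)
      } else {
        call <- if (conservativeMerge(callToState[aCalls$call]) == "Concern")
          "Positive" else "Negative"
      }
      aRows <- rows[rows$assay == a, , drop = FALSE]
      conv <- if ("overall_call" %in% aRows$measurement)
        aRows$convincingness[aRows$measurement == "overall_call"][1]
      else aRows$convincingness[which.max(gradeIndex(aRows$convincingness))]
      rel <- aa$reliability[aa$id == a][1]
      strength <- if (call == "Conflicted") "VeryLow"
                  else strengthOf(conv, rel, checkTables(net@calculusTables))
      items[[e]] <- c(items[[e]], list(list(
        kind = "assay", id = a, tier = aa$tier[aa$id == a][1],
        call = call, state = callToState[[call]],
        direction = callToDir[[call]], strength = strength)))
    }
    pRows <- pl[pl$kind == "event" & pl$target == e, , drop = FALSE]
    if (nrow(pRows) && nrow(preds)) {
      for (i in seq_len(nrow(pRows))) {
        hit <- preds[preds$model == pRows$model[i] &
                     preds$basis == pRows$basis[i], , drop = FALSE]
        if (!nrow(hit)) next  # an absent basis is not a negative prediction
        base <- pb[pb$model == pRows$model[i] & pb$basis == pRows$basis[i], ,
                   drop = FALSE]
        fired <- hit$outcome[1] == "fired"
        # explicit negatives enter weakly (convincingness Small)
        conv <- if (fired) pRows$convincingness[i] else "Small"
        strength <- transmitStrength(
          strengthOf(conv, base$reliability[1],
                     checkTables(net@calculusTables)),
          base$outcome_weight[1])
        items[[e]] <- c(items[[e]], list(list(
          kind = "prediction", id = paste(hit$model[1], hit$basis[1]),
          tier = "in_silico",
          call = if (fired) "Positive" else "Negative",
          state = if (fired) "Concern" else "NoConcern",
          direction = if (fired) "For" else "Against",
          strength = strength)))
      }
    }
  }
  items
}

#' Propagate compound evidence over a key event network
#'
#' Events are processed in topological order. At each event the local
#' evidence (assay overall calls reaching the event through its measurement
#' links, and prediction outcomes through event-kind prediction links) is
#' merged with the contributions of upstream events, each transmitted through
#' its KER, under one of three paradigms:
#'
#' * `conservative` — any cause for concern wins ([conservativeMerge()]);
#'   only Concern travels downstream: a negative assay is a local statement
#'   about that assay, not proof the pathway is blocked.
#' * `tiered` — assay results overrule predictions: local evidence is
#'   restricted to its highest informative tier ([tieredMerge()]) before a
#'   Concern inherited from upstream is merged in conservatively.
#' * `calculus` — the full signed argument calculus: local arguments and a
#'   single pooled upstream argument (the resolved likelihood of preceding
#'   events, capped by each KER via [transmitStrength()]) are resolved with
#'   [resolveArguments()] into a [SignedStrength()] per event.
#'
#' Events with no evidence anywhere upstream or local come out Unknown
#' (categorical) or Balanced (calculus).
#'
#' @param net A validated [KeyEventNetwork()].
#' @param evidence A [CompoundEvidence()].
#' @param paradigm `"conservative"`, `"tiered"` or `"calculus"`.
#' @param tierRanks Tier precedence for the tiered paradigm
#'   ([defaultTierRanks()]).
#' @return A [PropagationResult()].
#' @examples
#' fx <- aopFixture("linalool_evidence")
#' res <- propagate(fx$network, fx$evidence, "conservative")
#' propagationStates(res)
#' @export
propagate <- function(net, evidence, paradigm = c("conservative", "tiered",
                                                  "calculus"),
                      tierRanks = defaultTierRanks()) {
  paradigm <- match.arg(paradigm)
  v <- validateNetwork(net)
  if (nrow(v))
    stop("network does not validate (", nrow(v), " violation(s)); see validateNetwork()")
  local <- localEvidenceItems(net, evidence)
  ev <- events(net)
  kk <- kers(net)
  g <- kerGraph(net)
  order <- names(igraph::topo_sort(g, mode = "out"))

  states <- stats::setNames(vector("list", nrow(ev)), ev$id)
  provenance <- stats::setNames(vector("list", nrow(ev)), ev$id)
  tables <- checkTables(net@calculusTables)

  for (e in order) {
    items <- local[[e]]
    prov <- vapply(items, function(it) paste0(it$kind, ":", it$id, "=", it$call),
                   character(1))
    parents <- kk[kk$downstream == e, , drop = FALSE]
    if (paradigm == "calculus") {
      upDir <- character(0); upMag <- character(0)
      if (nrow(parents)) for (i in seq_len(nrow(parents))) {
        ps <- states[[parents$upstream[i]]]
        if (isBalanced(ps)) next
        upDir <- c(upDir, ps@direction)
        upMag <- c(upMag, transmitStrength(ps@magnitude, parents$strength[i]))
        prov <- c(prov, paste0("upstream:", parents$upstream[i], "=",
                               ps@direction, "/", ps@magnitude, " via KER ",
                               parents$strength[i]))
      }
      dirs <- vapply(items, `[[`, character(1), "direction")
      mags <- vapply(items, `[[`, character(1), "strength")
      if (length(upDir)) {
        pooled <- resolveSigned(upDir, upMag, tables)
        if (!isBalanced(pooled)) {
          dirs <- c(dirs, pooled@direction)
          mags <- c(mags, pooled@magnitude)
        }
      }
      states[[e]] <- resolveSigned(dirs, mags, tables)
    } else {
      upstreamConcern <- character(0)
      if (nrow(parents)) for (i in seq_len(nrow(parents))) {
        ps <- states[[parents$upstream[i]]]
        if (identical(ps, "Concern")) {
          upstreamConcern <- c(upstreamConcern, "Concern")
          prov <- c(prov, paste0("upstream:", parents$upstream[i], "=Concern"))
        }
      }
      localStates <- vapply(items, `[[`, character(1), "state")
      if (paradigm == "conservative") {
        states[[e]] <- conservativeMerge(c(localStates, upstreamConcern))
      } else {
        tiers <- vapply(items, `[[`, character(1), "tier")
        localMerged <- tieredMerge(tiers, localStates, tierRanks)
        states[[e]] <- conservativeMerge(c(localMerged, upstreamConcern))
      }
    }
    provenance[[e]] <- unname(prov)
  }

  if (paradigm == "calculus") {
    df <- data.frame(
      event = ev$id,
      direction = vapply(states[ev$id], function(s) s@direction, character(1)),
      magnitude = vapply(states[ev$id], function(s) s@magnitude, character(1)),
      stringsAsFactors = FALSE)
    rownames(df) <- NULL
  } else {
    df <- data.frame(event = ev$id,
                     state = unlist(states[ev$id], use.names = FALSE),
                     stringsAsFactors = FALSE)
  }
  PropagationResult(paradigm, df, provenance[ev$id])
}

#' Adverse outcomes alerted by a positive result
#'
#' Given a concerning (Positive) call on an assay — or directly on an event —
#' the alerted adverse outcomes are the AO-role events in the downstream
#' closure of every event the assay links to (an AO queried directly alerts
#' itself). Each AO is reported with one shortest supporting path. Negative
#' calls alert nothing: the query is hazard-only.
#'
#' @param net A [KeyEventNetwork()].
#' @param source An assay id or an event id.
#' @param call `"Positive"` or `"Negative"` (normalized vocabulary).
#' @return data.frame with columns `ao`, `from` (the linked event) and
#'   `path` (ids joined by `" -> "`).
#' @examples
#' alertedAOs(aopFixture("genotoxicity"), "ames", "Positive")
#' @export
alertedAOs <- function(net, source, call = "Positive") {
  ev <- events(net)
  empty <- data.frame(ao = character(0), from = character(0),
                      path = character(0), stringsAsFactors = FALSE)
  if (call %in% c("Negative", "NoConcern")) return(empty)
  if (!call %in% c("Positive", "Concern", "Conflicted"))
    stop("unknown call: ", call)
  if (source %in% assays(net)$id) {
    ll <- assayEventLinks(net)
    starts <- unique(ll$event[ll$assay == source])
  } else if (source %in% ev$id) {
    starts <- source
  } else stop("unknown assay or event id: ", source)

  g <- kerGraph(net)
  out <- list()
  for (s in sort(starts)) {
    reach <- c(s, downstreamClosure(net, s))
    aos <- sort(intersect(reach, ev$id[ev$role == "AO"]))
    for (ao in aos) {
      path <- if (ao == s) s else {
        p <- igraph::shortest_paths(g, s, ao, mode = "out")$vpath[[1]]
        paste(names(p), collapse = " -> ")
      }
      out[[length(out) + 1L]] <- data.frame(ao = ao, from = s, path = path,
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else empty
}
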