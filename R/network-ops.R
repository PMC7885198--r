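kerGraph <- function(net) {
  ev <- events(net)
  kk <- kers(net)
  igraph::graph_from_data_frame(kk[, c("upstream", "downstream")],
                                directed = TRUE, vertices = ev$id)
}

violation <- function(rule, message, subject = NA_character_) {
  data.frame(rule = rule, subject = subject, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a key event network
#'
#' Checks every structural invariant of the data model and returns the
#' violations found rather than raising: unique ids, controlled vocabularies,
#' resolvable cross-references, no self-loops, acyclicity of the KER graph,
#' group containment (a group's parent chain must not cycle), and uniqueness
#' of (assay, measurement, event) links. An empty result means the network is
#' well formed.
#'
#' @param net A [KeyEventNetwork()].
#' @return data.frame with columns `rule`, `subject`, `message`; zero rows
#'   iff valid.
#' @examples
#' validateNetwork(aopFixture("skin_sensitization"))  # 0 rows
#' @export
validateNetwork <- function(net) {
  ev <- events(net); kk <- kers(net); gg <- eventGroups(net)
  aa <- assays(net); ll <- assayEventLinks(net)
  pb <- predictionBases(net); pl <- predictionLinks(net)
  out <- list()
  add <- function(v) out[[length(out) + 1L]] <<- v

  dup <- unique(ev$id[duplicated(ev$id)])
  for (d in dup) add(violation("duplicate-event-id", "event id not unique", d))
  badLevel <- unique(ev$id[!ev$level %in% organizationLevels()])
  for (d in badLevel)
    add(violation("unknown-organization-level",
                  "event level outside the six swim lanes", d))
  badRole <- unique(ev$id[!ev$role %in% eventRoles()])
  for (d in badRole) add(violation("unknown-role", "event role not MIE/KE/AO", d))

  known <- ev$id
  if (nrow(kk)) {
    dangling <- unique(c(kk$upstream, kk$downstream))
    for (d in setdiff(dangling, known))
      add(violation("dangling-ker", "KER endpoint is not a known event", d))
    self <- kk$upstream[kk$upstream == kk$downstream]
    for (d in unique(self))
      add(violation("self-loop", "KER connects an event to itself", d))
    ok <- kk$upstream %in% known & kk$downstream %in% known &
      kk$upstream != kk$downstream
    if (any(ok)) {
      g <- igraph::graph_from_data_frame(kk[ok, c("upstream", "downstream")],
                                         directed = TRUE, vertices = known)
      if (!igraph::is_dag(g))
        add(violation("cycle", "KER graph contains a directed cycle"))
    }
    badStrength <- !kk$strength %in% strengthLevels()
    for (i in which(badStrength))
      add(violation("unknown-strength", "KER strength not a strength level",
                    paste0(kk$upstream[i], "->", kk$downstream[i])))
  }

  if (nrow(gg)) {
    for (d in unique(gg$id[duplicated(gg$id)]))
      add(violation("duplicate-group-id", "group id not unique", d))
    badParent <- setdiff(stats::na.omit(gg$parent), gg$id)
    for (d in badParent)
      add(violation("dangling-group-parent", "parent group does not exist", d))
    # parent chains must not cycle
    pe <- gg[!is.na(gg$parent) & gg$parent %in% gg$id, c("id", "parent")]
    if (nrow(pe)) {
      pg <- igraph::graph_from_data_frame(pe, directed = TRUE,
                                          vertices = unique(gg$id))
      if (!igraph::is_dag(pg))
        add(violation("group-cycle", "group nesting contains a cycle"))
    }
    memberCounts <- table(c(ev$group[!is.na(ev$group)],
                            gg$parent[!is.na(gg$parent)]))
    for (g in setdiff(gg$id, names(memberCounts)))
      add(violation("empty-group", "group has no members", g))
  }
  for (d in setdiff(stats::na.omit(ev$group), gg$id))
    add(violation("dangling-group", "event assigned to unknown group", d))

  if (nrow(aa)) {
    for (d in unique(aa$id[duplicated(aa$id)]))
      add(violation("duplicate-assay-id", "assay id not unique", d))
    for (d in unique(aa$id[!aa$tier %in% assayTiers()]))
      add(violation("unknown-tier", "assay tier outside the enumeration", d))
    for (d in unique(aa$id[!aa$reliability %in% grades()]))
      add(violation("unknown-grade", "assay reliability not a grade", d))
  }
  if (nrow(ll)) {
    for (d in setdiff(unique(ll$assay), aa$id))
      add(violation("dangling-link-assay", "link references unknown assay", d))
    for (d in setdiff(unique(ll$event), known))
      add(violation("dangling-link-event", "link references unknown event", d))
    key <- paste(ll$assay, ll$measurement, ll$event)
    for (d in unique(key[duplicated(key)]))
      add(violation("duplicate-link", "duplicate (assay, measurement, event) link", d))
    for (i in which(!ll$convincingness %in% grades()))
      add(violation("unknown-grade", "link convincingness not a grade",
                    paste(ll$assay[i], ll$measurement[i])))
  }
  if (nrow(pl)) {
    baseKey <- paste(pb$model, pb$basis)
    for (i in which(!paste(pl$model, pl$basis) %in% baseKey))
      add(violation("dangling-prediction-basis",
                    "prediction link references unknown basis",
                    paste(pl$model[i], pl$basis[i])))
    badKind <- !pl$kind %in% c("event", "assay")
    for (i in which(badKind))
      add(violation("unknown-link-kind", "prediction link kind not event/assay",
                    pl$kind[i]))
    evTargets <- pl$kind == "event" & !pl$target %in% known
    for (i in which(evTargets))
      add(violation("dangling-prediction-target",
                    "prediction link targets unknown event", pl$target[i]))
    asTargets <- pl$kind == "assay" & !pl$target %in% aa$id
    for (i in which(asTargets))
      add(violation("dangling-prediction-target",
                    "prediction link targets unknown assay", pl$target[i]))
  }
  if (nrow(pb)) {
    for (i in which(!pb$outcome_weight %in% strengthLevels()))
      add(violation("unknown-strength",
                    "prediction outcome weight not a strength level",
                    pb$basis[i]))
    for (i in which(!pb$reliability %in% grades()))
      add(violation("unknown-grade", "prediction reliability not a grade",
                    pb$basis[i]))
  }
  if (length(out)) do.call(rbind, out)
  else violation(character(0), character(0), character(0))
}

#' Reachability closures over the KER graph
#'
#' `downstreamClosure` returns every event reachable from `event` by
#' following KERs forwards (the events a concern could cascade to);
#' `upstreamClosure` follows them backwards (the preceding events). The start
#' event itself is excluded.
#'
#' @param net A [KeyEventNetwork()].
#' @param event An event id.
#' @return Character vector of event ids (sorted).
#' @examples
#' net <- aopFixture("skin_sensitization")
#' downstreamClosure(net, "covalent_protein_binding")
#' @export
downstreamClosure <- function(net, event) {
  reachable(net, event, mode = "out")
}

#' @rdname downstreamClosure
#' @export
upstreamClosure <- function(net, event) {
  reachable(net, event, mode = "in")
}

reachable <- function(net, event, mode) {
  if (!event %in% events(net)$id) stop("unknown event id: ", event)
  g <- kerGraph(net)
  ids <- names(igraph::subcomponent(g, event, mode = mode))
  sort(setdiff(ids, event))
}

## Event groups ---------------------------------------------------------------

#' Members of an event group
#'
#' Direct members are the events assigned to the group plus any nested
#' groups; `recursive = TRUE` (default) flattens nesting down to events.
#'
#' @param net A [KeyEventNetwork()].
#' @param group A group id.
#' @param recursive Flatten nested groups to their events?
#' @return Character vector of event ids (plus group ids when not recursive).
#' @export
groupMembers <- function(net, group, recursive = TRUE) {
  gg <- eventGroups(net)
  if (!group %in% gg$id) stop("unknown group id: ", group)
  ev <- events(net)
  direct <- ev$id[!is.na(ev$group) & ev$group == group]
  sub <- gg$id[!is.na(gg$parent) & gg$parent == group]
  if (!recursive) return(c(direct, sub))
  for (s in sub) direct <- c(direct, groupMembers(net, s, recursive = TRUE))
  unique(direct)
}

#' Collapse or expand an event group in a view
#'
#' `collapseGroup` marks a group as collapsed (accepting either a network,
#' which is first wrapped into a view, or an existing view); `expandGroup`
#' reverses it and errors if the group is not currently collapsed. The
#' underlying network is stored untouched, so collapse followed by expand is
#' the identity. The visible node and edge sets of a view are computed by
#' [viewEvents()] and [viewKers()].
#'
#' @param x A [KeyEventNetwork()] or [NetworkView()].
#' @param group A group id.
#' @return A [NetworkView()].
#' @examples
#' v <- collapseGroup(aopFixture("rxr_carcinogenicity"), "p38_mapk_group")
#' nrow(viewEvents(v))
#' v2 <- expandGroup(v, "p38_mapk_group")
#' @export
collapseGroup <- function(x, group) {
  view <- if (is(x, "NetworkView")) x else NetworkView(x)
  if (!group %in% eventGroups(view)$id) stop("unknown group id: ", group)
  if (group %in% view@collapsed) stop("group already collapsed: ", group)
  NetworkView(view@network, c(view@collapsed, group))
}

#' @rdname collapseGroup
#' @export
expandGroup <- function(x, group) {
  if (!is(x, "NetworkView")) stop("expandGroup requires a NetworkView")
  if (!group %in% x@collapsed) stop("group is not collapsed: ", group)
  NetworkView(x@network, setdiff(x@collapsed, group))
}

#' Visible nodes and edges of a network view
#'
#' Computes the displayed graph: members of each collapsed group are replaced
#' by a single node carrying the group's id and name (role `"KEG"`; level
#' taken from the first member), edges crossing the group boundary are
#' re-homed to the group node, edges internal to a collapsed group disappear,
#' and parallel edges created by the merge are deduplicated keeping the
#' maximum KER strength.
#'
#' @param view A [NetworkView()] (a bare network is treated as a view with
#'   nothing collapsed).
#' @return `viewEvents`: data.frame like the `events` table plus group nodes;
#'   `viewKers`: data.frame like the `kers` table.
#' @export
viewEvents <- function(view) {
  if (!is(view, "NetworkView")) view <- NetworkView(view)
  net <- view@network
  ev <- events(net)
  gg <- eventGroups(net)
  hidden <- character(0)
  nodes <- ev
  for (g in view@collapsed) {
    members <- groupMembers(net, g)
    hidden <- union(hidden, members)
    first <- ev[ev$id %in% members, , drop = FALSE]
    lvl <- if (nrow(first)) first$level[1] else NA_character_
    nodes <- rbind(nodes, data.frame(
      id = g, name = gg$name[gg$id == g][1], level = lvl, role = "KEG",
      group = NA_character_, stringsAsFactors = FALSE))
  }
  nodes <- nodes[!nodes$id %in% hidden, , drop = FALSE]
  rownames(nodes) <- NULL
  nodes
}

#' @rdname viewEvents
#' @export
viewKers <- function(view) {
  if (!is(view, "NetworkView")) view <- NetworkView(view)
  net <- view@network
  kk <- kers(net)
  if (!nrow(kk)) return(kk)
  up <- kk$upstream; down <- kk$downstream
  for (g in view@collapsed) {
    members <- groupMembers(net, g)
    up[up %in% members] <- g
    down[down %in% members] <- g
  }
  out <- data.frame(upstream = up, downstream = down,
                    strength = kk$strength, stringsAsFactors = FALSE)
  out <- out[out$upstream != out$downstream, , drop = FALSE]
  if (nrow(out)) {
    key <- paste(out$upstream, out$downstream, sep = "\r")
    keep <- vapply(split(seq_len(nrow(out)), key), function(ix) {
      ix[which.max(levelIndex(out$strength[ix]))]
    }, integer(1))
    out <- out[sort(unname(keep)), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
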