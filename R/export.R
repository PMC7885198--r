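## Deterministic graph export. Layers are assigned by longest path from the
## sources (ties broken by node id); repeated exports of the same view are
## byte-identical. Display conventions: node colour encodes the concern
## state (red/green/grey), edge width class encodes the KER strength.

layerAssignment <- function(nodes, edges) {
  layer <- stats::setNames(rep(0L, nrow(nodes)), sort(nodes$id))
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges[, c("upstream", "downstream")],
                                       directed = TRUE, vertices = sort(nodes$id))
    for (v in names(igraph::topo_sort(g, mode = "out"))) {
      preds <- edges$upstream[edges$downstream == v]
      if (length(preds)) layer[v] <- max(layer[preds]) + 1L
    }
  }
  layer
}

stateColor <- function(state) {
  switch(state, Concern = "red", NoConcern = "green", Unknown = "grey",
         "grey")
}

#' Export a network view as DOT or GraphML
#'
#' Writes a deterministic text rendering of the visible graph: nodes carry
#' their organization level (swim lane), role, assigned layer and — when a
#' propagation result is supplied — a concern colour (red for concern, green
#' for no concern, grey for no data); edges carry the KER strength as a
#' width class (1..5). Exporting the same view twice produces byte-identical
#' files. Layout aesthetics beyond the layer assignment are left to the
#' rendering tool.
#'
#' @param view A [NetworkView()] or [KeyEventNetwork()].
#' @param path Output path.
#' @param format `"dot"` or `"graphml"`.
#' @param states Optional [PropagationResult()] colouring the events.
#' @return Invisibly, the path.
#' @export
exportGraph <- function(view, path, format = c("dot", "graphml"),
                        states = NULL) {
  format <- match.arg(format)
  nodes <- viewEvents(view)
  edges <- viewKers(view)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  edges <- edges[order(edges$upstream, edges$downstream), , drop = FALSE]
  layer <- layerAssignment(nodes, edges)

  stateOf <- function(id) {
    if (is.null(states)) return(NA_character_)
    st <- propagationStates(states)
    if ("state" %in% names(st)) {
      hit <- st$state[st$event == id]
      if (length(hit)) hit[1] else "Unknown"
    } else {
      hit <- st$direction[st$event == id]
      if (!length(hit)) "Unknown"
      else switch(hit[1], For = "Concern", Against = "NoConcern", "Unknown")
    }
  }

  lines <- character(0)
  if (format == "dot") {
    lines <- c("digraph ken {", "  rankdir=LR;")
    for (i in seq_len(nrow(nodes))) {
      id <- nodes$id[i]
      attrs <- c(sprintf('label="%s"', nodes$name[i]),
                 sprintf('level="%s"', nodes$level[i]),
                 sprintf('role="%s"', nodes$role[i]),
                 sprintf("layer=%d", layer[[id]]))
      s <- stateOf(id)
      if (!is.na(s))
        attrs <- c(attrs, sprintf('color="%s"', stateColor(s)),
                   'style="filled"')
      lines <- c(lines, sprintf("  \"%s\" [%s];", id,
                                paste(attrs, collapse = ", ")))
    }
    for (i in seq_len(nrow(edges))) {
      w <- levelIndex(edges$strength[i])
      lines <- c(lines, sprintf(
        "  \"%s\" -> \"%s\" [penwidth=%d, strength=\"%s\"];",
        edges$upstream[i], edges$downstream[i], w, edges$strength[i]))
    }
    lines <- c(lines, "}")
  } else {
    esc <- function(x) {
      x <- gsub("&", "&amp;", x, fixed = TRUE)
      x <- gsub("<", "&lt;", x, fixed = TRUE)
      gsub(">", "&gt;", x, fixed = TRUE)
    }
    lines <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <key id="d_name" for="node" attr.name="name" attr.type="string"/>',
      '  <key id="d_level" for="node" attr.name="level" attr.type="string"/>',
      '  <key id="d_role" for="node" attr.name="role" attr.type="string"/>',
      '  <key id="d_layer" for="node" attr.name="layer" attr.type="int"/>',
      '  <key id="d_color" for="node" attr.name="color" attr.type="string"/>',
      '  <key id="d_strength" for="edge" attr.name="strength" attr.type="string"/>',
      '  <key id="d_width" for="edge" attr.name="width" attr.type="int"/>',
      '  <graph id="ken" edgedefault="directed">')
    for (i in seq_len(nrow(nodes))) {
      id <- nodes$id[i]
      s <- stateOf(id)
      lines <- c(lines,
        sprintf('    <node id="%s">', esc(id)),
        sprintf('      <data key="d_name">%s</data>', esc(nodes$name[i])),
        sprintf('      <data key="d_level">%s</data>', esc(nodes$level[i])),
        sprintf('      <data key="d_role">%s</data>', esc(nodes$role[i])),
        sprintf('      <data key="d_layer">%d</data>', layer[[id]]),
        if (!is.na(s))
          sprintf('      <data key="d_color">%s</data>', stateColor(s)),
        "    </node>")
    }
    for (i in seq_len(nrow(edges))) {
      lines <- c(lines,
        sprintf('    <edge source="%s" target="%s">',
                esc(edges$upstream[i]), esc(edges$downstream[i])),
        sprintf('      <data key="d_strength">%s</data>',
                esc(edges$strength[i])),
        sprintf('      <data key="d_width">%d</data>',
                levelIndex(edges$strength[i])),
        "    </edge>")
    }
    lines <- c(lines, "  </graph>", "</graphml>")
  }
  writeLines(lines, path, sep = "\n")
  invisible(path)
}
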