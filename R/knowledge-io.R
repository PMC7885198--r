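## Knowledge files: YAML (or JSON) with top-level keys events, kers, groups,
## assays, assay_event_links, prediction_bases and an optional
## calculus_tables override. Each prediction basis carries its links inline.

#' Load or save a key event network
#'
#' `loadKnowledge` reads a YAML (`.yml`/`.yaml`) or JSON knowledge file,
#' reports schema violations with their locations, and refuses networks that
#' fail [validateNetwork()] — acyclicity and reference integrity are enforced
#' at load time because propagation semantics require them.
#' `saveKnowledge` writes the same format; load and save round-trip.
#'
#' @param path File path.
#' @return `loadKnowledge`: a [KeyEventNetwork()].
#' @examples
#' net <- aopFixture("skin_sensitization")
#' f <- tempfile(fileext = ".yaml")
#' saveKnowledge(net, f)
#' identical(events(loadKnowledge(f)), events(net))
#' @export
loadKnowledge <- function(path) {
  if (!file.exists(path)) stop("knowledge file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path) else yaml::read_yaml(path)
  errors <- character(0)
  say <- function(...) errors <<- c(errors, paste0(...))

  block <- function(key, fields, optional = character(0)) {
    entries <- raw[[key]]
    if (is.null(entries)) return(NULL)
    rows <- lapply(seq_along(entries), function(i) {
      e <- entries[[i]]
      missing <- setdiff(fields, names(e))
      if (length(missing)) {
        say(key, "[", i, "]: missing field(s) ",
            paste(missing, collapse = ", "))
        return(NULL)
      }
      vals <- lapply(c(fields, optional), function(f) {
        v <- e[[f]]
        if (is.null(v)) NA_character_ else as.character(v)
      })
      as.data.frame(stats::setNames(vals, c(fields, optional)),
                    stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) do.call(rbind, rows) else NULL
  }

  events <- block("events", c("id", "name", "level", "role"), "group")
  kersDf <- block("kers", c("upstream", "downstream", "strength"))
  groups <- block("groups", c("id", "name"), "parent")
  assaysDf <- block("assays", c("id", "name", "reliability", "tier"))
  links <- block("assay_event_links",
                 c("assay", "measurement", "event", "convincingness"))

  bases <- NULL; predLinks <- NULL
  pbs <- raw$prediction_bases
  if (!is.null(pbs)) {
    rows <- list(); lrows <- list()
    for (i in seq_along(pbs)) {
      b <- pbs[[i]]
      missing <- setdiff(c("model", "basis", "outcome_weight", "reliability"),
                         names(b))
      if (length(missing)) {
        say("prediction_bases[", i, "]: missing field(s) ",
            paste(missing, collapse = ", "))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        model = b$model, basis = b$basis,
        outcome_weight = b$outcome_weight, reliability = b$reliability,
        stringsAsFactors = FALSE)
      for (j in seq_along(b$links)) {
        l <- b$links[[j]]
        lmiss <- setdiff(c("kind", "target", "convincingness"), names(l))
        if (length(lmiss)) {
          say("prediction_bases[", i, "]$links[", j, "]: missing field(s) ",
              paste(lmiss, collapse = ", "))
          next
        }
        lrows[[length(lrows) + 1L]] <- data.frame(
          model = b$model, basis = b$basis, kind = l$kind, target = l$target,
          convincingness = l$convincingness, stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) bases <- do.call(rbind, rows)
    if (length(lrows)) predLinks <- do.call(rbind, lrows)
  }

  tables <- if (!is.null(raw$calculus_tables_file))
    loadCalculusTables(file.path(dirname(path), raw$calculus_tables_file))
  else list()

  if (length(errors))
    stop("knowledge file schema violations:\n  ",
         paste(errors, collapse = "\n  "))
  net <- KeyEventNetwork(events, kersDf, groups, assaysDf, links, bases,
                         predLinks, tables)
  v <- validateNetwork(net)
  if (nrow(v))
    stop("knowledge file does not validate:\n  ",
         paste(sprintf("[%s] %s (%s)", v$rule, v$message, v$subject),
               collapse = "\n  "))
  net
}

#' @rdname loadKnowledge
#' @param net A [KeyEventNetwork()].
#' @export
saveKnowledge <- function(net, path) {
  dfToList <- function(df) {
    lapply(seq_len(nrow(df)), function(i) {
      row <- as.list(df[i, , drop = FALSE])
      row <- lapply(row, unname)
      row[!vapply(row, function(x) length(x) == 1 && is.na(x), logical(1))]
    })
  }
  pb <- predictionBases(net); pl <- predictionLinks(net)
  basesList <- lapply(seq_len(nrow(pb)), function(i) {
    sel <- pl$model == pb$model[i] & pl$basis == pb$basis[i]
    c(as.list(pb[i, , drop = FALSE]),
      list(links = dfToList(pl[sel, c("kind", "target", "convincingness"),
                               drop = FALSE])))
  })
  doc <- list(events = dfToList(events(net)),
              kers = dfToList(kers(net)),
              groups = dfToList(eventGroups(net)),
              assays = dfToList(assays(net)),
              assay_event_links = dfToList(assayEventLinks(net)),
              prediction_bases = basesList)
  doc <- doc[vapply(doc, length, integer(1)) > 0]
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  else yaml::write_yaml(doc, path)
  invisible(path)
}
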