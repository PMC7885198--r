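callSynonyms <- function() {
  list(Positive = c("positive", "active", "pos", "+"),
       Negative = c("negative", "inactive", "neg", "-", "−"),
       Conflicted = c("conflicted", "equivocal-conflict"))
}

#' Normalize raw result-call vocabulary
#'
#' Maps the call spellings encountered across source datasets onto the
#' three-value vocabulary: positive/active/pos/+ to Positive,
#' negative/inactive/neg/- to Negative, conflicted/equivocal-conflict to
#' Conflicted (all case-insensitive, whitespace-trimmed). Anything else is
#' rejected — results without a clear call are excluded rather than guessed.
#'
#' @param raw Character vector of raw call texts.
#' @return data.frame with columns `raw`, `call` (`NA` where rejected) and
#'   `accepted`.
#' @examples
#' normalizeCall(c("active", "Negative", "maybe"))
#' @export
normalizeCall <- function(raw) {
  syn <- callSynonyms()
  lut <- stats::setNames(rep(names(syn), lengths(syn)),
                         unlist(syn, use.names = FALSE))
  key <- tolower(trimws(raw))
  call <- unname(lut[key])
  data.frame(raw = raw, call = call, accepted = !is.na(call),
             stringsAsFactors = FALSE)
}

#' Overall call from repeated results under one assay definition
#'
#' The aggregation scheme for a compound tested more than once in the same
#' assay (same variables): all Positive stays Positive, all Negative stays
#' Negative, all Conflicted stays Conflicted, and any mixture of distinct
#' calls becomes Conflicted. Idempotent by construction.
#'
#' @param calls Nonempty character vector of normalized calls.
#' @return A single call.
#' @examples
#' overallCall(c("Positive", "Negative"))  # Conflicted
#' @export
overallCall <- function(calls) {
  if (length(calls) == 0L) stop("cannot take the overall call of no results")
  bad <- setdiff(calls, c("Positive", "Negative", "Conflicted"))
  if (length(bad)) stop("unnormalized call(s): ", paste(bad, collapse = ", "))
  u <- unique(calls)
  if (length(u) > 1L) "Conflicted" else u
}

# "Rat S9", "S9 Rat", "rattus s9" -> one canonical token ("rat s9" sorted).
canonicalizeVariables <- function(vars) {
  vapply(vars, function(v) {
    if (is.na(v) || !nzchar(v)) return("")
    pairs <- strsplit(v, ";", fixed = TRUE)[[1]]
    canon <- vapply(pairs, function(p) {
      kv <- strsplit(p, "=", fixed = TRUE)[[1]]
      key <- tolower(trimws(kv[1]))
      val <- if (length(kv) > 1) tolower(trimws(kv[2])) else ""
      toks <- sort(strsplit(val, "[ \t]+")[[1]])
      paste0(key, "=", paste(toks, collapse = " "))
    }, character(1))
    paste(sort(canon), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
}

#' Group raw results into per-assay-definition overall calls
#'
#' Records are grouped by compound, assay, measurement and the canonicalized
#' variable map (variable values are case-folded and token-sorted, so
#' "Rat S9" and "S9 Rat" define the same assay); [overallCall()] is applied
#' within each group. Records whose call fails [normalizeCall()] are dropped
#' and reported. The result does not depend on record order.
#'
#' @param records data.frame with columns `compound`, `assay`, `measurement`,
#'   `variables` (semicolon-separated `key=value` pairs, possibly empty),
#'   `call` (raw text), and optionally `source`.
#' @return List with `calls` (data.frame `compound`, `assay`, `measurement`,
#'   `variables` (canonical), `call`, `n_results`) and `rejected` (the
#'   offending raw rows).
#' @export
groupResults <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"measurement" %in% names(records))
    records$measurement <- "overall_call"
  if (!"variables" %in% names(records)) records$variables <- ""
  norm <- normalizeCall(records$call)
  rejected <- records[!norm$accepted, , drop = FALSE]
  records <- records[norm$accepted, , drop = FALSE]
  records$call <- norm$call[norm$accepted]
  records$variables <- canonicalizeVariables(records$variables)
  if (!nrow(records))
    return(list(calls = records[, c("compound", "assay", "measurement",
                                    "variables", "call")],
                rejected = rejected))
  key <- paste(records$compound, records$assay, records$measurement,
               records$variables, sep = "\r")
  groups <- split(seq_len(nrow(records)), key)
  calls <- do.call(rbind, lapply(groups[order(names(groups))], function(ix) {
    first <- records[ix[1], , drop = FALSE]
    data.frame(compound = first$compound, assay = first$assay,
               measurement = first$measurement, variables = first$variables,
               call = overallCall(records$call[ix]),
               n_results = length(ix), stringsAsFactors = FALSE)
  }))
  rownames(calls) <- NULL
  list(calls = calls, rejected = rejected)
}

#' Read a compound call table
#'
#' The one supported CSV dialect: columns `compound_id`, `assay_id`,
#' `measurement_id`, `variables` (semicolon `key=value` pairs), `call`,
#' `source`. Missing optional columns (`measurement_id`, `variables`,
#' `source`) are filled with defaults. Calls are returned raw; run
#' [groupResults()] to normalize and aggregate.
#'
#' @param path Path to the CSV.
#' @return data.frame with columns `compound`, `assay`, `measurement`,
#'   `variables`, `call`, `source`.
#' @export
readCalls <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("compound_id", "assay_id", "call") %in% names(df)))
    stop("call CSV needs at least compound_id, assay_id, call")
  data.frame(
    compound = df$compound_id, assay = df$assay_id,
    measurement = if ("measurement_id" %in% names(df)) df$measurement_id
                  else "overall_call",
    variables = if ("variables" %in% names(df)) df$variables else "",
    call = df$call,
    source = if ("source" %in% names(df)) df$source else NA_character_,
    stringsAsFactors = FALSE)
}

#' Write a propagation report as CSV
#'
#' One row per event: its state (or signed strength) and the provenance items
#' behind it, semicolon-joined.
#'
#' @param result A [PropagationResult()].
#' @param path Output path.
#' @return Invisibly, the written data.frame.
#' @export
writePropagation <- function(result, path) {
  df <- propagationStates(result)
  prov <- propagationProvenance(result)
  df$provenance <- vapply(df$event, function(e)
    paste(prov[[e]], collapse = "; "), character(1))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(df)
}
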