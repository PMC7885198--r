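## Hashed linear-path fingerprint over the molecular graph. SMILES parsing,
## canonicalization and aromatic ring perception are delegated to
## ChemmineR/ChemmineOB; the path enumeration and hashing are defined here so
## the scheme is fully documented and deterministic.

requireChem <- function() {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE))
    stop("the path_default fingerprint needs the ChemmineR and ChemmineOB ",
         "packages; supply precomputed fingerprints or use another scheme")
}

# FNV-1a over the UTF-8 bytes of a string, folded into [0, 2^31).
# Exact in double arithmetic: products are kept below 2^53 by splitting the
# 32-bit state into 16-bit halves before multiplying by the FNV prime.
hashFeature <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    h <- bitwXor(h %% 2^31, b) + (h %/% 2^31) * 2^31  # xor on low 31 bits
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ((hi * p) %% 4294967296 * 65536 + lo * p) %% 4294967296
  }
  as.integer(h %% 2^31)
}

# Molecular graph from a SMILES string: atoms (element, aromatic flag) and
# bonds (endpoints, symbol). Canonicalization first, so different SMILES of
# the same molecule give the same graph (and the same kekulization).
smilesGraph <- function(smiles) {
  requireChem()
  canon <- ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\n"))
  canon <- strsplit(canon, "[ \t\n]")[[1]][1]
  if (is.na(canon) || !nzchar(canon)) stop("unparsable SMILES: ", smiles)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(canon))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  atomNames <- rownames(ab)
  element <- sub("_.*$", "", atomNames)
  nAtoms <- length(atomNames)
  bb <- ChemmineR::bondblock(sdf)
  aromaticAtom <- rep(FALSE, nAtoms)
  aromaticRings <- list()
  if (nAtoms >= 3 && nrow(bb)) {
    r <- tryCatch(ChemmineR::rings(sdf, type = "all", arom = TRUE),
                  error = function(e) NULL)
    if (!is.null(r) && length(r$RINGS)) {
      aromaticRings <- r$RINGS[which(r$AROMATIC)]
      inAromatic <- unique(unlist(aromaticRings))
      aromaticAtom[match(inAromatic, atomNames)] <- TRUE
    }
  }
  bonds <- NULL
  if (!is.null(bb) && nrow(bb)) {
    a1 <- as.integer(bb[, 1]); a2 <- as.integer(bb[, 2])
    order <- as.integer(bb[, 3])
    arom <- logical(length(a1))
    for (ring in aromaticRings) {
      ix <- match(ring, atomNames)
      arom <- arom | (a1 %in% ix & a2 %in% ix)
    }
    sym <- ifelse(arom, ":", c("-", "=", "#", "$")[pmin(order, 4L)])
    bonds <- data.frame(a1 = a1, a2 = a2, sym = sym, stringsAsFactors = FALSE)
  }
  label <- ifelse(aromaticAtom, tolower(element), element)
  list(label = label, bonds = bonds)
}

# All linear atom/bond paths of 1..maxLen atoms, as canonical strings
# (the lexicographically smaller of a path and its reverse).
pathFeatures <- function(graph, maxLen = 7L) {
  n <- length(graph$label)
  if (n == 0L) return(character(0))
  adj <- vector("list", n)
  if (!is.null(graph$bonds) && nrow(graph$bonds)) {
    for (i in seq_len(nrow(graph$bonds))) {
      a <- graph$bonds$a1[i]; b <- graph$bonds$a2[i]; s <- graph$bonds$sym[i]
      adj[[a]] <- rbind(adj[[a]], data.frame(to = b, sym = s))
      adj[[b]] <- rbind(adj[[b]], data.frame(to = a, sym = s))
    }
  }
  feats <- character(0)
  walk <- function(atom, visited, str, depth) {
    feats[[length(feats) + 1L]] <<- str
    if (depth == maxLen) return()
    nb <- adj[[atom]]
    if (is.null(nb)) return()
    for (i in seq_len(nrow(nb))) {
      nxt <- nb$to[i]
      if (nxt %in% visited) next
      walk(nxt, c(visited, nxt),
           paste0(str, nb$sym[i], graph$label[nxt]), depth + 1L)
    }
  }
  for (a in seq_len(n)) walk(a, a, graph$label[a], 1L)
  revPath <- function(s) {
    toks <- regmatches(s, gregexpr("[A-Za-z]+|[-=#$:]", s))[[1]]
    paste(rev(toks), collapse = "")
  }
  unique(vapply(feats, function(s) min(s, revPath(s)), character(1),
                USE.NAMES = FALSE))
}

#' Compute a compound fingerprint
#'
#' Three schemes:
#' * `path_default` — hashed linear atom/bond paths of length 1 to
#'   `maxLength` atoms over the hydrogen-suppressed molecular graph. Atom
#'   labels are element symbols, lower-cased for atoms in perceived aromatic
#'   rings; bond symbols distinguish single/double/triple/aromatic. Each path
#'   (read in its lexicographically smaller direction) is hashed with FNV-1a
#'   into an integer feature. Identical molecules give identical
#'   fingerprints whatever SMILES spelling they arrive in, because the
#'   structure is canonicalized first.
#' * `alert_based` — the simple biological fingerprint: the set of fired
#'   prediction-basis ids (pass them via `alerts`). Compounds are similar if
#'   they fire the same alerts.
#' * anything else — a plug-in: supply `features`, a character vector of
#'   arbitrary feature strings computed by an external toolkit; they are
#'   hashed the same way. Similarity is measure-dependent by design, so the
#'   scheme is pluggable.
#'
#' @param smiles A SMILES string (`path_default` only).
#' @param scheme Scheme id.
#' @param alerts Character vector of fired alert ids (`alert_based`).
#' @param features Character vector of plug-in features.
#' @param maxLength Maximum path length in atoms (default 7).
#' @return A [Fingerprint()].
#' @examples
#' \donttest{
#' fingerprint("CCO")  # identical to fingerprint("OCC")
#' }
#' fingerprint(scheme = "alert_based", alerts = c("a1", "a2"))
#' @export
fingerprint <- function(smiles = NULL, scheme = "path_default",
                        alerts = NULL, features = NULL, maxLength = 7L) {
  if (scheme == "path_default") {
    if (is.null(smiles)) stop("path_default needs a SMILES string")
    feats <- pathFeatures(smilesGraph(smiles), maxLength)
  } else if (scheme == "alert_based") {
    if (is.null(alerts)) stop("alert_based needs the fired alert ids")
    feats <- unique(as.character(alerts))
  } else {
    if (is.null(features)) stop("plug-in schemes need precomputed features")
    feats <- unique(as.character(features))
  }
  Fingerprint(vapply(feats, hashFeature, integer(1), USE.NAMES = FALSE), scheme)
}

#' Tanimoto coefficient between two fingerprints
#'
#' |A intersect B| / |A union B| over the feature sets; 1 when both sets are
#' empty (two featureless objects are indistinguishable). Comparing
#' fingerprints from different schemes is an error, not a 0.
#'
#' @param a,b [Fingerprint()] objects of the same scheme.
#' @return A number in [0, 1].
#' @examples
#' a <- Fingerprint(1:4, "x"); b <- Fingerprint(3:6, "x")
#' tanimoto(a, b)  # 2/6
#' @export
tanimoto <- function(a, b) {
  if (fingerprintScheme(a) != fingerprintScheme(b))
    stop("fingerprint scheme mismatch: ", fingerprintScheme(a), " vs ",
         fingerprintScheme(b))
  ba <- fingerprintBits(a); bb <- fingerprintBits(b)
  u <- length(union(ba, bb))
  if (u == 0L) return(1)
  length(intersect(ba, bb)) / u
}

#' Similarity neighborhood of a query compound
#'
#' All dataset compounds at Tanimoto similarity >= `cutoff` to the query,
#' sorted by descending similarity (ties broken by compound id). A query
#' present in the dataset ranks first with similarity 1.
#'
#' @param query A [Fingerprint()], or a SMILES string (fingerprinted with
#'   `scheme`).
#' @param dataset Named list of [Fingerprint()]s, or a data.frame with
#'   columns `id` and `smiles`.
#' @param cutoff Similarity threshold in [0, 1].
#' @param scheme Scheme used when fingerprinting SMILES input.
#' @return data.frame with columns `id`, `similarity`.
#' @export
neighbors <- function(query, dataset, cutoff, scheme = "path_default") {
  if (cutoff < 0 || cutoff > 1) stop("cutoff must lie in [0, 1]")
  if (is.character(query)) query <- fingerprint(query, scheme)
  if (is.data.frame(dataset)) {
    fps <- lapply(dataset$smiles, fingerprint, scheme = scheme)
    names(fps) <- dataset$id
    dataset <- fps
  }
  sims <- vapply(dataset, tanimoto, numeric(1), a = query)
  keep <- sims >= cutoff
  out <- data.frame(id = names(sims)[keep], similarity = unname(sims[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$similarity, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-assay activity profile of a compound set
#'
#' Counts Positive and Negative overall calls per assay among a compound set
#' (a similarity neighborhood, typically). Conflicted and missing calls are
#' excluded from both counts; the positive proportion is taken over the
#' informative calls only, so profiles of differently sized sets compare
#' directly. `proportion_pos` is `NA` when a set contributes no informative
#' call.
#'
#' @param compounds Character vector of compound ids.
#' @param calls data.frame with columns `compound`, `assay`, `call`
#'   (normalized overall calls).
#' @param assayIds Assays to profile (default: all present in `calls`).
#' @return data.frame with columns `assay`, `n_pos`, `n_neg`,
#'   `proportion_pos`.
#' @export
activityProfile <- function(compounds, calls, assayIds = NULL) {
  if (is.null(assayIds)) assayIds <- sort(unique(calls$assay))
  sub <- calls[calls$compound %in% compounds, , drop = FALSE]
  out <- lapply(assayIds, function(a) {
    cc <- sub$call[sub$assay == a]
    nPos <- sum(cc == "Positive"); nNeg <- sum(cc == "Negative")
    data.frame(assay = a, n_pos = nPos, n_neg = nNeg,
               proportion_pos = if (nPos + nNeg > 0) nPos / (nPos + nNeg)
                                else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Overlap between two neighbor sets
#'
#' Set algebra for comparing the compound sets selected by two similarity
#' measures: counts unique to each, shared, and total.
#'
#' @param a,b Character vectors of compound ids.
#' @return Named numeric vector `a_only`, `b_only`, `both`, `total`.
#' @examples
#' compareNeighborSets(c("1", "2", "3"), c("2", "3", "4"))
#' @export
compareNeighborSets <- function(a, b) {
  a <- unique(a); b <- unique(b)
  c(a_only = length(setdiff(a, b)), b_only = length(setdiff(b, a)),
    both = length(intersect(a, b)), total = length(union(a, b)))
}

#' Read a SMILES file
#'
#' One compound per line: SMILES, whitespace, id.
#'
#' @param path Path to a `.smi` file.
#' @return data.frame with columns `id`, `smiles`.
#' @export
readSmiles <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  data.frame(id = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                         character(1)),
             smiles = vapply(parts, `[[`, character(1), 1),
             stringsAsFactors = FALSE)
}
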