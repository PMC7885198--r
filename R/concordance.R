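#' Phi coefficient between two assays' calls
#'
#' Restricts to compounds with a Positive-or-Negative call in both assays
#' (Conflicted and missing calls are non-informative), builds the 2x2 table
#' (a = both positive, b = positive/negative, c = negative/positive, d = both
#' negative) and returns phi = (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d)) with
#' the informative count n. When any margin of the table is zero the
#' correlation is undefined and the cell is masked (`phi = NA`) rather than
#' set to 0, to avoid fabricating independence. Phi equals the Pearson
#' correlation of the 0/1-coded calls on the same support.
#'
#' @param callsA,callsB Character vectors of calls, aligned by position (or
#'   by names when both are named).
#' @return List with `phi` (number in [-1, 1] or `NA` when masked) and `n`.
#' @examples
#' phiCoefficient(c("Positive", "Positive", "Negative", "Negative"),
#'                c("Positive", "Negative", "Positive", "Negative"))
#' @export
phiCoefficient <- function(callsA, callsB) {
  if (!is.null(names(callsA)) && !is.null(names(callsB))) {
    shared <- intersect(names(callsA), names(callsB))
    callsA <- callsA[shared]; callsB <- callsB[shared]
  }
  if (length(callsA) != length(callsB))
    stop("call vectors must be paired over the same compounds")
  ok <- callsA %in% c("Positive", "Negative") &
        callsB %in% c("Positive", "Negative")
  x <- callsA[ok] == "Positive"
  y <- callsB[ok] == "Positive"
  n <- sum(ok)
  a <- sum(x & y); b <- sum(x & !y); cc <- sum(!x & y); d <- sum(!x & !y)
  margins <- c(a + b, cc + d, a + cc, b + d)
  if (n == 0L || any(margins == 0L)) return(list(phi = NA_real_, n = n))
  list(phi = (a * d - b * cc) / sqrt(prod(margins)), n = n)
}

#' Assay-by-assay call concordance matrix
#'
#' Computes [phiCoefficient()] for every assay pair over a long call table.
#' Cells with fewer than `minN` informative pairs, or with a degenerate 2x2
#' margin, are masked (`NA`) — too few points to make a correlation. The
#' diagonal is 1 with n equal to each assay's informative call count.
#'
#' @param calls data.frame with columns `compound`, `assay`, `call`.
#' @param assayIds Assays to include (default: all in `calls`, sorted).
#' @param minN Minimum informative pair count before masking (default 5).
#' @return List with matrices `phi` and `n` (assay x assay).
#' @seealso [conditionSubset()], [similaritySubset()]
#' @export
concordanceMatrix <- function(calls, assayIds = NULL, minN = 5L) {
  if (minN < 2L) stop("minN must be at least 2")
  if (is.null(assayIds)) assayIds <- sort(unique(calls$assay))
  k <- length(assayIds)
  phi <- matrix(NA_real_, k, k, dimnames = list(assayIds, assayIds))
  n <- matrix(0L, k, k, dimnames = list(assayIds, assayIds))
  callVec <- function(a) {
    sub <- calls[calls$assay == a, , drop = FALSE]
    stats::setNames(sub$call, sub$compound)
  }
  vecs <- lapply(assayIds, callVec)
  names(vecs) <- assayIds
  for (i in seq_len(k)) {
    informative <- sum(vecs[[i]] %in% c("Positive", "Negative"))
    phi[i, i] <- 1
    n[i, i] <- informative
    if (i == k) break
    for (j in seq((i + 1L), k)) {
      cell <- phiCoefficient(vecs[[i]], vecs[[j]])
      nn <- cell$n
      p <- if (nn < minN) NA_real_ else cell$phi
      phi[i, j] <- phi[j, i] <- p
      n[i, j] <- n[j, i] <- nn
    }
  }
  list(phi = phi, n = n)
}

#' Filter a call dataset by an existing call or by chemical similarity
#'
#' `conditionSubset` keeps the compounds whose call in `byAssay` equals
#' `call` — the chemical-context filter behind call-conditioned heat maps.
#' Conditioning removes the conditioning assay's informative variance, so its
#' row and column are necessarily masked afterwards. `similaritySubset`
#' keeps the compounds whose Tanimoto similarity to the query reaches
#' `cutoff` (see [neighbors()]).
#'
#' @param calls data.frame with columns `compound`, `assay`, `call`.
#' @param byAssay Conditioning assay id.
#' @param call The required call in `byAssay`.
#' @return The filtered call data.frame.
#' @export
conditionSubset <- function(calls, byAssay, call) {
  keep <- unique(calls$compound[calls$assay == byAssay & calls$call == call])
  calls[calls$compound %in% keep, , drop = FALSE]
}

#' @rdname conditionSubset
#' @param compounds data.frame with columns `id`, `smiles` (or named list of
#'   [Fingerprint()]s).
#' @param query SMILES string or [Fingerprint()] of the compound under study.
#' @param cutoff Tanimoto threshold.
#' @param scheme Fingerprint scheme for SMILES input.
#' @export
similaritySubset <- function(calls, compounds, query, cutoff,
                             scheme = "path_default") {
  nb <- neighbors(query, compounds, cutoff, scheme)
  calls[calls$compound %in% nb$id, , drop = FALSE]
}

#' Write a concordance matrix as CSV
#'
#' Two layers (phi and n) stacked long-form, one row per assay pair, suitable
#' for rendering a heat map. Masked cells carry an empty phi field.
#'
#' @param mat Result of [concordanceMatrix()].
#' @param path Output path.
#' @return Invisibly, the written data.frame.
#' @export
writeConcordance <- function(mat, path) {
  ids <- rownames(mat$phi)
  df <- expand.grid(assay_a = ids, assay_b = ids, KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  df$phi <- as.vector(mat$phi)
  df$n <- as.vector(mat$n)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(df)
}
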