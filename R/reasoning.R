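#' Strength of an argument from its convincingness and reliability
#'
#' An argument's strength is the exact lookup of the 3x3 weighting table on
#' the intrinsic convincingness of the argument and the reliability (or
#' consistency) of the evidence behind it. The default table is symmetric in
#' the two grades: a Large/Small pairing yields Medium whichever quality is
#' Large.
#'
#' @param convincingness,reliability Vectors over [grades()], recycled.
#' @param tables Calculus tables ([loadCalculusTables()]); `NULL` for the
#'   packaged defaults.
#' @return Character vector of [strengthLevels()].
#' @examples
#' strengthOf("Large", "Large")   # VeryHigh
#' strengthOf("Small", "Large")   # Medium
#' @export
strengthOf <- function(convincingness, reliability, tables = NULL) {
  tables <- checkTables(tables)
  gradeIndex(convincingness); gradeIndex(reliability)
  n <- max(length(convincingness), length(reliability))
  convincingness <- rep_len(convincingness, n)
  reliability <- rep_len(reliability, n)
  vapply(seq_len(n), function(i)
    tables$weighting[reliability[i], convincingness[i]], character(1))
}

#' Combine two same-direction argument strengths
#'
#' Exact lookup of the 5x5 combination table. Small strengths can reinforce
#' each other into higher ones, but only so far: very low arguments do not
#' enhance medium-or-stronger arguments, and low arguments do not enhance
#' high-or-stronger ones. The table is commutative and never returns less
#' than the stronger input, but it is not associative — which is why
#' multi-argument combination is defined by [combineSorted()], not by an
#' arbitrary fold order.
#'
#' @param a,b Strength levels.
#' @param tables See [strengthOf()].
#' @return A strength level.
#' @examples
#' combinePair("VeryLow", "VeryLow")  # Low
#' combinePair("Medium", "VeryLow")   # Medium
#' @export
combinePair <- function(a, b, tables = NULL) {
  tables <- checkTables(tables)
  levelIndex(a); levelIndex(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  vapply(seq_len(n), function(i) tables$combination[a[i], b[i]], character(1))
}

#' Combine several same-direction strengths
#'
#' The normative multi-argument rule: sort the strengths from lowest to
#' highest and combine them sequentially with [combinePair()]. Sorting first
#' matters because pairwise combination is not associative — four very-low
#' arguments build up to Medium (VL+VL = L, L+VL = M, M+VL = M), whereas a
#' different bracketing could differ.
#'
#' @param strengths Nonempty character vector of strength levels.
#' @param tables See [strengthOf()].
#' @return A single strength level.
#' @examples
#' combineSorted(rep("VeryLow", 4))  # Medium
#' @export
combineSorted <- function(strengths, tables = NULL) {
  if (length(strengths) == 0L) stop("cannot combine an empty strength list")
  tables <- checkTables(tables)
  sorted <- strengths[order(levelIndex(strengths))]
  Reduce(function(a, b) combinePair(a, b, tables), sorted)
}

#' Combine opposing argument strengths
#'
#' Exact lookup of the signed 5x5 opposition table: the aggregate strength
#' against a conclusion meets the aggregate strength for it, and the result
#' is a signed strength. Equal strengths balance exactly (zero diagonal);
#' even the strongest argument can be offset by an equally strong argument
#' against — there are no irrefutable arguments. The table is antisymmetric
#' under swapping the two sides but deliberately not monotone (it is applied
#' literally, with no smoothing).
#'
#' @param against,for_ Strength levels of the two aggregate sides.
#' @param tables See [strengthOf()].
#' @return A [SignedStrength()].
#' @examples
#' oppose("Medium", "Medium")   # Balanced
#' oppose("High", "Medium")     # Against / Medium
#' @export
oppose <- function(against, for_, tables = NULL) {
  tables <- checkTables(tables)
  levelIndex(against); levelIndex(for_)
  parseSigned(tables$opposition[against, for_])
}

#' Transmit a strength along a key event relationship
#'
#' An argument travelling to the next event is capped by the connection: take
#' the lower value of the argument and the KER strength. This is the lattice
#' meet on the five-level order (commutative, idempotent, monotone).
#'
#' @param argument,ker Strength levels.
#' @return A strength level (vectorized).
#' @examples
#' transmitStrength("Medium", "Low")  # Low
#' @export
transmitStrength <- function(argument, ker) {
  n <- max(length(argument), length(ker))
  a <- rep_len(levelIndex(argument), n)
  k <- rep_len(levelIndex(ker), n)
  strengthLevels()[pmin(a, k)]
}

#' Resolve a mixed list of for/against arguments
#'
#' The full calculus for one conclusion: (1) each argument's strength is
#' derived from its grades via [strengthOf()]; (2) arguments of equal
#' strength but opposite direction cancel pairwise; (3) the surviving
#' strengths on each side are combined with [combineSorted()]; (4) if both
#' sides survive the two aggregates meet in [oppose()]; a single surviving
#' side is returned signed; no survivors means a balanced conclusion.
#' Because equal-strength pairs are interchangeable, the result does not
#' depend on the order of the input rows.
#'
#' @param arguments data.frame with columns `direction` (`"For"`/`"Against"`)
#'   and either `strength` or both `convincingness` and `reliability`.
#'   Zero rows are allowed.
#' @param tables See [strengthOf()].
#' @return A [SignedStrength()].
#' @examples
#' resolveArguments(data.frame(
#'   direction = c("Against", "For", "For"),
#'   strength = c("Medium", "Medium", "Low")))  # For / Low
#' @export
resolveArguments <- function(arguments, tables = NULL) {
  tables <- checkTables(tables)
  if (is.null(arguments) || nrow(arguments) == 0L) return(balanced())
  if (!"strength" %in% names(arguments))
    arguments$strength <- strengthOf(arguments$convincingness,
                                     arguments$reliability, tables)
  bad <- setdiff(arguments$direction, c("For", "Against"))
  if (length(bad)) stop("unknown argument direction: ", paste(bad, collapse = ", "))
  resolveSigned(arguments$direction, arguments$strength, tables)
}

# Core of resolve, on already-derived strengths.
resolveSigned <- function(direction, strength, tables = NULL) {
  tables <- checkTables(tables)
  lev <- strengthLevels()
  nFor <- tabulate(levelIndex(strength[direction == "For"]), 5L)
  nAgainst <- tabulate(levelIndex(strength[direction == "Against"]), 5L)
  cancelled <- pmin(nFor, nAgainst)
  nFor <- nFor - cancelled
  nAgainst <- nAgainst - cancelled
  aggregate <- function(counts) {
    if (sum(counts) == 0L) return(NULL)
    combineSorted(rep(lev, counts), tables)
  }
  aFor <- aggregate(nFor)
  aAgainst <- aggregate(nAgainst)
  if (is.null(aFor) && is.null(aAgainst)) return(balanced())
  if (is.null(aAgainst)) return(SignedStrength(aFor, "For"))
  if (is.null(aFor)) return(SignedStrength(aAgainst, "Against"))
  oppose(aAgainst, aFor, tables)
}

#' Conservative merge of cause-for-concern states
#'
#' Where an event has both cause-for-concern and no-cause-for-concern inputs,
#' the overall call is cause for concern: any Concern wins, otherwise any
#' NoConcern, otherwise Unknown (no data).
#'
#' @param states Character vector over [concernStates()] (may be empty).
#' @return A single concern state.
#' @examples
#' conservativeMerge(c("Concern", "NoConcern"))  # Concern
#' @export
conservativeMerge <- function(states) {
  bad <- setdiff(states, concernStates())
  if (length(bad)) stop("unknown concern state: ", paste(bad, collapse = ", "))
  if (any(states == "Concern")) "Concern"
  else if (any(states == "NoConcern")) "NoConcern"
  else "Unknown"
}

#' Tiered merge: assay results overrule predictions
#'
#' The alternative paradigm in which evidence of higher biological complexity
#' overrules lower tiers: human observation over in vivo, in vivo over the in
#' vitro / in chemico tiers, and every measured result over in silico
#' prediction. Evidence is restricted to the highest-ranked tier carrying an
#' informative (non-Unknown) state, then merged conservatively within it.
#'
#' @param tiers Character vector over [assayTiers()].
#' @param states Concern states, parallel to `tiers`.
#' @param tierRanks Named rank vector; see [defaultTierRanks()].
#' @return A single concern state.
#' @examples
#' tieredMerge(c("in_vitro", "in_silico"), c("NoConcern", "Concern"))
#' @export
tieredMerge <- function(tiers, states, tierRanks = defaultTierRanks()) {
  if (length(tiers) != length(states))
    stop("tiers and states must have the same length")
  if (length(tiers) == 0L) return("Unknown")
  rank <- tierRanks[tiers]
  if (anyNA(rank)) stop("unknown tier: ",
                        paste(unique(tiers[is.na(rank)]), collapse = ", "))
  informative <- states != "Unknown"
  if (!any(informative)) return("Unknown")
  top <- max(rank[informative])
  conservativeMerge(states[informative & rank == top])
}

#' Weighted pie-chart scoring of arguments
#'
#' A simple single-dimension weighting: each argument carries an
#' expert-assigned weight and a concern score in [-1, +1] (-1 = no concern,
#' +1 = great concern, 0 = equivocal). The overall score is the
#' weight-normalized mean; it is translated to an overall call via a symmetric
#' threshold (default 0.15) so that modest re-weighting of conflicting
#' arguments can flip the call.
#'
#' @param weights Nonnegative weights, at least one positive.
#' @param scores Scores in [-1, 1], parallel to `weights`.
#' @param threshold Calls Concern above `+threshold`, NoConcern below
#'   `-threshold`, Unknown (equivocal) between.
#' @return List with `score` and `state`.
#' @examples
#' weightedScore(c(75, 23, 2), c(-1, 1, 1))  # score -0.5, NoConcern
#' @export
weightedScore <- function(weights, scores, threshold = 0.15) {
  if (length(weights) != length(scores))
    stop("weights and scores must have the same length")
  if (length(weights) == 0L || all(weights == 0)) stop("all weights are zero")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (any(abs(scores) > 1)) stop("scores must lie in [-1, 1]")
  score <- sum(weights * scores) / sum(weights)
  state <- if (score > threshold) "Concern"
           else if (score < -threshold) "NoConcern"
           else "Unknown"
  list(score = score, state = state)
}
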