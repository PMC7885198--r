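# Independent oracles used across the suite.

# Brute-force reachability by boolean matrix powers (no graph library).
bruteForceClosure <- function(net, from, direction = c("down", "up")) {
  direction <- match.arg(direction)
  ids <- events(net)$id
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  kk <- kers(net)
  for (i in seq_len(nrow(kk))) A[kk$upstream[i], kk$downstream[i]] <- TRUE
  if (direction == "up") A <- t(A)
  reach <- A
  for (step in seq_len(n)) reach <- reach | (reach %*% A > 0)
  sort(setdiff(ids[reach[from, ]], from))
}

# Pearson correlation of 0/1-coded calls on the shared informative support.
pearsonPhi <- function(callsA, callsB) {
  ok <- callsA %in% c("Positive", "Negative") &
        callsB %in% c("Positive", "Negative")
  x <- as.numeric(callsA[ok] == "Positive")
  y <- as.numeric(callsB[ok] == "Positive")
  suppressWarnings(stats::cor(x, y))
}

# Tiny linear chain network used by several propagation tests.
chainNetwork <- function(strengths = c("High", "Medium", "High")) {
  n <- length(strengths) + 1L
  ids <- sprintf("e%d", seq_len(n))
  KeyEventNetwork(
    events = data.frame(
      id = ids, name = toupper(ids),
      level = rep_len(organizationLevels(), n),
      role = c("MIE", rep("KE", n - 2L), "AO"),
      group = NA_character_, stringsAsFactors = FALSE),
    kers = data.frame(upstream = ids[-n], downstream = ids[-1],
                      strength = strengths, stringsAsFactors = FALSE))
}

# Single-event network with one assay and one prediction basis, for testing
# the local evidence merges in isolation.
singleEventNetwork <- function(assayTier = "in_vitro",
                               assayReliability = "Large",
                               convincingness = "Medium") {
  KeyEventNetwork(
    events = data.frame(id = "ke", name = "KE", level = "cellular",
                        role = "KE", group = NA_character_),
    assays = data.frame(id = "a1", name = "Assay 1",
                        reliability = assayReliability, tier = assayTier),
    assayEventLinks = data.frame(assay = "a1", measurement = "overall_call",
                                 event = "ke",
                                 convincingness = convincingness),
    predictionBases = data.frame(model = "m", basis = "alert1",
                                 outcome_weight = "Medium",
                                 reliability = "Large"),
    predictionLinks = data.frame(model = "m", basis = "alert1",
                                 kind = "event", target = "ke",
                                 convincingness = "Small"))
}

wideCalls <- function(calls, assayA, assayB) {
  a <- calls[calls$assay == assayA, ]
  b <- calls[calls$assay == assayB, ]
  shared <- intersect(a$compound, b$compound)
  list(a = a$call[match(shared, a$compound)],
       b = b$call[match(shared, b$compound)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
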