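withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a random layered key event network
#'
#' Seeded generator of well-formed networks for property testing: events are
#' spread over `nLayers` layers, every edge points to a strictly later layer
#' (so the graph is acyclic by construction), every non-first-layer event is
#' guaranteed at least one incoming KER, first-layer events take the MIE
#' role, last-layer events the AO role, and KER strengths are sampled
#' uniformly over the five levels.
#'
#' @param seed Integer seed; the same seed reproduces the same network.
#' @param nEvents Number of events (>= 2).
#' @param nLayers Number of layers (>= 2, <= nEvents).
#' @param edgeDensity Probability of each admissible forward edge, in (0, 1].
#' @return A [KeyEventNetwork()] that passes [validateNetwork()].
#' @export
randomKEN <- function(seed, nEvents = 12L, nLayers = 4L, edgeDensity = 0.3) {
  if (nEvents < 2L || nLayers < 2L || nLayers > nEvents)
    stop("need nEvents >= 2 and 2 <= nLayers <= nEvents")
  if (edgeDensity <= 0 || edgeDensity > 1) stop("edgeDensity must be in (0, 1]")
  withSeed(seed, {
    layer <- sort(c(seq_len(nLayers),
                    sample(nLayers, nEvents - nLayers, replace = TRUE)))
    ids <- sprintf("ev%02d", seq_len(nEvents))
    role <- ifelse(layer == 1L, "MIE", ifelse(layer == nLayers, "AO", "KE"))
    lev <- organizationLevels()[pmin(layer, 6L)]
    edges <- list()
    for (i in seq_len(nEvents)) for (j in seq_len(nEvents)) {
      if (layer[j] > layer[i] && stats::runif(1) < edgeDensity)
        edges[[length(edges) + 1L]] <- c(ids[i], ids[j])
    }
    # guarantee connectivity: one incoming edge per non-source event
    haveIn <- vapply(edges, `[[`, character(1), 2)
    for (j in which(layer > 1L)) {
      if (!ids[j] %in% haveIn) {
        cand <- which(layer < layer[j])
        i <- cand[sample.int(length(cand), 1L)]
        edges[[length(edges) + 1L]] <- c(ids[i], ids[j])
      }
    }
    em <- do.call(rbind, edges)
    em <- em[!duplicated(paste(em[, 1], em[, 2])), , drop = FALSE]
    kersDf <- data.frame(
      upstream = em[, 1], downstream = em[, 2],
      strength = sample(strengthLevels(), nrow(em), replace = TRUE),
      stringsAsFactors = FALSE)
    KeyEventNetwork(
      events = data.frame(id = ids, name = toupper(ids), level = lev,
                          role = role, group = NA_character_,
                          stringsAsFactors = FALSE),
      kers = kersDf)
  })
}

#' Generate a call dataset with planted assay concordance
#'
#' Latent-threshold construction: per compound a multivariate normal latent
#' vector is drawn with correlation `rho = sin(pi * phi / 2)` for each
#' requested pairwise target phi (the inverse of the tetrachoric relation
#' `phi = (2/pi) asin(rho)` at zero thresholds), and each assay's call is
#' Positive where its latent exceeds zero. The empirical phi of the calls
#' then converges to the requested target as the number of compounds grows.
#'
#' @param seed Integer seed.
#' @param compounds Compound ids (or a single count).
#' @param assayIds Assay ids (columns).
#' @param targetPhi Either a single pairwise phi applied to all assay pairs,
#'   or a symmetric matrix of pairwise phis (unit diagonal), entries in
#'   [-1, 1].
#' @return data.frame with columns `compound`, `assay`, `call`.
#' @examples
#' head(randomCalls(1, 10, c("a", "b"), 0.8))
#' @export
randomCalls <- function(seed, compounds, assayIds, targetPhi = 0) {
  if (length(compounds) == 1L && is.numeric(compounds))
    compounds <- sprintf("cmp%04d", seq_len(compounds))
  k <- length(assayIds)
  if (is.matrix(targetPhi)) {
    if (!all(dim(targetPhi) == k)) stop("targetPhi matrix must be ", k, "x", k)
    phi <- targetPhi
  } else {
    phi <- matrix(targetPhi, k, k)
    diag(phi) <- 1
  }
  if (any(abs(phi) > 1)) stop("target phi values must lie in [-1, 1]")
  rho <- sin(pi * phi / 2)
  diag(rho) <- 1
  eig <- eigen(rho, symmetric = TRUE)
  if (min(eig$values) < -1e-8)
    stop("infeasible correlation matrix: not positive semidefinite")
  factor <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), k)
  n <- length(compounds)
  withSeed(seed, {
    z <- matrix(stats::rnorm(n * k), n, k) %*% t(factor)
    data.frame(
      compound = rep(compounds, times = k),
      assay = rep(assayIds, each = n),
      call = ifelse(as.vector(z) > 0, "Positive", "Negative"),
      stringsAsFactors = FALSE)
  })
}
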