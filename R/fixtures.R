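fixturePath <- function(...) {
  p <- system.file("extdata", "fixtures", ..., package = "aopnet")
  if (!nzchar(p)) stop("packaged fixture file not found: ", ...)
  p
}

#' Packaged example networks and worked scenarios
#'
#' Deterministic encodings of the worked examples used throughout the
#' documentation and tests:
#'
#' * `skin_sensitization` — the covalent-protein-binding AOP (1 MIE, 3
#'   intermediate KEs, 1 AO) with the seven sensitization assays (DPRA with
#'   cysteine/lysine/overall measurement links, KeratinoSens, LuSens,
#'   h-CLAT, U-SENS, LLNA with EC3/overall links, human observation) and a
#'   prediction basis for the AO. The keratinocyte-to-dendritic KER is
#'   Medium, the others High, encoding the thin arrow of the display.
#' * `reprotoxicity` — two MIEs converging on reproductive toxicity.
#' * `genotoxicity` — Ames linked to inherited DNA mutation, which leads to
#'   the genetic instability and cancer AOs.
#' * `rxr_carcinogenicity` — retinoid X receptor binding leading to
#'   carcinogenicity, with the three-member p38 MAPK signalling pathway
#'   dysregulation event group (`p38_mapk_group`).
#' * `oestrogen_ontology` — an [EventOntology()] of oestrogen-receptor terms
#'   (multi-parent is-a links) with the ToxCast assay groupings.
#' * `linalool_evidence` — list with the skin sensitization `network` and
#'   the `evidence` ([CompoundEvidence()]) for (+/-)-linalool: negative
#'   early-pathway assays, positive LLNA and human observation, one fired
#'   alert.
#' * `dihydroxyaniline_scenario` — list with the skin sensitization
#'   `network`, a synthetic set of `compounds` around 2,4-dihydroxyaniline
#'   (`query = "dha"`), and `calls`: a seeded, planted-concordance call
#'   dataset (stronger concordance within the in vitro / in chemico
#'   subgroup) in which the query compound has LuSens and KeratinoSens calls
#'   but none of the others.
#'
#' @param name Fixture name (see above).
#' @return A [KeyEventNetwork()], an [EventOntology()], or a list (see the
#'   per-fixture descriptions).
#' @examples
#' aopFixture("skin_sensitization")
#' @export
aopFixture <- function(name) {
  switch(name,
    skin_sensitization = loadKnowledge(fixturePath("skin_sensitization.yaml")),
    reprotoxicity = loadKnowledge(fixturePath("reprotoxicity.yaml")),
    genotoxicity = loadKnowledge(fixturePath("genotoxicity.yaml")),
    rxr_carcinogenicity = loadKnowledge(fixturePath("rxr_carcinogenicity.yaml")),
    oestrogen_ontology = loadOntology(fixturePath("oestrogen_terms.tsv"),
                                      fixturePath("oestrogen_mapping.tsv")),
    linalool_evidence = {
      calls <- readCalls(fixturePath("linalool_calls.csv"))
      preds <- utils::read.csv(fixturePath("linalool_predictions.csv"),
                               stringsAsFactors = FALSE)
      list(network = aopFixture("skin_sensitization"),
           evidence = CompoundEvidence(
             "linalool",
             calls = calls[, c("assay", "measurement", "call")],
             predictions = preds),
           smiles = "CC(C)=CCCC(C)(O)C=C")
    },
    dihydroxyaniline_scenario = {
      net <- aopFixture("skin_sensitization")
      compounds <- readSmiles(fixturePath("dihydroxyaniline_compounds.smi"))
      assayIds <- sort(assays(net)$id)
      # planted structure: tight concordance among the non-animal assays,
      # moderate with the in vivo/human calls
      k <- length(assayIds)
      phi <- matrix(0.4, k, k, dimnames = list(assayIds, assayIds))
      nonAnimal <- c("dpra", "keratinosens", "lusens", "hclat", "usens")
      phi[nonAnimal, nonAnimal] <- 0.8
      diag(phi) <- 1
      calls <- randomCalls(20210122, compounds$id, assayIds, phi)
      keep <- !(calls$compound == "dha" &
                  !calls$assay %in% c("lusens", "keratinosens"))
      list(network = net, compounds = compounds,
           calls = calls[keep, , drop = FALSE], query = "dha")
    },
    stop("unknown fixture: ", name))
}

#' @rdname aopFixture
#' @export
fixtureNames <- function() {
  c("skin_sensitization", "reprotoxicity", "genotoxicity",
    "rxr_carcinogenicity", "oestrogen_ontology", "linalool_evidence",
    "dihydroxyaniline_scenario")
}
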