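test_that("linalool evidence colours early events green and late events red", {
  fx <- aopFixture("linalool_evidence")
  res <- propagate(fx$network, fx$evidence, "conservative")
  st <- propagationStates(res)
  state <- setNames(st$state, st$event)
  expect_equal(state[["covalent_protein_binding"]], "NoConcern")
  expect_equal(state[["keratinocyte_activation"]], "NoConcern")
  expect_equal(state[["tcell_activation"]], "Concern")
  expect_equal(state[["skin_sensitization"]], "Concern")
  # no local data and no upstream concern: the dendritic event stays grey
  expect_equal(state[["dendritic_cell_activation"]], "Unknown")
  prov <- propagationProvenance(res)
  expect_true(any(grepl("llna", prov[["tcell_activation"]])))
})

test_that("a positive Ames call cascades to both downstream adverse outcomes", {
  net <- aopFixture("genotoxicity")
  ev <- CompoundEvidence("imine", calls = data.frame(
    assay = "ames", measurement = "overall_call", call = "Positive"))
  st <- propagationStates(propagate(net, ev, "conservative"))
  state <- setNames(st$state, st$event)
  expect_equal(state[["inherited_dna_mutation"]], "Concern")
  expect_equal(state[["genetic_instability"]], "Concern")
  expect_equal(state[["cancer"]], "Concern")
  expect_equal(state[["dna_adduct_formation"]], "Unknown")  # no back-flow
})

test_that("empty evidence leaves every event unknown or balanced", {
  net <- aopFixture("skin_sensitization")
  none <- CompoundEvidence("cmp")
  expect_true(all(propagationStates(
    propagate(net, none, "conservative"))$state == "Unknown"))
  calc <- propagationStates(propagate(net, none, "calculus"))
  expect_true(all(calc$direction == "None"))
})

test_that("an assay result overrules a conflicting prediction in the tiered paradigm", {
  net <- singleEventNetwork(assayTier = "in_vitro")
  ev <- CompoundEvidence(
    "cmp",
    calls = data.frame(assay = "a1", measurement = "overall_call",
                       call = "Negative"),
    predictions = data.frame(model = "m", basis = "alert1",
                             outcome = "fired"))
  tiered <- propagationStates(propagate(net, ev, "tiered"))
  expect_equal(tiered$state, "NoConcern")
  # the conservative paradigm would have called the same inputs a concern
  cons <- propagationStates(propagate(net, ev, "conservative"))
  expect_equal(cons$state, "Concern")
})

test_that("conservative propagation is monotone in added concern inputs", {
  net <- aopFixture("skin_sensitization")
  base <- CompoundEvidence("cmp", calls = data.frame(
    assay = c("dpra", "llna"), measurement = "overall_call",
    call = c("Negative", "Positive")))
  more <- CompoundEvidence("cmp", calls = data.frame(
    assay = c("dpra", "llna", "keratinosens"), measurement = "overall_call",
    call = c("Negative", "Positive", "Positive")))
  s1 <- propagationStates(propagate(net, base, "conservative"))
  s2 <- propagationStates(propagate(net, more, "conservative"))
  for (i in seq_len(nrow(s1))) {
    if (s1$state[i] == "Concern")
      expect_equal(s2$state[i], "Concern", label = s1$event[i])
  }
})

test_that("concern at an event implies concern at every downstream adverse outcome", {
  for (seed in c(3, 14)) {
    net <- randomKEN(seed, nEvents = 12L, nLayers = 4L, edgeDensity = 0.3)
    src <- events(net)$id[1]
    net2 <- KeyEventNetwork(
      events = events(net), kers = kers(net),
      assays = data.frame(id = "probe", name = "Probe",
                          reliability = "Large", tier = "in_vitro"),
      assayEventLinks = data.frame(assay = "probe",
                                   measurement = "overall_call",
                                   event = src, convincingness = "Large"))
    ev <- CompoundEvidence("c", calls = data.frame(
      assay = "probe", measurement = "overall_call", call = "Positive"))
    st <- propagationStates(propagate(net2, ev, "conservative"))
    state <- setNames(st$state, st$event)
    aos <- intersect(downstreamClosure(net2, src),
                     events(net2)$id[events(net2)$role == "AO"])
    for (ao in aos) expect_equal(state[[ao]], "Concern", label = ao)
  }
})

test_that("calculus propagation along a chain equals folded transmission", {
  strengths <- c("High", "Low", "VeryHigh")
  net0 <- chainNetwork(strengths)
  net <- KeyEventNetwork(
    events = events(net0), kers = kers(net0),
    assays = data.frame(id = "a", name = "A", reliability = "Large",
                        tier = "in_vitro"),
    assayEventLinks = data.frame(assay = "a", measurement = "overall_call",
                                 event = "e1", convincingness = "Large"))
  ev <- CompoundEvidence("c", calls = data.frame(
    assay = "a", measurement = "overall_call", call = "Positive"))
  st <- propagationStates(propagate(net, ev, "calculus"))
  mag <- setNames(st$magnitude, st$event)
  expected <- strengthOf("Large", "Large")  # the source argument
  expect_equal(mag[["e1"]], expected)
  for (i in seq_along(strengths)) {
    expected <- transmitStrength(expected, strengths[i])
    expect_equal(mag[[sprintf("e%d", i + 1L)]], expected)
    expect_equal(st$direction[st$event == sprintf("e%d", i + 1L)], "For")
  }
})

test_that("propagation does not depend on event-table order", {
  fx <- aopFixture("linalool_evidence")
  net <- fx$network
  perm <- c(5, 3, 1, 4, 2)
  shuffled <- KeyEventNetwork(
    events = events(net)[perm, ], kers = kers(net),
    assays = assays(net), assayEventLinks = assayEventLinks(net),
    predictionBases = predictionBases(net),
    predictionLinks = predictionLinks(net))
  for (paradigm in c("conservative", "tiered", "calculus")) {
    a <- propagationStates(propagate(net, fx$evidence, paradigm))
    b <- propagationStates(propagate(shuffled, fx$evidence, paradigm))
    expect_identical(a[order(a$event), , drop = FALSE] |> `rownames<-`(NULL),
                     b[order(b$event), , drop = FALSE] |> `rownames<-`(NULL),
                     label = paradigm)
  }
})

test_that("dangling evidence references are refused", {
  net <- aopFixture("skin_sensitization")
  expect_error(propagate(net, CompoundEvidence("c", calls = data.frame(
    assay = "ghost", measurement = "overall_call", call = "Positive"))),
    "unknown assay")
  expect_error(propagate(net, CompoundEvidence("c", calls = data.frame(
    assay = "dpra", measurement = "ghost_measure", call = "Positive"))),
    "undeclared measurement")
  expect_error(propagate(net, CompoundEvidence("c", predictions = data.frame(
    model = "m", basis = "ghost", outcome = "fired"))),
    "unknown prediction")
})

test_that("alerted adverse outcomes follow the downstream closure of the call", {
  net <- aopFixture("genotoxicity")
  hits <- alertedAOs(net, "ames", "Positive")
  expect_setequal(hits$ao, c("genetic_instability", "cancer"))
  expect_true(all(grepl("^inherited_dna_mutation", hits$path)))
  # negative calls alert nothing: hazard-only semantics
  expect_equal(nrow(alertedAOs(net, "ames", "Negative")), 0L)
  # a call directly on a terminal AO alerts that AO
  direct <- alertedAOs(net, "cancer", "Positive")
  expect_equal(direct$ao, "cancer")
  expect_equal(direct$path, "cancer")
  expect_error(alertedAOs(net, "ghost", "Positive"), "unknown")
})
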