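test_that("call vocabulary normalizes case-insensitively and rejects the rest", {
  out <- normalizeCall(c("active", "Positive", "POS", "+",
                         "Negative", "inactive", "neg", "-",
                         "Conflicted", "equivocal-conflict",
                         "maybe", "3.2"))
  expect_equal(out$call[1:4], rep("Positive", 4))
  expect_equal(out$call[5:8], rep("Negative", 4))
  expect_equal(out$call[9:10], rep("Conflicted", 2))
  expect_true(all(is.na(out$call[11:12])))
  expect_equal(out$raw[!out$accepted], c("maybe", "3.2"))
})

test_that("overall call collapses repeats and conflicts per the curation scheme", {
  expect_equal(overallCall(c("Positive", "Negative")), "Conflicted")
  expect_equal(overallCall(c("Positive", "Positive")), "Positive")
  expect_equal(overallCall(c("Negative", "Negative")), "Negative")
  expect_equal(overallCall("Conflicted"), "Conflicted")
  expect_equal(overallCall(c("Positive", "Conflicted")), "Conflicted")
  # idempotent
  for (calls in list(c("Positive", "Negative"), c("Positive", "Positive"),
                     "Conflicted")) {
    once <- overallCall(calls)
    expect_equal(overallCall(once), once)
  }
  expect_error(overallCall(character(0)), "no results")
  expect_error(overallCall("active"), "unnormalized")
})

test_that("grouping canonicalizes assay variables before aggregating", {
  records <- data.frame(
    compound = "c1", assay = "ames", measurement = "overall_call",
    variables = c("s9=Rat S9", "s9=S9 Rat", "s9=Hamster S9"),
    call = c("positive", "negative", "positive"))
  out <- groupResults(records)$calls
  expect_equal(nrow(out), 2L)  # the two rat spellings share one key
  ratRow <- out[grepl("rat", out$variables), ]
  expect_equal(ratRow$call, "Conflicted")
  expect_equal(ratRow$n_results, 2L)
  expect_equal(out$call[grepl("hamster", out$variables)], "Positive")
})

test_that("records differing in a variable keep separate overall calls", {
  records <- data.frame(
    compound = "c1", assay = "a", measurement = "overall_call",
    variables = c("exposure=24h", "exposure=48h"),
    call = c("positive", "negative"))
  out <- groupResults(records)$calls
  expect_equal(nrow(out), 2L)
  expect_setequal(out$call, c("Positive", "Negative"))
  single <- groupResults(data.frame(
    compound = "c2", assay = "a", measurement = "overall_call",
    variables = "", call = "active"))$calls
  expect_equal(single$call, "Positive")
})

test_that("grouping is invariant under record order and reports rejections", {
  records <- data.frame(
    compound = rep(c("c1", "c2"), each = 3),
    assay = "a", measurement = "overall_call", variables = "",
    call = c("positive", "negative", "junk", "active", "pos", "positive"))
  a <- groupResults(records)
  b <- groupResults(records[sample(6), , drop = FALSE])
  expect_equal(a$calls, b$calls)
  expect_equal(nrow(a$rejected), 1L)
  expect_equal(a$rejected$call, "junk")
  expect_equal(a$calls$call[a$calls$compound == "c2"], "Positive")
})

test_that("knowledge files round-trip through YAML and JSON", {
  net <- aopFixture("skin_sensitization")
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    saveKnowledge(net, f)
    back <- loadKnowledge(f)
    expect_identical(events(back), events(net), label = ext)
    expect_identical(kers(back), kers(net), label = ext)
    expect_identical(assays(back), assays(net), label = ext)
    expect_identical(assayEventLinks(back), assayEventLinks(net), label = ext)
    expect_identical(predictionBases(back), predictionBases(net), label = ext)
    expect_identical(predictionLinks(back), predictionLinks(net), label = ext)
  }
  grp <- aopFixture("rxr_carcinogenicity")
  f <- tempfile(fileext = ".yaml")
  saveKnowledge(grp, f)
  expect_identical(eventGroups(loadKnowledge(f)), eventGroups(grp))
})

test_that("malformed knowledge files fail with located schema errors", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("events:",
               "- id: a", "  name: A", "  level: molecular", "  role: MIE",
               "- id: b", "  name: B", "  level: molecular",
               "kers:",
               "- upstream: a", "  downstream: ghost", "  strength: High"), f)
  expect_error(loadKnowledge(f), "events\\[2\\]")
  f2 <- tempfile(fileext = ".yaml")
  writeLines(c("events:",
               "- {id: a, name: A, level: molecular, role: MIE}",
               "kers:",
               "- {upstream: a, downstream: ghost, strength: High}"), f2)
  expect_error(loadKnowledge(f2), "dangling-ker")
  f3 <- tempfile(fileext = ".yaml")
  writeLines(c("events:",
               "- {id: a, name: A, level: cosmic, role: MIE}"), f3)
  expect_error(loadKnowledge(f3), "unknown-organization-level")
  expect_error(loadKnowledge(tempfile()), "not found")
})

test_that("call CSVs read in the documented dialect", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("compound_id,assay_id,measurement_id,variables,call,source",
               "c1,ames,overall_call,s9=rat s9,positive,vitic",
               "c1,ames,overall_call,,negative,kirkland"), f)
  df <- readCalls(f)
  expect_named(df, c("compound", "assay", "measurement", "variables",
                     "call", "source"))
  expect_equal(nrow(df), 2L)
  expect_error(readCalls({
    g <- tempfile(); writeLines("a,b\n1,2", g); g
  }), "compound_id")
})

test_that("graph export is deterministic and structurally faithful", {
  net <- aopFixture("skin_sensitization")
  f1 <- tempfile(fileext = ".dot"); f2 <- tempfile(fileext = ".dot")
  exportGraph(net, f1, "dot")
  exportGraph(net, f2, "dot")
  expect_identical(readLines(f1), readLines(f2))
  dot <- readLines(f1)
  expect_length(grep("^  \"[a-z_]+\" \\[", dot), 5)       # 5 event nodes
  expect_length(grep("->", dot, fixed = TRUE), 4)          # 4 KER edges
  # the weaker keratinocyte->dendritic KER gets a thinner pen
  thin <- grep("keratinocyte_activation\" -> \"dendritic", dot, value = TRUE)
  expect_true(grepl("penwidth=3", thin))
})

test_that("propagation states colour the exported graph", {
  fx <- aopFixture("linalool_evidence")
  res <- propagate(fx$network, fx$evidence, "conservative")
  f <- tempfile(fileext = ".dot")
  exportGraph(fx$network, f, "dot", states = res)
  dot <- readLines(f)
  mie <- grep("^  \"covalent_protein_binding\" \\[", dot, value = TRUE)
  ao <- grep("^  \"skin_sensitization\" \\[", dot, value = TRUE)
  grey <- grep("^  \"dendritic_cell_activation\" \\[", dot, value = TRUE)
  expect_true(grepl("green", mie))
  expect_true(grepl("red", ao))
  expect_true(grepl("grey", grey))
  g <- tempfile(fileext = ".graphml")
  exportGraph(fx$network, g, "graphml", states = res)
  xml <- xml2::read_xml(g)  # well-formed XML
  expect_equal(length(xml2::xml_find_all(xml, ".//d1:node",
    c(d1 = "http://graphml.graphdrawing.org/xmlns"))), 5L)
})

test_that("layer assignment follows the longest path from the sources", {
  net <- aopFixture("genotoxicity")
  f <- tempfile(fileext = ".dot")
  exportGraph(net, f, "dot")
  dot <- readLines(f)
  layerOf <- function(id) {
    line <- grep(paste0("^  \"", id, "\" \\["), dot, value = TRUE)
    as.integer(sub(".*layer=(\\d+).*", "\\1", line))
  }
  expect_equal(layerOf("dna_adduct_formation"), 0L)
  expect_equal(layerOf("inherited_dna_mutation"), 1L)
  expect_equal(layerOf("cancer"), 2L)
})
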