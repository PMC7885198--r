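test_that("strength weighting follows the reference 3x3 table", {
  expect_equal(strengthOf("Large", "Large"), "VeryHigh")
  expect_equal(strengthOf("Medium", "Large"), "High")
  expect_equal(strengthOf("Small", "Large"), "Medium")
  expect_equal(strengthOf("Small", "Medium"), "Low")
  expect_equal(strengthOf("Small", "Small"), "VeryLow")
  expect_equal(strengthOf("Medium", "Medium"), "Medium")
  # symmetric in convincingness and reliability, cell by cell
  for (g1 in grades()) for (g2 in grades())
    expect_equal(strengthOf(g1, g2), strengthOf(g2, g1))
})

test_that("pairwise combination is commutative, monotone and capped", {
  lev <- strengthLevels()
  idx <- function(x) match(x, lev)
  for (a in lev) for (b in lev) {
    r <- combinePair(a, b)
    expect_equal(r, combinePair(b, a))
    expect_gte(idx(r), max(idx(a), idx(b)))  # never weakens the stronger arm
  }
  # weak arguments cannot enhance much stronger ones
  expect_equal(combinePair("Medium", "VeryLow"), "Medium")
  expect_equal(combinePair("High", "VeryLow"), "High")
  expect_equal(combinePair("VeryHigh", "VeryLow"), "VeryHigh")
  expect_equal(combinePair("High", "Low"), "High")
  expect_equal(combinePair("VeryHigh", "Low"), "VeryHigh")
  # VeryHigh is absorbing
  for (a in lev) expect_equal(combinePair("VeryHigh", a), "VeryHigh")
})

test_that("pairwise combination is not associative, so sorted folding is normative", {
  left <- combinePair(combinePair("VeryLow", "VeryLow"), "Medium")   # (VL+VL)+M
  right <- combinePair("VeryLow", combinePair("VeryLow", "Medium"))  # VL+(VL+M)
  expect_equal(left, "High")
  expect_equal(right, "Medium")
  expect_false(left == right)
  # the sorted fold picks the ascending bracketing
  expect_equal(combineSorted(c("Medium", "VeryLow", "VeryLow")), "High")
})

test_that("sorted combination reproduces the worked build-up of weak arguments", {
  expect_equal(combinePair("VeryLow", "VeryLow"), "Low")
  expect_equal(combinePair("Low", "VeryLow"), "Medium")
  expect_equal(combinePair("Medium", "VeryLow"), "Medium")
  expect_equal(combineSorted(rep("VeryLow", 4)), "Medium")
  for (x in strengthLevels()) expect_equal(combineSorted(x), x)
  expect_error(combineSorted(character(0)), "empty")
})

test_that("opposition table balances equals and is antisymmetric under side swap", {
  lev <- strengthLevels()
  for (x in lev) expect_true(isBalanced(oppose(x, x)))
  flip <- c(For = "Against", Against = "For", None = "None")
  for (a in lev) for (f in lev) {
    r1 <- oppose(a, f)
    r2 <- oppose(f, a)
    expect_equal(r1@magnitude, r2@magnitude)
    expect_equal(r1@direction, unname(flip[r2@direction]))
  }
  expect_equal(oppose("High", "Medium"), SignedStrength("Medium", "Against"))
  expect_equal(oppose("VeryLow", "Medium"), SignedStrength("Low", "For"))
})

test_that("resolution cancels equal opposed strengths then combines the rest", {
  # the worked balance: -M and +M cancel, one +L survives
  eq5 <- resolveArguments(data.frame(
    direction = c("Against", "For", "For"),
    strength = c("Medium", "Medium", "Low")))
  expect_equal(eq5, SignedStrength("Low", "For"))
  expect_equal(resolveArguments(data.frame(direction = character(0),
                                           strength = character(0))),
               balanced())
  expect_equal(resolveArguments(NULL), balanced())
  # one VL pair cancels; a single For/VeryLow survives
  expect_equal(resolveArguments(data.frame(
    direction = c("For", "For", "Against"),
    strength = rep("VeryLow", 3))), SignedStrength("VeryLow", "For"))
  # a single argument resolves to itself, via the grade weighting
  one <- resolveArguments(data.frame(direction = "Against",
                                     convincingness = "Large",
                                     reliability = "Small"))
  expect_equal(one, SignedStrength("Medium", "Against"))
})

test_that("resolution is invariant under permutation of the argument list", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(1:6, 1)
    args <- data.frame(
      direction = sample(c("For", "Against"), n, replace = TRUE),
      convincingness = sample(grades(), n, replace = TRUE),
      reliability = sample(grades(), n, replace = TRUE))
    ref <- resolveArguments(args)
    perm <- args[sample(n), , drop = FALSE]
    expect_equal(resolveArguments(perm), ref)
  }
})

test_that("transmission along a KER is the lattice meet", {
  expect_equal(transmitStrength("Medium", "Low"), "Low")
  expect_equal(transmitStrength("High", "VeryHigh"), "High")
  lev <- strengthLevels()
  idx <- function(x) match(x, lev)
  for (a in lev) for (k in lev) {
    r <- transmitStrength(a, k)
    expect_equal(r, transmitStrength(k, a))            # commutative
    expect_equal(idx(r), min(idx(a), idx(k)))          # meet
  }
  for (a in lev) expect_equal(transmitStrength(a, a), a)  # idempotent
})

test_that("the strength scale and the signed carrier have the stated sizes", {
  expect_length(strengthLevels(), 5)
  carrier <- signedStrengthCarrier()
  expect_length(carrier, 11)
  keys <- vapply(carrier, function(s) paste(s@direction, s@magnitude),
                 character(1))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("conservative merge lets any cause for concern win", {
  expect_equal(conservativeMerge(c("Concern", "NoConcern")), "Concern")
  expect_equal(conservativeMerge(c("NoConcern", "NoConcern")), "NoConcern")
  expect_equal(conservativeMerge(c("Unknown", "NoConcern")), "NoConcern")
  expect_equal(conservativeMerge(character(0)), "Unknown")
  expect_error(conservativeMerge("Maybe"), "unknown")
})

test_that("tiered merge lets measured results overrule predictions", {
  expect_equal(tieredMerge(c("in_vitro", "in_silico"),
                           c("NoConcern", "Concern")), "NoConcern")
  expect_equal(tieredMerge(c("in_vivo", "in_vitro"),
                           c("NoConcern", "Concern")), "NoConcern")
  expect_equal(tieredMerge("in_silico", "Concern"), "Concern")
  # ties within a tier merge conservatively
  expect_equal(tieredMerge(c("in_vitro", "in_chemico"),
                           c("NoConcern", "Concern")), "Concern")
  # uninformative top tiers do not blank out lower informative ones
  expect_equal(tieredMerge(c("in_vivo", "in_silico"),
                           c("Unknown", "Concern")), "Concern")
  # precedence is configurable
  invert <- c(in_silico = 5L, in_chemico = 2L, in_vitro = 2L, in_vivo = 1L,
              human_observation = 0L)
  expect_equal(tieredMerge(c("in_vitro", "in_silico"),
                           c("NoConcern", "Concern"), invert), "Concern")
})

test_that("weighted scoring averages by weight and thresholds the call", {
  r <- weightedScore(c(75, 23, 2), c(-1, 1, 1))
  expect_equal(r$score, -0.5)
  expect_equal(r$state, "NoConcern")
  expect_equal(weightedScore(c(1, 1), c(1, -1))$state, "Unknown")
  expect_equal(weightedScore(c(5, 2), c(1, 1)),
               list(score = 1, state = "Concern"))
  expect_error(weightedScore(c(0, 0), c(1, 1)), "zero")
  # a re-weighting of the same three arguments can flip the overall call
  flip <- weightedScore(c(50, 40, 10), c(-1, 1, 1))
  expect_equal(flip$state, "Unknown")
  expect_false(identical(r$state, "Concern"))
})

test_that("a calculus-table override loads and is used by the lookups", {
  path <- system.file("extdata", "calculus_tables.json", package = "aopnet")
  tabs <- loadCalculusTables(path)
  expect_equal(tabs$combination["VeryLow", "VeryLow"], "Low")
  expect_equal(strengthOf("Large", "Large", tabs), "VeryHigh")
  # a doctored table changes the answer, proving the tables are not baked in
  tweaked <- tabs
  tweaked$combination["VeryLow", "VeryLow"] <- "VeryHigh"
  expect_equal(combinePair("VeryLow", "VeryLow", tweaked), "VeryHigh")
})
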