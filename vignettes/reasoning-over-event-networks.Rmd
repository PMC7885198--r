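---
title: "Reasoning over key event networks: model and methods"
author: "aopnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reasoning over key event networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aopnet)
```

## The data model

An adverse outcome pathway (AOP) describes a causal chain from a molecular
initiating event (MIE) through measurable key events (KEs) to an adverse
outcome (AO), with each key event relationship (KER) carrying an innate
weight of evidence. Because real key events are shared between pathways,
`aopnet` works on *key event networks*: directed acyclic graphs whose nodes
are events at one of six organization levels (molecular, cellular, tissue,
organ, individual, population) and whose edges are KERs graded on a
five-level strength scale (VeryLow–VeryHigh).

The network is augmented with two kinds of chemistry-facing knowledge:

* **Assays** — each with an expert-assigned reliability grade
  (Small/Medium/Large) and an evidence tier (in silico, in chemico, in
  vitro, in vivo, human observation). An assay reaches an event through one
  or more *measurement links* (e.g. the peptide reactivity assay contributes
  cysteine depletion, lysine depletion and an overall call to the protein
  binding MIE), each with its own convincingness grade.
* **Prediction bases** — structure–activity alerts. Their semantics are
  deliberately asymmetric: a fired alert is a concerning prediction, but an
  *absent* alert is not a negative prediction. Only models that emit
  explicit negative predictions contribute no-concern arguments, and those
  enter weakly (convincingness Small). Each basis carries an
  `outcome_weight` capping the strength of the prediction–event
  relationship.

Acyclicity, reference integrity and vocabulary membership are enforced when
a knowledge file is loaded (`loadKnowledge()`, `validateNetwork()`), because
the propagation semantics below assume a DAG. Event groups allow related
sub-events to be collapsed to a single node for display; collapsing re-homes
boundary edges to the group node and keeps the strongest strength when
parallel edges merge (a conservative display choice, consistent with the
conservative reasoning paradigm), and is exactly invertible because the
underlying network is retained in the view.

## The argument calculus

Quantitative belief propagation is intentionally avoided: the judgements
being combined (how convincing is a line of argument, how reproducible is
its evidence) do not support continuous precision. Every quantity in the
calculus therefore lives on a small ordered scale, and all combination rules
are exact lookups of three tables that ship as JSON
(`system.file("extdata", "calculus_tables.json", package = "aopnet")`), so
an alternative calculus can be loaded without touching code.

1. **Weighting** (`strengthOf`): a 3×3 table turns an argument's
   convincingness and its evidence reliability into one of five strengths.
   The table is symmetric in its two grades.
2. **Same-direction combination** (`combinePair`, `combineSorted`): a 5×5
   table. Weak arguments reinforce each other (two VeryLow make a Low), but
   only so far: VeryLow arguments do not enhance Medium or stronger ones,
   and Low arguments do not enhance High or stronger ones. The table is
   commutative and never returns less than its stronger input, but it is
   *not associative* — `(VL+VL)+M` gives High while `VL+(VL+M)` gives
   Medium — so the multi-argument rule is normative: sort ascending, then
   fold pairwise. The tests assert this witness explicitly.
3. **Opposition** (`oppose`): a signed 5×5 table resolving the aggregate
   strength against a conclusion with the aggregate strength for it. Equal
   strengths balance exactly, and no argument level is irrefutable. The
   table is applied literally; it is not monotone in the obvious sense
   (e.g. −VeryHigh against High yields −High, but against Medium yields
   −VeryHigh), and no smoothing is applied.

`resolveArguments()` composes these: derive each argument's strength, cancel
equal-strength opposed pairs, fold each surviving side with the sorted
combination, and oppose the two aggregates. Cancellation pairs equal
magnitudes greedily; since equal-magnitude arguments are interchangeable the
result is order-independent (asserted by permutation tests). The carrier of
conclusions has exactly eleven positions: five deflections in each
direction plus perfect balance.

Transmission along a KER (`transmitStrength`) takes the lower of the
argument and the connection — the lattice meet on the five-level order — so
a strong argument travelling over a weak relationship arrives weak.

## Propagation paradigms

`propagate()` processes events in topological order and merges, at each
event, the local evidence with the transmitted upstream contributions:

* **conservative** — any cause for concern wins. Only Concern travels
  downstream: a negative assay result is a statement about that assay, not
  proof that the pathway is blocked, so NoConcern and Unknown create no
  downstream state. This makes conservative propagation monotone (adding a
  concern input can never clear a downstream event) and guarantees that a
  concern at an event implies concern at every AO in its downstream
  closure.
* **tiered** — assay results overrule predictions: local evidence is first
  restricted to its highest informative tier (human observation > in vivo >
  in vitro = in chemico > in silico, configurable because the proper rank
  of poorly reproducible human data is genuinely debatable) and merged
  conservatively within it; a Concern inherited from upstream then joins
  conservatively. The tier override is defined among local evidence only —
  the source material specifies the override for co-located assay and
  prediction results, and we chose not to let an in-silico-derived upstream
  concern be silently discarded by a local assay.
* **calculus** — the full signed calculus. Upstream contributions are first
  resolved into a single "likelihood of preceding events" argument
  (mirroring the three-line balance display: local assay data, preceding
  events, predictions), each transmitted through its KER, then pooled with
  the local arguments in `resolveArguments()`. On a linear chain with a
  single source argument this reduces to folding `transmitStrength` along
  the chain, which the tests check in closed form.

Conflicted calls map to Concern under the categorical paradigms and enter
the calculus as a For/VeryLow argument — a package decision (disagreeing
repeat results are a weak reason for concern, not for reassurance), since
the source material does not state how conflicted calls colour the display.
Measurement-level calls feed an event only through the assay's overall call
when one exists; otherwise their conservative merge stands in.

`weightedScore()` implements the simpler single-dimension weighting (pie
chart metaphor): expert weights times scores in [−1, +1], normalized. The
±0.15 call threshold is a package choice, set so that plausible
re-weightings of a three-argument conflict (e.g. 75:23:2 versus 50:40:10
with one dissenting heavyweight argument) can flip the overall call; it is
a tunable parameter, not part of the published scheme.

## Compound-level use cases

**Similar-compound profiling.** Similarity is measure-dependent, and that
is the point of making the fingerprint pluggable. The default scheme hashes
all linear atom/bond paths of 1–7 atoms of the hydrogen-suppressed
molecular graph (aromaticity-aware: atoms in perceived aromatic rings are
lower-cased and ring bonds marked aromatic; structures are canonicalized
first so the fingerprint does not depend on the SMILES spelling); the
alert-based scheme uses the set of fired alerts; arbitrary external
features can be injected. Path length 7 matches common path-fingerprint
practice — long enough to separate local chemotypes, short enough that bit
collisions stay rare on small feature sets. Neighborhoods are Tanimoto
thresholded; no cutoff is presented as canonical, and correcting for the
"lumpiness" of tested chemical space is explicitly out of scope. Activity
profiles count Positive and Negative overall calls only, with proportions
over informative calls, so differently sized neighbor sets compare
directly.

**Alerted outcomes.** A positive call on an assay alerts every AO in the
downstream closure of the events the assay links to, each reported with one
shortest supporting path. Negative calls alert nothing — the query is
hazard-level and one-sided.

**Next-assay suggestion.** Candidates are the unmeasured assays on
pathways into the target event. Each is scored by |phi| against the assays
linked to the target, over the compound's similarity neighborhood,
conditioned on the compound's own calls while the conditioned subset keeps
at least `minN` compounds (filters applied in assay-id order for
determinism). Phi (the 2×2 Matthews/Pearson-on-0/1 coefficient) was chosen
because the underlying calls are binary; the equivalence to Pearson on 0/1
coding is asserted against `stats::cor` as an oracle. Cells with a zero
margin or fewer than `minN` informative pairs are masked rather than set to
0 — a zero would fabricate evidence of independence. The default
`minN = 5` encodes "too few points to correlate" and is configurable.
Fully masked candidates fall back to pathway proximity (fewest KER hops).

## Curation rules

Raw result calls are normalized case-insensitively through a fixed synonym
table (positive/active/pos/+ → Positive, etc.); anything unmapped is
rejected and reported, which is the only operational form of the source
exclusion rule for unclear results. Repeated results under one assay
definition aggregate to an overall call: any disagreement yields
Conflicted. Assay-definition keys canonicalize variable values by
case-folding and token-sorting ("Rat S9" ≡ "S9 Rat"); records differing in
a variable (e.g. exposure time) keep separate calls. Structure
standardization (valency checks, tautomer canonicalization) is out of
scope; SMILES are accepted as given.

## Synthetic generators and what the tests show

`randomKEN()` generates layered DAGs (acyclic by construction, every
non-source event reachable) for property tests — closure oracles, paradigm
monotonicity, generator validity over 100 seeds. `randomCalls()` plants
pairwise concordance by a latent-threshold construction; note the latent
correlation is `sin(pi*phi/2)`, the inverse of the tetrachoric relation, so
the *empirical phi* converges to the target (the tests check ±0.1 at
n = 2000 for targets −0.8, 0, 0.8). The packaged compound scenario uses 24
small aromatic amines/phenols around 2,4-dihydroxyaniline with planted
concordance (0.8 within the non-animal assays, 0.4 elsewhere) at a fixed
seed.

These generators emulate call datasets with controllable dependence
structure; they do not emulate real chemical-biological coupling (calls are
independent of the structures), assay applicability domains, missingness
patterns, or dose dependence. Passing tests therefore demonstrate the
correctness of the machinery — not predictive performance on real data.
The published neighbor counts and the phi = 0.84 / N = 26 heat-map cell of
the original skin-sensitization analysis depend on an external curated
dataset and a proprietary fingerprint and are not reproduced here; the
property suites cover the same machinery instead.

Problem sizes used by the test-suite and the acceptance script — 2000
compounds for concordance recovery, 100 seeds for generator validity, 500
random tables for the phi oracle — were chosen as the smallest sizes at
which the stochastic assertions are stable, and run in seconds.

## Numerical and design notes

* All categorical scales are closed vocabularies validated at load; unknown
  organization levels or grades are violations, not warnings.
* Ties everywhere break deterministically by id (neighbor ranking, layer
  assignment in exports, candidate ordering), so identical inputs give
  byte-identical outputs.
* The events of a fixture encode one editorial choice worth noting: the
  skin-sensitization pathway is kept as a linear four-KER chain with the
  keratinocyte→dendritic link graded Medium (the thin arrow of the
  published display); the evidence tables of the source also mention a
  direct binding→dendritic relationship, which this fixture omits in favour
  of the linear display structure.
* A key event may belong to at most one direct group (groups may nest);
  overlapping selections are the ontology layer's job, where multi-parent
  is-a terms are explicitly supported.
* The ontology input is a minimal parent–child TSV plus a mapping TSV; OBO
  import is an extension point, deliberately not implemented.

## Known limitations

Undercutting ("gotcha") arguments — reasons to disbelieve an argument
wholesale — are not modelled. Hazard only: no dose–response, exposure or
risk. Human-relevance discounting of pathways is carried as provenance
text, not computed. The opposition table's non-monotonicity is inherited
from the published scheme and surfaced, not repaired.
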