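# aopnet

Key event networks with qualitative weight-of-evidence reasoning for
toxicity hazard assessment.

Adverse outcome pathways (AOPs) chain a molecular initiating event (MIE)
through measurable key events (KEs) to an adverse outcome (AO), each key
event relationship (KER) graded by its weight of evidence. `aopnet` merges
such pathways into validated key event networks, attaches assay knowledge
(reliability, evidence tier, measurement links to events) and
structure–activity prediction bases (alerts), and then reasons about
individual compounds:

* **Categorical argument calculus** — an argument's *convincingness* and
  its evidence *reliability* (each Small/Medium/Large) combine by table
  lookup into one of five strengths (VeryLow–VeryHigh); same-direction
  strengths combine through a 5×5 table (sorted ascending, folded
  pairwise — the table is deliberately not associative); opposing
  aggregates resolve through a signed 5×5 table onto an eleven-position
  balance (five deflections each way plus balanced). Strengths transmit
  along a KER as the minimum of argument and connection.
* **Propagation paradigms** — per-compound evidence flows through the
  network in topological order under a `conservative` rule (any cause for
  concern wins; only concern travels downstream), a `tiered` rule (assay
  results overrule predictions; in vivo overrules in vitro), or the full
  signed `calculus`.
* **Compound-level queries** — activity profiles of Tanimoto neighborhoods
  (hashed path fingerprints, pluggable schemes), "given this positive
  result, which AOs should worry me?" (downstream closure with supporting
  paths), and "which assay should I run next?" (phi-coefficient call
  concordance within a similarity neighborhood, conditioned on the
  compound's own calls).
* Plus: collapsible key event groups, an is-a ontology over events and
  assays, call-vocabulary curation and overall-call aggregation, YAML/JSON
  knowledge files, deterministic DOT/GraphML export, and seeded generators
  of random networks and call datasets with planted concordance.

See `vignettes/reasoning-over-event-networks.Rmd` for the model, its
assumptions and the design decisions.

## Worked example

The packaged skin-sensitization fixture encodes the covalent-protein-binding
pathway with its seven assays, and the linalool evidence record encodes the
classic mixed pattern: reactivity and keratinocyte assays negative, the
murine lymph node assay and human data positive, one fired alert.

```r
library(aopnet)

net <- aopFixture("skin_sensitization")
net
#> KeyEventNetwork with 5 key events ( 1 MIE, 3 KE, 1 AO ), 4 KERs, 0 groups, 7 assays, 1 prediction bases

fx <- aopFixture("linalool_evidence")
propagationStates(propagate(fx$network, fx$evidence, "conservative"))
#>                       event     state
#> 1  covalent_protein_binding NoConcern
#> 2   keratinocyte_activation NoConcern
#> 3 dendritic_cell_activation   Unknown
#> 4          tcell_activation   Concern
#> 5        skin_sensitization   Concern
```

Early events come out green (the assays aimed at them are negative), the
late events red (positive in vivo and human evidence cascade to the AO),
and the dendritic-cell event stays grey: it has no data of its own and a
negative upstream result is not proof the pathway is blocked.

The calculus itself:

```r
combineSorted(c("VeryLow", "VeryLow", "VeryLow", "VeryLow"))
#> [1] "Medium"                       # weak arguments build up, but only so far

resolveArguments(data.frame(direction = c("Against", "For", "For"),
                            strength  = c("Medium", "Medium", "Low")))
#> SignedStrength: For / Low          # -M and +M cancel; one +L survives

alertedAOs(aopFixture("genotoxicity"), "ames", "Positive")
#>                    ao                   from                                          path
#> 1              cancer inherited_dna_mutation              inherited_dna_mutation -> cancer
#> 2 genetic_instability inherited_dna_mutation inherited_dna_mutation -> genetic_instability
```

A command-line wrapper is installed with the package
(`system.file("exec", "aopnet.R", package = "aopnet")`) with subcommands
`validate`, `propagate`, `alerted-aos`, `similar`, `profile`, `correlate`,
`suggest-next`, `ontology-query`, `export` and `fixtures`.

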