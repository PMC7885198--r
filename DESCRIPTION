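Package: aopnet
Title: Key Event Networks with Qualitative Weight-of-Evidence Reasoning
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Data model and reasoning engine for adverse outcome pathway
    (AOP) networks augmented with assay knowledge and structure-activity
    predictions. Key events, key event relationships, collapsible event
    groups, assays and prediction bases are held in a validated network
    object. A categorical argumentation calculus combines the
    convincingness of an argument with the reliability of its evidence
    into a five-level strength, merges same-direction and opposing
    arguments through fixed lookup tables, and transmits conclusions
    along evidence-weighted relationships. Per-compound evidence is
    propagated over the network under conservative, tiered or calculus
    paradigms to colour events by cause for concern, alert downstream
    adverse outcomes from a single assay result, and rank candidate
    follow-up assays by call concordance (phi) within a chemical
    similarity neighbourhood (Tanimoto over hashed path fingerprints).
    Includes an is-a ontology layer for selecting events and assays by
    term, curation utilities for call vocabulary and overall-call
    aggregation, YAML knowledge files, DOT/GraphML export, packaged
    example networks and seeded generators of random networks and call
    datasets with planted concordance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports: methods, stats, utils, igraph, yaml, jsonlite
Suggests: testthat (>= 3.0.0), ChemmineR, ChemmineOB, optparse, xml2
Config/testthat/edition: 3
biocViews: Software, Pathways, Network, Cheminformatics
RoxygenNote: 7.3.3
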