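# Covalent protein binding leading to skin sensitization, with the seven
# assays of the curated sensitization dataset and a structure-activity
# prediction basis for the adverse outcome.
events:
- id: covalent_protein_binding
  name: Covalent binding to skin proteins
  level: molecular
  role: MIE
- id: keratinocyte_activation
  name: Keratinocyte activation
  level: cellular
  role: KE
- id: dendritic_cell_activation
  name: Dendritic cell activation
  level: cellular
  role: KE
- id: tcell_activation
  name: T-cell proliferation and activation
  level: organ
  role: KE
- id: skin_sensitization
  name: Skin sensitization
  level: organ
  role: AO
kers:
- upstream: covalent_protein_binding
  downstream: keratinocyte_activation
  strength: High
- upstream: keratinocyte_activation
  downstream: dendritic_cell_activation
  strength: Medium
- upstream: dendritic_cell_activation
  downstream: tcell_activation
  strength: High
- upstream: tcell_activation
  downstream: skin_sensitization
  strength: High
assays:
- id: dpra
  name: DPRA
  reliability: Large
  tier: in_chemico
- id: keratinosens
  name: KeratinoSens
  reliability: Large
  tier: in_vitro
- id: lusens
  name: LuSens
  reliability: Large
  tier: in_vitro
- id: hclat
  name: h-CLAT
  reliability: Medium
  tier: in_vitro
- id: usens
  name: U-SENS
  reliability: Medium
  tier: in_vitro
- id: llna
  name: LLNA
  reliability: Large
  tier: in_vivo
- id: human_obs
  name: Observation in human
  reliability: Small
  tier: human_observation
assay_event_links:
- assay: dpra
  measurement: cysteine_depletion
  event: covalent_protein_binding
  convincingness: Large
- assay: dpra
  measurement: lysine_depletion
  event: covalent_protein_binding
  convincingness: Large
- assay: dpra
  measurement: overall_call
  event: covalent_protein_binding
  convincingness: Large
- assay: keratinosens
  measurement: overall_call
  event: keratinocyte_activation
  convincingness: Medium
- assay: lusens
  measurement: overall_call
  event: keratinocyte_activation
  convincingness: Medium
- assay: hclat
  measurement: overall_call
  event: dendritic_cell_activation
  convincingness: Medium
- assay: usens
  measurement: overall_call
  event: dendritic_cell_activation
  convincingness: Medium
- assay: llna
  measurement: ec3
  event: tcell_activation
  convincingness: Large
- assay: llna
  measurement: overall_call
  event: tcell_activation
  convincingness: Large
- assay: human_obs
  measurement: overall_call
  event: skin_sensitization
  convincingness: Large
prediction_bases:
- model: derek
  basis: skin_sens_plausible
  outcome_weight: Low
  reliability: Large
  links:
  - kind: event
    target: skin_sensitization
    convincingness: Small
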