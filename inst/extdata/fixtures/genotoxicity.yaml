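# Mutagenicity branch of the carcinogenicity network: the Ames test reports
# for inherited DNA mutation, which leads to the genetic instability and
# cancer adverse outcomes. The other mutation assays carry no calls in the
# worked example and are candidates for follow-up testing.
events:
- id: dna_adduct_formation
  name: DNA adduct formation
  level: molecular
  role: MIE
- id: inherited_dna_mutation
  name: Inherited DNA mutation
  level: molecular
  role: KE
- id: genetic_instability
  name: Genetic instability
  level: cellular
  role: AO
- id: cancer
  name: Cancer
  level: individual
  role: AO
kers:
- upstream: dna_adduct_formation
  downstream: inherited_dna_mutation
  strength: High
- upstream: inherited_dna_mutation
  downstream: genetic_instability
  strength: High
- upstream: inherited_dna_mutation
  downstream: cancer
  strength: High
assays:
- id: ames
  name: Ames bacterial reverse mutation
  reliability: Large
  tier: in_vitro
- id: mouse_lymphoma
  name: Mouse lymphoma tk assay
  reliability: Medium
  tier: in_vitro
- id: transgenic_rodent
  name: Transgenic rodent mutation assay
  reliability: Large
  tier: in_vivo
assay_event_links:
- assay: ames
  measurement: overall_call
  event: inherited_dna_mutation
  convincingness: Large
- assay: mouse_lymphoma
  measurement: overall_call
  event: inherited_dna_mutation
  convincingness: Medium
- assay: transgenic_rodent
  measurement: overall_call
  event: inherited_dna_mutation
  convincingness: Large
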