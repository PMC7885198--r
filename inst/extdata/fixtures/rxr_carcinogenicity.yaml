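# Retinoid X receptor binding leading to carcinogenicity, with the p38 MAPK
# signalling pathway dysregulation key event group and its three sub-events.
# Sub-event and intermediate names not quoted in the source figure labels
# are synthetic placeholders.
events:
- id: rxr_binding
  name: Retinoid X receptor binding
  level: molecular
  role: MIE
- id: rxr_heterodimer_activation
  name: RXR heterodimer activation (synthetic name)
  level: molecular
  role: KE
- id: p38_phosphorylation_decrease
  name: Decreased p38 phosphorylation (synthetic name)
  level: molecular
  role: KE
  group: p38_mapk_group
- id: p38_activity_decrease
  name: Decreased p38 MAPK activity (synthetic name)
  level: molecular
  role: KE
  group: p38_mapk_group
- id: p38_target_dysregulation
  name: Dysregulated p38 target gene expression (synthetic name)
  level: cellular
  role: KE
  group: p38_mapk_group
- id: cell_proliferation_increase
  name: Cell proliferation increase
  level: cellular
  role: KE
- id: carcinogenicity
  name: Carcinogenicity
  level: individual
  role: AO
kers:
- upstream: rxr_binding
  downstream: rxr_heterodimer_activation
  strength: High
- upstream: rxr_heterodimer_activation
  downstream: p38_phosphorylation_decrease
  strength: Medium
- upstream: p38_phosphorylation_decrease
  downstream: p38_activity_decrease
  strength: High
- upstream: p38_activity_decrease
  downstream: p38_target_dysregulation
  strength: Medium
- upstream: p38_target_dysregulation
  downstream: cell_proliferation_increase
  strength: Medium
- upstream: cell_proliferation_increase
  downstream: carcinogenicity
  strength: Medium
groups:
- id: p38_mapk_group
  name: p38 MAPK signalling pathway dysregulation
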