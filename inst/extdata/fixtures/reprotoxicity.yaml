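# Network of two pathways converging on reproductive toxicity: aromatase
# inhibition and androgen receptor agonism both feed the reduction in
# 17-beta oestradiol synthesis by ovarian granulosa cells.
events:
- id: aromatase_inhibition
  name: Aromatase inhibition
  level: molecular
  role: MIE
- id: androgen_receptor_agonism
  name: Androgen receptor agonism
  level: molecular
  role: MIE
- id: oestradiol_synthesis_reduction
  name: Reduction in 17-beta oestradiol synthesis by ovarian granulosa cells
  level: cellular
  role: KE
- id: impaired_ovarian_cycling
  name: Impaired ovarian cyclicity
  level: organ
  role: KE
- id: reproductive_toxicity
  name: Reproductive toxicity
  level: individual
  role: AO
kers:
- upstream: aromatase_inhibition
  downstream: oestradiol_synthesis_reduction
  strength: High
- upstream: androgen_receptor_agonism
  downstream: oestradiol_synthesis_reduction
  strength: Medium
- upstream: oestradiol_synthesis_reduction
  downstream: impaired_ovarian_cycling
  strength: High
- upstream: impaired_ovarian_cycling
  downstream: reproductive_toxicity
  strength: High
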