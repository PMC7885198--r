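compound_id,assay_id,measurement_id,variables,call,source
linalool,dpra,overall_call,,Negative,urbisch
linalool,keratinosens,overall_call,,Negative,urbisch
linalool,lusens,overall_call,,Negative,urbisch
linalool,llna,overall_call,,Positive,urbisch
linalool,human_obs,overall_call,,Positive,expert
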