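term_id	term_name	parent_id
oestrogen_receptor_event	oestrogen receptor event	
oestrogen_receptor_alpha_event	oestrogen receptor alpha event	oestrogen_receptor_event
oestrogen_receptor_beta_event	oestrogen receptor beta event	oestrogen_receptor_event
oestrogen_receptor_binding	oestrogen receptor binding	oestrogen_receptor_event
oestrogen_receptor_alpha_binding	oestrogen receptor alpha binding	oestrogen_receptor_alpha_event
oestrogen_receptor_alpha_binding	oestrogen receptor alpha binding	oestrogen_receptor_binding
oestrogen_receptor_beta_binding	oestrogen receptor beta binding	oestrogen_receptor_beta_event
oestrogen_receptor_beta_binding	oestrogen receptor beta binding	oestrogen_receptor_binding
er_assay	oestrogen receptor assay	
er_activation_assay	oestrogen receptor (ER) activation assay	er_assay
er_binding_assay	oestrogen receptor (ER) binding assay	er_assay
er_deactivation_assay	oestrogen receptor (ER) deactivation assay	er_assay
er_dimerization_assay	oestrogen receptor (ER) dimerization assay	er_assay
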