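source_id	group_index	attribute_id	value_id
sce-adverse-reaction	1	causative-agent	subst-sce
edetate-adverse-reaction	1	causative-agent	subst-edetate
subst-sce	1	is-modification-of	subst-edetate
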