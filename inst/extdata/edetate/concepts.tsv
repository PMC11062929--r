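id	name	definition_status	active
116680003	Is a (attribute)	primitive	TRUE
causative-agent	Causative agent (attribute)	primitive	TRUE
is-modification-of	Is modification of (attribute)	primitive	TRUE
subst-sce	Sodium calcium edetate (substance)	primitive	TRUE
subst-edetate	Edetate (substance)	primitive	TRUE
sce-adverse-reaction	Sodium calcium edetate adverse reaction (disorder)	fully_defined	TRUE
edetate-adverse-reaction	Edetate adverse reaction (disorder)	primitive	TRUE
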