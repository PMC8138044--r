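allele	nf_type	pass
Afghan	NF5Ac	TRUE
Afghan	NF4Ac	FALSE
Tajik	NF5Ac	TRUE
Tajik	NF4Ac	TRUE
Tajik	NF5NonAc	TRUE
European	NF5Ac	TRUE
European	NF4Ac	FALSE
European	NF4NonAc	TRUE
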