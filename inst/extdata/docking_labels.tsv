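allele	nf_type	pass
Afghan	NF5Ac	TRUE
Afghan	NF4Ac	TRUE
Afghan	NF5NonAc	FALSE
Afghan	NF4NonAc	FALSE
Tajik	NF5Ac	TRUE
Tajik	NF4Ac	TRUE
Tajik	NF5NonAc	TRUE
Tajik	NF4NonAc	FALSE
European	NF5Ac	TRUE
European	NF4Ac	TRUE
European	NF5NonAc	FALSE
European	NF4NonAc	TRUE
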