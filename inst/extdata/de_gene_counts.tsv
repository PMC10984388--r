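genotype	up_regulated	total_de
E168d2_hom	248	673
R90W_hom	70	265
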