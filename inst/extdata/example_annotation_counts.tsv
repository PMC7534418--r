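quantity	value
gypsy_like_elements	64897
copia_like_elements	20632
busco_complete	277
busco_total	303
genes_total	37908
genes_tpm_supported	23724
genes_in_orthogroup	36521
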