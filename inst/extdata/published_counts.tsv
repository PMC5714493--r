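dataset	introns	ga_donors	gg_donors
focus_genes	297	31	5
large_gene_sample	623	54	10
human_genome	222263	14	32
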