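group	n_eves	n_lineages
Bunyaviridae	103	4
Circoviridae	46	2
Mononegavirales	32	5
Parvoviridae	21	2
Totiviridae	8	1
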