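species	cluster_index	cluster_type	p450_name
Sphaerosporella brunnea	2	Terpene	CYP654C8
Sphaerosporella brunnea	2	Terpene	CYP667F1
Sphaerosporella brunnea	11	Fungal-RiPP	CYP51F1
Sphaerosporella brunnea	12	NRPS	CYP5109B1
Sphaerosporella brunnea	12	NRPS	CYP6836A1
Sphaerosporella brunnea	16	NRPS	CYP613S1
Trichophaea hybrida	14	Terpene	CYP6637B2
Wilcoxina mikolae CBS 423.85	9	Terpene	CYP51048A1
Wilcoxina mikolae CBS 423.85	11	Terpene	CYP6637B2
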