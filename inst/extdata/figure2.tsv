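group	n_families
SAP	103
ECM	89
SHARED	39
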