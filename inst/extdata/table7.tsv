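species	n_clusters
Ascobolus immersus	14
Morchella importuna	12
Sphaerosporella brunnea	18
Terfezia claveryi	8
Tirmania nivea	9
Trichophaea hybrida	16
Tuber borchii	8
Tuber brumale	8
Tuber indicum	10
Tuber magnatum	10
Tuber melanosporum	8
Wilcoxina mikolae CBS 423.85	21
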