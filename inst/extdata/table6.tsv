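species	n_families	n_subfamilies
Ascobolus immersus RN42	36	49
Ascodesmis nigricans CBS 389.68	24	26
Choiromyces venosus 120613-1	24	29
Kalaharituber pfeilii F3	20	22
Morchella importuna CCBAS932	33	36
Morchella importuna SCYDJ1-A1	33	36
Pyronema confluens CBS100304	37	43
Sphaerosporella brunnea Sb_GMNB300	38	45
Terfezia boudieri ATCC MYA-4762	16	18
Terfezia claveryi T7	14	16
Tirmania nivea G3	17	19
Trichophaea hybrida UTF0779	31	36
Tuber aestivum var. urcinatum	24	26
Tuber borchii Tbo3840	22	27
Tuber brumale	24	27
Tuber indicum	24	28
Tuber magnatum	21	23
Tuber melanosporum Mel28	23	25
Wilcoxina mikolae CBS 423.85	40	49
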