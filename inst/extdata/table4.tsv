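species	lifestyle	total_hits	p450s	no_hits	false_positives	fragments
Ascobolus immersus RN42	SAP	63	58	4	1	0
Ascodesmis nigricans CBS 389.68	SAP	31	28	2	0	1
Morchella importuna CCBAS932	SAP	40	37	3	0	0
Morchella importuna SCYDJ1-A1	SAP	41	37	3	0	1
Pyronema confluens CBS100304	SAP	55	44	1	2	8
Choiromyces venosus 120613-1	ECM	52	33	1	1	17
Kalaharituber pfeilii F3	ECM	35	32	0	0	3
Sphaerosporella brunnea Sb_GMNB300	ECM	49	47	0	0	2
Terfezia boudieri ATCC MYA-4762	ECM	24	19	1	2	2
Terfezia claveryi T7	ECM	19	17	0	0	2
Tirmania nivea G3	ECM	21	19	0	0	2
Trichophaea hybrida UTF0779	ECM	44	37	0	0	7
Tuber aestivum var. urcinatum	ECM	31	29	0	0	2
Tuber borchii Tbo3840	ECM	74	55	0	0	19
Tuber brumale	ECM	37	32	0	0	5
Tuber indicum	ECM	39	35	0	0	4
Tuber magnatum	ECM	32	27	0	1	4
Tuber melanosporum Mel28	ECM	35	30	0	0	5
Wilcoxina mikolae CBS 423.85	ECM	57	52	1	0	4
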