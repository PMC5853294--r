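# Daily TAG production (nmol C per 1e6 cells) in N-deprived D. tertiolecta,
# by pathway, from published pulse-chase measurements: starch degradation,
# direct de novo assimilation, de novo via newly made polar lipids, and the
# independently measured daily total from complete labeling. *_sd columns are
# reported standard deviations of three experiments.
day	from_starch	from_starch_sd	de_novo_direct	de_novo_direct_sd	de_novo_via_pl	de_novo_via_pl_sd	total_measured	total_measured_sd
1	0	0	8.0	1	0	0	38	3
2	36.2	3.1	7.5	1	17.5	2.0	66	3
3	46.6	3.3	6.25	0.8	20.2	2.8	74	7
4	38.0	3.9	3.75	0.2	12.9	1.5	50	5
5	37.2	2.2	3.1	0.3	11.0	1.0	44	8
6	27.3	5.1	2.5	0.2	10.1	0.8	34	4
7	24.0	3.2	2.5	0.3	10.0	1.1	28	7
8	25.2	3.0	1.25	0.1	4.2	0.5	24	6
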