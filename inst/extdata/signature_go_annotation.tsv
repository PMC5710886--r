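go_id	go_name	total_genes	changed_genes	enrichment
GO:0002376	Immune system process	921	22	5.440415
GO:0042110	T cell activation	209	12	13.076874
GO:0046649	Lymphocyte activation	279	13	10.612266
GO:0001775	Cell activation	452	15	7.558260
GO:0045321	Leukocyte activation	318	13	9.310762
GO:0006955	Immune response	567	16	6.426965
GO:0042287	MHC protein binding	13	5	87.598291
GO:0002682	Regulation of immune system process	461	14	6.916655
GO:0048583	Regulation of response to stimulus	516	14	6.179414
GO:0042288	MHC class I protein binding	10	4	91.102222
GO:0050776	Regulation of immune response	282	10	8.076438
GO:0023052	signaling	2301	26	2.573509
GO:0002684	Positive regulation of immune system process	315	10	7.230335
GO:0051249	Regulation of lymphocyte activation	181	8	10.066544
GO:0030217	T cell differentiation	82	6	16.665041
GO:0002694	Regulation of leukocyte activation	194	8	9.391982
GO:0048518	Positive regulation of biological process	1680	21	2.846944
GO:0019882	antigen processing and presentation	49	5	23.240363
GO:0051251	Positive regulation of lymphocyte activation	141	7	11.307013
GO:0050865	Regulation of cell activation	204	8	8.931590
GO:0050778	Positive regulation of immune response	205	8	8.888022
GO:0002696	Positive regulation of leukocyte activation	146	7	10.919787
GO:0048584	Positive regulation of response to stimulus	286	9	7.167133
GO:0050863	Regulation of T cell activation	149	7	10.699925
GO:0050867	Positive regulation of cell activation	151	7	10.558205
GO:0002521	Leukocyte differentiation	152	7	10.488743
GO:0002429	Immune response-activating cell surface receptor signaling pathway	99	6	13.803367
GO:0002768	Immune response-regulating cell surface receptor signaling pathway	102	6	13.397386
GO:0023033	Signaling pathway	1801	21	2.655673
GO:0050896	Response to stimulus	2482	25	2.294073
GO:0030098	Lymphocyte differentiation	109	6	12.537003
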