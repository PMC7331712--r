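condition	gene	function	betweenness	degree
glycine	4.3.1.1	Aspartate ammonia-lyase	0.0320	6
glycine	1.1.1.30	3-hydroxybutyrate dehydrogenase	0.0176	4
glycine	3.1.1.75	Poly(3-hydroxybutyrate) depolymerase	0.0081	4
glycine	2.6.1.66	Valine-pyruvate transaminase	0.0064	3
glycine	1.1.1.36	Acetoacetyl-CoA reductase	0.0026	2
glycine	3.1.1.22	Hydroxybutyrate-dimer hydrolase	0.0006	2
glycine	2.8.3.5	3-oxoacid CoA-transferase	0.0000	2
glycine	3.2.1.22	Alpha-galactosidase	0.0000	1
wet	1.2.1.60	5-carboxymethyl-2-hydroxymuconic-semialdehyde dehydrogenase	0.0035	8
wet	4.1.3.1	Isocitrate lyase	0.0142	4
wet	1.1.1.42	Isocitrate dehydrogenase (NADP+)	0.0031	6
dry	5.4.99.15	(1->4)-alpha-D-glucan 1-alpha-D-glucosylmutase	0.0089	6
dry	2.2.1.1	Transketolase	0.0532	21
dry	5.4.99.16	Maltose alpha-D-glucosyltransferase	0.0303	10
dry	6.5.1.1	DNA ligase (ATP)	0.0180	9
dry	3.2.1.141	4-alpha-D-glucanotrehalose trehalohydrolase	0.0156	9
dry	5.4.2.6	Beta-phosphoglucomutase	0.0108	17
dry	3.4.11.5	Prolyl aminopeptidase	0.0157	6
dry	2.7.1.29	Glycerone kinase	0.0001	2
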