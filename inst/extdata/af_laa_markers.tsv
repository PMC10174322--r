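id	layer	FC	log2FC	pValue	qValue	Regulation
XR_001750763.2	lncRNA	25.10239951	4.649753371	0.00016291	0.03332375	Up
XR_932105.2	lncRNA	12.9478958	3.694645755	2.05e-9	2.49e-6	Up
NR_038446.1	lncRNA	8.119639528	3.02141568	5.54e-7	0.00029081	Up
ENST00000447009	lncRNA	9.139720493	3.192150046	0.000106541	0.024118784	Up
Has-miR-512-3p	miRNA	0.428858815	-1.221425321	0.00000915	0.001991071	Down
Has-miR-302c-3p	miRNA	0.39841765	-1.327646533	0.001069633	0.034465953	Down
Has-miR-302b-3p	miRNA	0.276407886	-1.855129318	0.000399227	0.024354625	Down
TLR2	mRNA	2.387902301	1.255743811	0.0000422	0.001975113	Up
JAK3	mRNA	2.510805036	1.328150008	0.0000272	0.001413451	Up
CCL5	mRNA	3.193522958	1.675148822	0.000175172	0.005543213	Up
VCAM1	mRNA	2.270942613	1.18329125	1.75e-10	0.000000111	Up
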