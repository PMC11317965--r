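# DnaA-bound regions of E. coli MG1655 (NC_000913.2 coordinates) mapped by
# ChIP-seq, with coverage relative to an untagged-function control and the
# annotated double DnaA box within 200 bp of each coordinate. Upper-case
# bases mark the two 9 bp boxes; the dnaN region has no double box (na);
# box_shared marks regions annotated with the same box as the row above.
coordinate	locus	intragenic	coverage_ratio	double_box	box_shared
813331	DARS1	FALSE	16	cTAATACACAtggTTATCCACAg	FALSE
1144772	rne	TRUE	5	tTTATCACCCgcTTACTCACAg	FALSE
2344805	nrdA	FALSE	14	gTTATCCACAaagTTATGCACTt	FALSE
2969124	DARS2	FALSE	78	gTTCTTCACAactCTATCCACAg	FALSE
2969306	DARS2	FALSE	199	gTTCTTCACAactCTATCCACAg	TRUE
2969501	DARS2	FALSE	213	tCTTACACCAtgTTATCCACAg	FALSE
3600944	rpoH	FALSE	4	tTTATCCACAagTTCAATGCAa	FALSE
3882238	dnaN	TRUE	5	na	FALSE
3883968	dnaA	FALSE	5	tTTATCCACAggaCTTTCCAGAa	FALSE
3925806	oriC	FALSE	218	cTTCCTGACAgagTTATCCACAg	FALSE
3925943	oriC	FALSE	174	cTTCCTGACAgagTTATCCACAg	TRUE
3926498	mioC	FALSE	25	tTTAATCCCAtacTTTTCCACAg	FALSE
4046831	polA	FALSE	123	tTTATGCACAaagTTATCCACAt	FALSE
4207740	purH	FALSE	124	tTTACGCACAgagTTATCCACAa	FALSE
4392740	datA	FALSE	213	cTTGTAAACAgagTTATCCACAg	FALSE
4462739	nrdD	FALSE	62	tTTAAGAACAggTTATCCACAg	FALSE
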