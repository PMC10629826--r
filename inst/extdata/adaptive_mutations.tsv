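environment	ploidy	gene	mutation	class
CLM	2N	PDR1	+/E768G	missense
CLM	2N	PDR1	F1047V	missense
CLM	2N	PDR1	+/C862Y	missense
CLM	2N	PDR1	+/T817K	missense
CLM	2N	PDR1	+/K540E	missense
CLM	2N	PDR1	+/G282V	missense
CLM	2N	PDR1	+/E829K	missense
CLM	2N	PDR1	+/N733Y	missense
CLM	2N	PDR1	+/T1043K	missense
CLM	2N	PDR1	+/F769L	missense
CLM	2N	PDR1	+/Y864H	missense
CLM	2N	PDR1	+/Q762K	missense
CLM	2N	PDR1	+/L278V	missense
CLM	2N	PDR1	+/A826E	missense
CLM	2N	PDR1	+/R821G	missense
CLM	2N	PDR3	+/S773I	missense
CLM	2N	PDR3	+/L281F	missense
CLM	2N	PDR3	+/G957D	missense
CLM	2N	PDR3	+/L279S	missense
CLM	2N	PDR3	+/K272N	missense
CLM	1N	PDR1	N1050D	missense
CLM	1N	PDR1	P261L	missense
CLM	1N	PDR1	P261S	missense
CLM	1N	PDR1	L868F	missense
CLM	1N	PDR1	V871F	missense
CLM	1N	PDR1	H751N	missense
CLM	1N	PDR1	H751Q	missense
CLM	1N	PDR1	S753SVYRSFAHYS	coding_indel
CLM	1N	PDR1	C862W	missense
CLM	1N	PDR1	H723N	missense
CLM	1N	PDR1	Y270S	missense
CLM	1N	PDR1	K540Q	missense
CLM	1N	PDR1	R959M	missense
CLM	1N	PDR1	E688D	missense
CLM	1N	PDR1	N1049H	missense
CLM	1N	PDR1	A301S	missense
CLM	1N	PDR1	Y864H	missense
CLM	1N	PDR1	T358R	missense
CLM	1N	PDR1	S814Y	missense
CLM	1N	PDR1	F607L	missense
CLM	1N	PDR1	R747P	missense
CLM	1N	PDR1	L867F	missense
CLM	1N	PDR1	L714R	missense
CLM	1N	PDR1	G875A	missense
CLM	1N	PDR1	E491D	missense
CLM	1N	PDR1	F511V	missense
CLM	1N	PDR1	A863G	missense
CLM	1N	PDR1	S259G	missense
CLM	1N	PDR1	V819I	missense
CLM	1N	PDR3	R794S	missense
CLM	1N	PDR3	C707F	missense
CLM	1N	PDR3	F710L	missense
CLM	1N	PDR3	L249V	missense
CLM	1N	PDR3	L959Q	missense
CLM	1N	PDR3	Y963H	missense
CLM	1N	PDR3	A681E	missense
FLC4	2N	CYC8	+/Q610*	nonsense
FLC4	2N	CYC8	+/L370P	missense
FLC4	2N	HAP1	+/V638F	missense
FLC4	2N	PDR1	+/H689N	missense
FLC4	2N	SSO2	+/627963T>A	noncoding
FLC4	2N	SSO2	+/D233G	missense
FLC4	2N	TUP1	+/I416_fs	coding_indel
FLC4	2N	TUP1	+/I704N	missense
FLC4	2N	TUP1	+/262515A>T	noncoding
FLC4	2N	VPS35	+/131054G>GT	noncoding
FLC4	2N	VPS35	+/S64T	missense
FLC4	2N	YHK8	+/N337T	missense
FLC4	2N	YHK8	+/203404T>C	noncoding
FLC4	1N	CSG2	S26F	missense
FLC4	1N	CSG2	E234D	missense
FLC4	1N	CSG2	G258C	missense
FLC4	1N	CYC8	G265C	missense
FLC4	1N	CYC8	NA729_fs	coding_indel
FLC4	1N	CYC8	A384T	missense
FLC4	1N	CYC8	Y268D	missense
FLC4	1N	HAP1	646403A>C	noncoding
FLC4	1N	HAP1	V1471ETHKFNCSNKRSEIDQTSSN	coding_indel
FLC4	1N	PDR1	S832N	missense
FLC4	1N	PDR1	E675K	missense
FLC4	1N	PDR3	L249I	missense
FLC4	1N	PDR3	R210M	missense
FLC4	1N	PDR5	P943T	missense
FLC4	1N	PDR5	E169K	missense
FLC4	1N	PDR5	L790I	missense
FLC4	1N	PDR5	T912S	missense
FLC4	1N	ROX1	Q107*	nonsense
FLC4	1N	ROX1	K72T	missense
FLC4	1N	ROX1	M1T	missense
FLC4	1N	SKN7	D446E_fs	coding_indel
FLC4	1N	SKN7	D446E	missense
FLC4	1N	SKN7	S486*	nonsense
FLC4	1N	SKN7	S411P	missense
FLC4	1N	SUR1	Y116_fs	coding_indel
FLC4	1N	SUR1	Y116N	missense
FLC4	1N	SUR1	Y235C	missense
FLC4	1N	SUR1	E263*	nonsense
FLC4	1N	SUR1	Y104*	nonsense
FLC4	1N	SUR1	D141E	missense
FLC4	1N	SUR1	M1V	missense
FLC4	1N	SUR1	R218*	nonsense
FLC4	1N	SUR1	Y116*	nonsense
FLC4	1N	SUR1	H176Y	missense
FLC4	1N	SUR1	R360_fs	coding_indel
FLC4	1N	SXM1	SS58_fs	coding_indel
FLC4	1N	SXM1	E701*_fs	coding_indel
FLC4	1N	SXM1	G259_fs	coding_indel
FLC4	1N	TUP1	D699Y	missense
FLC4	1N	UPC2	V419F	missense
FLC4	1N	UPC2	L876R	missense
FLC4	1N	UPC2	L876P	missense
GlyEtOH	2N	HAP1	K1474E	missense
GlyEtOH	2N	HAP1	V1485I/K1474E,V1485I	missense
GlyEtOH	2N	HAP1	+/IYVTSI1483I	coding_indel
GlyEtOH	2N	HEM2	+/L338*	nonsense
GlyEtOH	2N	HEM2	+/A248E	missense
GlyEtOH	2N	HEM3	+/S20P	missense
GlyEtOH	2N	HEM3	+/G10E	missense
GlyEtOH	2N	HEM3	+/G130G_fs	coding_indel
GlyEtOH	2N	HEM3	+/C111F	missense
GlyEtOH	2N	HEM3	+/Y261*	nonsense
GlyEtOH	2N	HEM3	+/G157E	missense
GlyEtOH	2N	HEM3	+/G211C	missense
GlyEtOH	2N	IRA1	+/N66I	missense
GlyEtOH	2N	IRA2	+/I1657N	missense
GlyEtOH	2N	NDI1	+/I298S	missense
GlyEtOH	2N	NDI1	+/R205G	missense
GlyEtOH	2N	WHI2	+/S289P	missense
GlyEtOH	2N	WHI2	+/G141*	nonsense
GlyEtOH	2N	WHI2	+/410637A>T	noncoding
GlyEtOH	2N	WHI2	+/VLREDLDYYC165_fs	coding_indel
GlyEtOH	1N	GPB2	Q602*	nonsense
GlyEtOH	1N	GPB2	R509*	nonsense
GlyEtOH	1N	IRA1	D1116_fs	coding_indel
GlyEtOH	1N	IRA1	L1429*	nonsense
GlyEtOH	1N	IRA1	ILV1729I	coding_indel
GlyEtOH	1N	IRA1	P1827L	missense
GlyEtOH	1N	IRA1	K2034_fs	coding_indel
GlyEtOH	1N	IRA1	Y2354*	nonsense
GlyEtOH	1N	IRA1	L1549F_fs	coding_indel
GlyEtOH	1N	IRA1	E2440*	nonsense
GlyEtOH	1N	IRA1	S1612*	nonsense
GlyEtOH	1N	IRA1	G780_fs	coding_indel
GlyEtOH	1N	IRA1	G780*	nonsense
GlyEtOH	1N	IRA1	S2966*	nonsense
GlyEtOH	1N	IRA1	W2779L_fs	coding_indel
GlyEtOH	1N	IRA1	C2067*	nonsense
GlyEtOH	1N	IRA1	I1862S	missense
GlyEtOH	1N	IRA1	LLMRYLL2976_fs	coding_indel
GlyEtOH	1N	IRA1	Y1239*	nonsense
GlyEtOH	1N	IRA1	L587*	nonsense
GlyEtOH	1N	IRA1	G1716_fs	coding_indel
GlyEtOH	1N	IRA2	G2097*	nonsense
GlyEtOH	1N	IRA2	I339R	missense
GlyEtOH	1N	IRA2	E3063*	nonsense
GlyEtOH	1N	IRA2	L598W	missense
GlyEtOH	1N	IRA2	F2628S	missense
GlyEtOH	1N	IRA2	R1852L	missense
GlyEtOH	1N	IRA2	I1463_fs	coding_indel
GlyEtOH	1N	IRA2	E2558*	nonsense
GlyEtOH	1N	IRA2	R2195_fs	coding_indel
GlyEtOH	1N	SSK2	G1275D	missense
GlyEtOH	1N	SSK2	L968_fs	coding_indel
GlyEtOH	1N	WHI2	410536G>A	noncoding
GlyEtOH	1N	YTA6	K517R	missense
GlyEtOH	1N	YTA6	418169T>G	noncoding
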