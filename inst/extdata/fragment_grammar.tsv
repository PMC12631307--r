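role	name	smiles
core	benzene	cxccc|ccx
core	pyridine	cxccc|ncx
core	pyrimidine	cxncc|cnx
core	pyrazine	cxncc|ncx
core	thiophene	cxcc|csx
core	furan	cxcc|cox
core	pyrrole	cxcc|c[nH]x
core	imidazole	cxnc|c[nH]x
core	cyclohexane	CxCCC|CCx
core	cyclopentane	CxCC|CCx
core	piperidine	CxCCN|CCx
core	piperazine	CxCN|CCNx
core	morpholine	CxCN|CCOx
core	oxane	CxCCC|OCx
core	pyrrolidine	CxCCN|Cx
core	naphthalene	cxcccyccc|ccycx
macro	macro12	Cx|CCCCCCCCCCCx
macro	macro13o	Cx|CCCCOCCCCCCx
macro	macro14n	Cx|CCCNC(=O)CCCCCCx
macro	macro15oo	Cx|CCOCCOCCCCCCx
sidechain	ala	C
sidechain	val	C(C)C
sidechain	ser	CO
sidechain	leu	CC(C)C
sidechain	met	CCSC
sidechain	phe	Cc9ccccc9
suba	none
suba	methyl	C
suba	ethyl	CC
suba	propyl	CCC
suba	hydroxyethyl	OCC
suba	aminoethyl	NCC
suba	methoxy	CO
suba	hydroxy	O
suba	amino	N
suba	fluoro	F
suba	chloro	Cl
suba	nitrile	N#C
suba	trifluoromethyl	FC(F)(F)
suba	acetamido	CC(=O)N
suba	methylsulfonyl	CS(=O)(=O)
subb	methyl	C
subb	ethyl	CC
subb	propyl	CCC
subb	isopropyl	C(C)C
subb	hydroxyethyl	CCO
subb	aminoethyl	CCN
subb	methoxy	OC
subb	hydroxy	O
subb	amino	N
subb	fluoro	F
subb	chloro	Cl
subb	nitrile	C#N
subb	trifluoromethyl	C(F)(F)F
subb	carboxyl	C(=O)O
subb	acetamide	NC(C)=O
subb	sulfonamide	S(N)(=O)=O
subb	dimethylamino	N(C)C
linker	c1	C
linker	c2	CC
linker	c3	CCC
linker	oxyethyl	CCO
linker	amide	C(=O)NC
linker	peg	CCOCCOCC
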