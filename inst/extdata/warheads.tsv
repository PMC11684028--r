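id	name	smarts	reversibility	family	priority	exemplar_smiles
1	acrylamide	[CH2]=[CH][CX3](=O)[NX3]	irreversible	acrylamide	7	C=CC(=O)Nc1ccccc1
2	substituted acrylamide	[#6][CX3]=[CX3][CX3](=O)[NX3]	irreversible	acrylamide	6	CN(C)C/C=C/C(=O)Nc1ccccc1
3	propiolamide	[CX2H1]#[CX2][CX3](=O)[NX3]	irreversible	alkynamide	14	C#CC(=O)Nc1ccccc1
4	butynamide	[CH3][CX2]#[CX2][CX3](=O)[NX3]	irreversible	alkynamide	12	CC#CC(=O)Nc1ccccc1
5	substituted alkynamide	[#6;!$([CH3])][CX2]#[CX2][CX3](=O)[NX3]	irreversible	alkynamide	13	O=C(C#Cc1ccccc1)N(C)C
6	chloroacetamide	Cl[CH2][CX3](=O)[NX3]	irreversible	haloacetamide	17	O=C(CCl)Nc1ccccc1
7	bromoacetamide	Br[CH2][CX3](=O)[NX3]	irreversible	haloacetamide	18	O=C(CBr)Nc1ccccc1
8	chlorofluoroacetamide	Cl[CH1](F)[CX3](=O)[NX3]	irreversible	haloacetamide	16	O=C(C(F)Cl)Nc1ccccc1
9	epoxide	[CX4]1[OX2][CX4]1	irreversible	epoxide	21	c1ccccc1C1CO1
10	aziridine	[CX4]1[NX3][CX4]1	irreversible	aziridine	22	C1CN1c1ccccc1
11	vinyl sulfonamide	[CH2]=[CH][SX4](=O)(=O)[NX3]	irreversible	vinyl sulfonamide	8	C=CS(=O)(=O)Nc1ccccc1
12	vinyl sulfone	[CH2]=[CH][SX4](=O)(=O)[#6]	irreversible	vinyl sulfone	9	C=CS(=O)(=O)c1ccccc1
13	vinyl ketone	[CH2]=[CH][CX3](=O)[#6]	irreversible	vinyl ketone	10	C=CC(=O)c1ccccc1
14	acrylate ester	[CH2]=[CH][CX3](=O)[OX2][#6]	irreversible	acrylate	11	C=CC(=O)OCC
15	maleimide	[CX3]1(=O)[CH]=[CH][CX3](=O)[NX3]1	irreversible	maleimide	4	O=C1C=CC(=O)N1c1ccccc1
16	allenamide	[CH2]=[CX2]=[CH][CX3](=O)[NX3]	irreversible	allenamide	5	C=C=CC(=O)N(C)C
17	alpha-chloroketone	Cl[CH2][CX3](=O)[#6]	irreversible	haloketone	19	O=C(CCl)c1ccccc1
18	alpha-bromoketone	Br[CH2][CX3](=O)[#6]	irreversible	haloketone	20	O=C(CBr)c1ccccc1
19	ynone	[CX2]#[CX2][CX3](=O)[#6]	irreversible	ynone	15	C#CC(=O)c1ccccc1
20	isothiocyanate	[NX2]=[CX2]=[SX1]	irreversible	isothiocyanate	30	S=C=Nc1ccccc1
21	sulfonyl fluoride	[SX4](=O)(=O)F	irreversible	sulfonyl fluoride	28	O=S(=O)(F)c1ccccc1
22	2-halopyrimidine	[F,Cl]c1ncccn1	irreversible	heteroaryl halide	29	Clc1ncccn1
23	cyanoacrylamide	[CH2]=[CX3]([CX2]#[NX1])[CX3](=O)[NX3]	reversible	cyanoacrylamide	3	C=C(C#N)C(=O)Nc1ccccc1
24	beta-substituted cyanoacrylamide	[#6][CX3H1]=[CX3]([CX2]#[NX1])[CX3](=O)[NX3]	reversible	cyanoacrylamide	2	C/C=C(\C#N)C(=O)N1CCCCC1
25	beta,beta-disubstituted cyanoacrylamide	[#6][CX3]([#6])=[CX3]([CX2]#[NX1])[CX3](=O)[NX3]	reversible	cyanoacrylamide	1	CC(C)=C(C#N)C(=O)N1CCCCC1
26	aldehyde	[CX3H1](=O)[#6]	reversible	aldehyde	25	O=Cc1ccccc1
27	cyanamide	[NX3][CX2]#[NX1]	reversible	cyanamide	26	N#CN1CCCCC1
28	boronic acid	[BX3]([OX2])[OX2]	reversible	boronic acid	27	OB(O)c1ccccc1
29	alpha-ketoamide	[#6][CX3](=O)[CX3](=O)[NX3]	reversible	ketoamide	23	CC(=O)C(=O)Nc1ccccc1
30	trifluoromethyl ketone	[#6][CX3](=O)[CX4](F)(F)F	reversible	activated ketone	24	O=C(c1ccccc1)C(F)(F)F
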