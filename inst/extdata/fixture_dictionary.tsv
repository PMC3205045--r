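benzene	SMILES	c1ccccc1
benzene	InChI	InChI=1S/C6H6/c1-2-4-6-5-3-1/h1-6H
toluene	SMILES	Cc1ccccc1
toluene	InChI	InChI=1S/C7H8/c1-7-5-3-2-4-6-7/h2-6H,1H3
ethyl acetate	SMILES	CCOC(C)=O
ethyl acetate	InChI	InChI=1S/C4H8O2/c1-3-6-4(2)5/h3H2,1-2H3
water	SMILES	O
water	InChI	InChI=1S/H2O/h1H2
methanol	SMILES	CO
methanol	InChI	InChI=1S/CH4O/c1-2/h2H,1H3
ethanol	SMILES	CCO
ethanol	InChI	InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3
acetone	SMILES	CC(C)=O
acetone	InChI	InChI=1S/C3H6O/c1-3(2)4/h1-2H3
acetic acid	SMILES	CC(O)=O
acetic acid	InChI	InChI=1S/C2H4O2/c1-2(3)4/h1H3,(H,3,4)
pyridine	SMILES	c1ccncc1
pyridine	InChI	InChI=1S/C5H5N/c1-2-4-6-5-3-1/h1-5H
phenol	SMILES	Oc1ccccc1
phenol	InChI	InChI=1S/C6H6O/c7-6-4-2-1-3-5-6/h1-5,7H
aniline	SMILES	Nc1ccccc1
aniline	InChI	InChI=1S/C6H7N/c7-6-4-2-1-3-5-6/h1-5H,7H2
naphthalene	SMILES	c1ccc2ccccc2c1
naphthalene	InChI	InChI=1S/C10H8/c1-2-6-10-8-4-3-7-9(10)5-1/h1-8H
chloroform	SMILES	ClC(Cl)Cl
chloroform	InChI	InChI=1S/CHCl3/c2-1(3)4/h1H
dichloromethane	SMILES	ClCCl
dichloromethane	InChI	InChI=1S/CH2Cl2/c2-1-3/h1H2
diethyl ether	SMILES	CCOCC
diethyl ether	InChI	InChI=1S/C4H10O/c1-3-5-4-2/h3-4H2,1-2H3
tetrahydrofuran	SMILES	C1CCOC1
tetrahydrofuran	InChI	InChI=1S/C4H8O/c1-2-4-5-3-1/h1-4H2
hexane	SMILES	CCCCCC
hexane	InChI	InChI=1S/C6H14/c1-3-5-6-4-2/h3-6H2,1-2H3
cyclohexane	SMILES	C1CCCCC1
cyclohexane	InChI	InChI=1S/C6H12/c1-2-4-6-5-3-1/h1-6H2
acetonitrile	SMILES	CC#N
acetonitrile	InChI	InChI=1S/C2H3N/c1-2-3/h1H3
formaldehyde	SMILES	C=O
formaldehyde	InChI	InChI=1S/CH2O/c1-2/h1H2
formic acid	SMILES	OC=O
formic acid	InChI	InChI=1S/CH2O2/c2-1-3/h1H,(H,2,3)
benzaldehyde	SMILES	O=Cc1ccccc1
benzaldehyde	InChI	InChI=1S/C7H6O/c8-6-7-4-2-1-3-5-7/h1-6H
benzoic acid	SMILES	OC(=O)c1ccccc1
benzoic acid	InChI	InChI=1S/C7H6O2/c8-7(9)6-4-2-1-3-5-6/h1-5H,(H,8,9)
styrene	SMILES	C=Cc1ccccc1
styrene	InChI	InChI=1S/C8H8/c1-2-8-6-4-3-5-7-8/h2-7H,1H2
anisole	SMILES	COc1ccccc1
anisole	InChI	InChI=1S/C7H8O/c1-8-7-5-3-2-4-6-7/h2-6H,1H3
nitrobenzene	SMILES	O=[N+]([O-])c1ccccc1
nitrobenzene	InChI	InChI=1S/C6H5NO2/c8-7(9)6-4-2-1-3-5-6/h1-5H
chlorobenzene	SMILES	Clc1ccccc1
chlorobenzene	InChI	InChI=1S/C6H5Cl/c7-6-4-2-1-3-5-6/h1-5H
bromobenzene	SMILES	Brc1ccccc1
bromobenzene	InChI	InChI=1S/C6H5Br/c7-6-4-2-1-3-5-6/h1-5H
ethylene	SMILES	C=C
ethylene	InChI	InChI=1S/C2H4/c1-2/h1-2H2
propene	SMILES	CC=C
propene	InChI	InChI=1S/C3H6/c1-3-2/h3H,1H2,2H3
methane	SMILES	C
methane	InChI	InChI=1S/CH4/h1H4
ethane	SMILES	CC
ethane	InChI	InChI=1S/C2H6/c1-2/h1-2H3
propane	SMILES	CCC
propane	InChI	InChI=1S/C3H8/c1-3-2/h3H2,1-2H3
butane	SMILES	CCCC
butane	InChI	InChI=1S/C4H10/c1-3-4-2/h3-4H2,1-2H3
glycerol	SMILES	OCC(O)CO
glycerol	InChI	InChI=1S/C3H8O3/c4-1-3(6)2-5/h3-6H,1-2H2
glucose	SMILES	OCC1OC(O)C(O)C(O)C1O
glucose	InChI	InChI=1S/C6H12O6/c7-1-2-3(8)4(9)5(10)6(11)12-2/h2-11H,1H2
urea	SMILES	NC(N)=O
urea	InChI	InChI=1S/CH4N2O/c2-1(3)4/h(H4,2,3,4)
ammonia	SMILES	N
ammonia	InChI	InChI=1S/H3N/h1H3
hydrogen peroxide	SMILES	OO
hydrogen peroxide	InChI	InChI=1S/H2O2/c1-2/h1-2H
sulfuric acid	SMILES	OS(O)(=O)=O
sulfuric acid	InChI	InChI=1S/H2O4S/c1-5(2,3)4/h(H2,1,2,3,4)
nitric acid	SMILES	O[N+]([O-])=O
nitric acid	InChI	InChI=1S/HNO3/c2-1(3)4/h(H,2,3,4)
hydrochloric acid	SMILES	Cl
hydrochloric acid	InChI	InChI=1S/ClH/h1H
sodium chloride	SMILES	[Na+].[Cl-]
sodium chloride	InChI	InChI=1S/ClH.Na/h1H;/q;+1/p-1
ethyl benzoate	SMILES	CCOC(=O)c1ccccc1
ethyl benzoate	InChI	InChI=1S/C9H10O2/c1-2-11-9(10)8-6-4-3-5-7-8/h3-7H,2H2,1H3
methyl acetate	SMILES	COC(C)=O
methyl acetate	InChI	InChI=1S/C3H6O2/c1-3(4)5-2/h1-2H3
dimethyl sulfoxide	SMILES	CS(C)=O
dimethyl sulfoxide	InChI	InChI=1S/C2H6OS/c1-4(2)3/h1-2H3
dimethylformamide	SMILES	CN(C)C=O
dimethylformamide	InChI	InChI=1S/C3H7NO/c1-4(2)3-5/h3H,1-2H3
2,5-dichlorobenzylamine	SMILES	NCc1cc(Cl)ccc1Cl
2,5-dichlorobenzylamine	InChI	InChI=1S/C7H7Cl2N/c8-6-1-2-7(9)5(3-6)4-10/h1-3H,4,10H2
ethylbenzene	SMILES	CCc1ccccc1
ethylbenzene	InChI	InChI=1S/C8H10/c1-2-8-6-4-3-5-7-8/h3-7H,2H2,1H3
xylene	SMILES	Cc1ccccc1C
xylene	InChI	InChI=1S/C8H10/c1-7-5-3-4-6-8(7)2/h3-6H,1-2H3
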