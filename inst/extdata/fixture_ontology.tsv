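melting point	FIX:0000001
boiling point	FIX:0000002
infrared spectroscopy	FIX:0000011
mass spectrometry	FIX:0000012
nuclear magnetic resonance	FIX:0000013
x-ray diffraction	FIX:0000014
chromatography	FIX:0000015
distillation	FIX:0000016
crystallisation	FIX:0000017
crystallization	FIX:0000017
titration	FIX:0000018
electrophoresis	FIX:0000019
spectroscopy	FIX:0000020
solvent	CHEBI:46787
acid	CHEBI:37527
base	CHEBI:22695
salt	CHEBI:24866
ion	CHEBI:24870
cation	CHEBI:36916
anion	CHEBI:22563
molecule	CHEBI:25367
polymer	CHEBI:60027
monomer	CHEBI:77632
catalyst	CHEBI:35223
inhibitor	CHEBI:35222
ligand	CHEBI:52214
metal	CHEBI:33521
alkali metal	CHEBI:22314
alkaline earth metal	CHEBI:22315
halogen	CHEBI:47905
noble gas	CHEBI:33310
hydrocarbon	CHEBI:24632
aromatic compound	CHEBI:33655
heterocyclic compound	CHEBI:5686
organic compound	CHEBI:50860
inorganic compound	CHEBI:24835
alcohol	CHEBI:30879
aldehyde	CHEBI:17478
ketone	CHEBI:17087
carboxylic acid	CHEBI:33575
ester	CHEBI:35701
ether	CHEBI:25698
amine	CHEBI:32952
amide	CHEBI:32988
nitrile	CHEBI:18379
alkane	CHEBI:18310
alkene	CHEBI:32878
alkyne	CHEBI:33644
arene	CHEBI:33655
amino acid	CHEBI:33709
peptide	CHEBI:16670
protein	CHEBI:36080
carbohydrate	CHEBI:16646
lipid	CHEBI:18059
nucleic acid	CHEBI:33696
nucleotide	CHEBI:36976
steroid	CHEBI:35341
alkaloid	CHEBI:22315b
terpene	CHEBI:35186
flavonoid	CHEBI:47916
oxidation	REX:0000001
reduction	REX:0000002
hydrolysis	REX:0000003
condensation	REX:0000004
substitution	REX:0000005
elimination	REX:0000006
addition	REX:0000007
polymerisation	REX:0000008
polymerization	REX:0000008
isomerisation	REX:0000009
isomerization	REX:0000009
methylation	REX:0000010
acetylation	REX:0000011
halogenation	REX:0000012
nitration	REX:0000013
sulfonation	REX:0000014
esterification	REX:0000015
saponification	REX:0000016
dehydration	REX:0000017
hydrogenation	REX:0000018
dehydrogenation	REX:0000019
carboxylation	REX:0000020
decarboxylation	REX:0000021
phosphorylation	REX:0000022
cycloaddition	REX:0000023
rearrangement	REX:0000024
solvolysis	REX:0000025
photolysis	REX:0000026
pyrolysis	REX:0000027
electrolysis	REX:0000028
fermentation	REX:0000029
combustion	REX:0000030
precipitation	REX:0000031
sublimation	REX:0000032
evaporation	REX:0000033
ethyl acetate	CHEBI:27750
benzene	CHEBI:16716
toluene	CHEBI:17578
methanol	CHEBI:17790
ethanol	CHEBI:16236
acetone	CHEBI:15347
functional group	CHEBI:24433
reaction mixture	REX:0000034
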