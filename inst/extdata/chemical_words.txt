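benzene
toluene
xylene
phenol
aniline
pyridine
ethanol
methanol
propanol
butanol
glycerol
acetone
acetate
acetic
acetyl
methyl
ethyl
propyl
butyl
pentyl
hexyl
phenyl
benzyl
vinyl
allyl
formyl
carbonyl
hydroxyl
amino
nitro
chloro
bromo
fluoro
iodo
methane
ethane
propane
butane
pentane
hexane
heptane
octane
cyclohexane
ethylene
propene
butene
styrene
acetylene
benzaldehyde
formaldehyde
acetaldehyde
chloroform
dichloromethane
tetrahydrofuran
acetonitrile
naphthalene
anthracene
anisole
nitrobenzene
chlorobenzene
bromobenzene
ethylbenzene
sulfate
sulfide
sulfoxide
sulfone
nitrate
nitrite
chloride
bromide
fluoride
iodide
oxide
peroxide
hydroxide
carbonate
bicarbonate
phosphate
ammonium
sodium
potassium
calcium
magnesium
lithium
titanium
palladium
platinum
benzoate
benzoic
salicylic
citric
tartaric
oxalic
formic
lactic
malic
stearic
oleic
glucose
fructose
sucrose
urea
ammonia
hydrazine
imidazole
indole
furan
thiophene
pyrrole
quinoline
morpholine
piperidine
pyrimidine
purine
adenine
guanine
cytosine
thymine
alanine
glycine
serine
cysteine
leucine
valine
butanone
pentanone
hexanol
heptanol
octanol
glycol
ether
ketone
aldehyde
amide
amine
imine
nitrile
ester
lactone
lactam
epoxide
silane
borane
stannane
ferrocene
toluidine
cresol
catechol
resorcinol
hydroquinone
benzophenone
acetophenone
dimethylformamide
dimethylsulfoxide
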