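name,formula
glycine,C2H5NO2
acetate,C2H4O2
glycolate,C2H4O3
ethanolamine,C2H7NO
oxalate,C2H2O4
alanine,C3H7NO2
serine,C3H7NO3
lactate,C3H6O3
pyruvate,C3H4O3
glycerol,C3H8O3
aspartate,C4H7NO4
threonine,C4H9NO3
asparagine,C4H8N2O3
succinate,C4H6O4
fumarate,C4H4O4
malate,C4H6O5
4-aminobutanoate,C4H9NO2
uracil,C4H4N2O2
cytosine,C4H5N3O
erythritol,C4H10O4
glutamate,C5H9NO4
glutamine,C5H10N2O3
proline,C5H9NO2
valine,C5H11NO2
ornithine,C5H12N2O2
adenine,C5H5N5
guanine,C5H5N5O
thymine,C5H6N2O2
ribose,C5H10O5
2-oxoglutarate,C5H6O5
4-guanidinobutanoate,C5H11N3O2
xylitol,C5H12O5
leucine,C6H13NO2
isoleucine,C6H13NO2
lysine,C6H14N2O2
histidine,C6H9N3O2
arginine,C6H14N4O2
glucose,C6H12O6
citrate,C6H8O7
ascorbate,C6H8O6
pipecolate,C6H11NO2
nicotinate,C6H5NO2
mannitol,C6H14O6
citrulline,C6H13N3O3
2-aminobenzoate,C7H7NO2
benzoate,C7H6O2
salicylate,C7H6O3
sedoheptulose,C7H14O7
pimelate,C7H12O4
N-acetylglutamate,C7H11NO5
3-methylhistidine,C7H11N3O2
octanoate,C8H16O2
phenylacetate,C8H8O2
phenylalanine,C9H11NO2
tyrosine,C9H11NO3
hippurate,C9H9NO3
pantothenate,C9H17NO5
nonanoate,C9H18O2
uridine,C9H12N2O6
cytidine,C9H13N3O5
4-hydroxyphenylpyruvate,C9H8O4
adenosine,C10H13N5O4
guanosine,C10H13N5O5
inosine,C10H12N4O5
decanoate,C10H20O2
kynurenine,C10H12N2O3
Val-Glu,C10H18N2O5
tryptophan,C11H12N2O2
5-hydroxytryptophan,C11H12N2O3
cyclo(Leu-Pro),C11H18N2O2
Leu-Gln,C11H21N3O4
sucrose,C12H22O11
trehalose,C12H22O11
Leu-Leu,C12H24N2O3
laurate,C12H24O2
N-acetyltryptophan,C13H14N2O3
tridecanoate,C13H26O2
Phe-Pro,C14H18N2O3
myristate,C14H28O2
cyclo(Phe-Leu),C15H20N2O2
Phe-Leu,C15H22N2O3
cyclo(dehydroPhe-Leu),C15H18N2O2
pentadecanoate,C15H30O2
palmitate,C16H32O2
N-methyl-cyclo(Phe-Leu),C16H22N2O2
unknown-C16,C16H24N4O7
riboflavin,C17H20N4O6
Phe-Leu-Gly,C17H25N3O4
heptadecanoate,C17H34O2
cyclo(Phe-Phe),C18H18N2O2
Phe-Phe,C18H20N2O3
cyclo(Phe-Tyr),C18H18N2O3
stearate,C18H36O2
linoleate,C18H32O2
oleate,C18H34O2
maltotriose,C18H32O16
dimethyl-cyclo(dehydroPhe-dehydroTyr),C19H18N2O3
folate,C19H19N7O6
nonadecanoate,C19H38O2
Phe-Phe-Gly,C20H23N3O4
arachidonate,C20H32O2
Phe-Phe-Ala,C21H25N3O4
docosanoate,C22H44O2
Leu-Leu-Leu-Leu,C24H46N4O5
desferrioxamine-like,C25H48N6O8
glycocholate,C26H43NO6
Phe-Phe-Phe,C27H29N3O4
Phe-Phe-Phe-Gly,C29H32N4O5
triterpenoid-like,C30H52O2
peptide-like-C32,C32H58N4O8
depsipeptide-like-C33,C33H40N2O9
lipopeptide-like-C34,C34H63N5O6
Leu-hexapeptide,C36H68N6O7
macrolide-like-C36,C36H60O8
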