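name,formula,adducts,pathway_position
leucine,C6H13NO2,[M+H]+,precursor
phenylalanine,C9H11NO2,[M+H]+,precursor
tyrosine,C9H11NO3,[M+H]+,precursor
cyclo(Phe-Leu),C15H20N2O2,[M+H]+,early DKP
cyclo(dehydroPhe-Leu),C15H18N2O2,[M+H]+,late DKP
N-methyl-cyclo(Phe-Leu),C16H22N2O2,[M+H]+,late DKP
cyclo(Phe-Phe),C18H18N2O2,[M+H]+,early DKP
cyclo(Phe-Tyr),C18H18N2O3,[M+H]+,early DKP
dimethyl-cyclo(dehydroPhe-dehydroTyr),C19H18N2O3,[M+H]+,late DKP
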