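name,formula,mass_difference,category,description
H2,H2,2.0156501,biotic,hydrogenation / dehydrogenation
CH2,CH2,14.0156501,biotic,methylation / demethylation
NH,NH,15.0108990,biotic,imine amination
O,O,15.9949146,abiotic,oxygenation / hydroxylation
NH3,NH3,17.0265491,biotic,amination / deamination
H2O,H2O,18.0105647,abiotic,hydration / condensation
C2H2,C2H2,26.0156501,abiotic,acetylene addition
HCN,HCN,27.0108990,abiotic,hydrogen cyanide addition
CO,CO,27.9949146,abiotic,carbonylation / decarbonylation
C2H4,C2H4,28.0313001,biotic,ethylation
CH2O,CH2O,30.0105647,biotic,hydroxymethylation (formaldehyde)
CH4O,CH4O,32.0262147,biotic,methanol addition
C2H2O,C2H2O,42.0105647,biotic,acetylation (ketene)
CO2,CO2,43.9898292,biotic,carboxylation / decarboxylation
C2H4O,C2H4O,44.0262147,biotic,acetaldehyde addition
CH2O2,CH2O2,46.0054793,abiotic,formic acid addition
C3H4O,C3H4O,56.0262147,abiotic,acrolein addition
glycine,C2H3NO,57.0214637,biotic,glycine residue gain / loss
C2H4O2,C2H4O2,60.0211294,biotic,glycolate / acetic acid
alanine,C3H5NO,71.0371138,biotic,alanine residue gain / loss
SO3,SO3,79.9568146,biotic,sulfonation / desulfonation
HPO3,HPO3,79.9663304,biotic,phosphorylation / dephosphorylation
serine,C3H5NO2,87.0320284,biotic,serine residue gain / loss
C3H4O3,C3H4O3,88.0160440,biotic,pyruvate addition
cysteine,C3H5NOS,103.0091845,biotic,cysteine residue gain / loss
aspartate,C4H5NO3,115.0269430,biotic,aspartate residue gain / loss
C5H8O4,C5H8O4,132.0422587,biotic,pentose (glycosylation)
C6H10O5,C6H10O5,162.0528234,biotic,hexose (glycosylation)
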