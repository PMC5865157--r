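name,formula,chem_class,carbon_count,reference_ri,proton_affinity,aromatic_substituted
propanal,C3H6O,aldehyde_saturated,3,489,786,FALSE
acetone,C3H6O,ketone,3,498,812,FALSE
propenal,C3H4O,aldehyde_unsaturated,3,470,,FALSE
butanal,C4H8O,aldehyde_saturated,4,576,793,FALSE
heptanal,C7H14O,aldehyde_saturated,7,944,,FALSE
2-hexenal,C6H10O,aldehyde_unsaturated,6,892,,FALSE
2-butanone,C4H8O,ketone,4,625,827,FALSE
acetic acid,C2H4O2,acid,2,675,784,FALSE
butanoic acid,C4H8O2,acid,4,863,,FALSE
hexanoic acid,C6H12O2,acid,6,1060,,FALSE
ethanol,C2H6O,alcohol_primary,2,450,776,FALSE
1-butanol,C4H10O,alcohol_primary,4,712,789,FALSE
phenol,C6H6O,phenol,6,1023,817,FALSE
4-methylphenol,C7H8O,phenol,7,1120,,TRUE
2-ethylphenol,C8H10O,phenol,8,1286,,TRUE
4-ethylphenol,C8H10O,phenol,8,1323,,TRUE
benzaldehyde,C7H6O,aromatic,7,982,834,TRUE
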