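id,common_name,iupac_name,compound_class,r1,r2,r3,n_oh,n_och3,has_catechol
P,protocatechuic acid,"3,4-dihydroxybenzoic acid",hydroxybenzoic,OH,OH,H,2,0,TRUE
Ge,gentisic acid,"2,5-dihydroxybenzoic acid",hydroxybenzoic,OH,H,OH,2,0,FALSE
G,gallic acid,"3,4,5-trihydroxybenzoic acid",hydroxybenzoic,OH,OH,OH,3,0,TRUE
V,vanillic acid,4-hydroxy-3-methoxybenzoic acid,hydroxybenzoic,OCH3,OH,H,1,1,FALSE
Sy,syringic acid,"4-hydroxy-3,5-dimethoxybenzoic acid",hydroxybenzoic,OCH3,OH,OCH3,1,2,FALSE
pC,p-coumaric acid,4-hydroxycinnamic acid,hydroxycinnamic,H,OH,H,1,0,FALSE
C,caffeic acid,"3,4-dihydroxycinnamic acid",hydroxycinnamic,OH,OH,H,2,0,TRUE
F,ferulic acid,4-hydroxy-3-methoxycinnamic acid,hydroxycinnamic,OCH3,OH,H,1,1,FALSE
Si,sinapic acid,"4-hydroxy-3,5-dimethoxycinnamic acid",hydroxycinnamic,OCH3,OH,OCH3,1,2,FALSE
R,rosmarinic acid,"3,4-dihydroxycinnamic acid (R)-1-carboxy-2-(3,4-dihydroxyphenyl)ethyl ester",caffeic_ester,,,,4,0,TRUE
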