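trait,pve_NL,nsnp_NL,pve_UK,nsnp_UK
clutch_size,0.141,169,0.646,310
egg_mass,NA,NA,0.720,309
fledgling_weight_offspring,0.034,31,0.086,60
adult_weight,0.394,163,0.279,288
fledgling_weight_individual,0.581,241,0.312,245
tarsus_length,0.196,243,0.354,269
wing_length,0.131,238,0.350,297
exploratory_behaviour,0.157,94,0.162,200
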