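name,value,provenance
dead_space_ET_cm3,50,"ICRP 66 reference adult male extrathoracic dead space"
dead_space_BB_cm3,49,"ICRP 66 reference adult male bronchial dead space"
dead_space_bb_cm3,47,"ICRP 66 reference adult male bronchiolar dead space"
mean_free_path_um,0.0712,"air mean free path at body conditions, for the Cunningham slip correction"
air_viscosity_poise,0.00019,"dynamic viscosity of air at 37 C"
body_temperature_K,310,"body temperature for the Stokes-Einstein diffusion coefficient"
default_density_g_cm3,3,"ICRP 66 default particle material density"
default_shape_factor,1.5,"ICRP 66 default dynamic shape factor"
inhalability_a,0.00076,"inhalable fraction 1 - 0.5(1 - 1/(a d_ae^p + 1)), ICRP 66 inhalability"
inhalability_p,2.8,"inhalable fraction exponent, ICRP 66 inhalability"
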