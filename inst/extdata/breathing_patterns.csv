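activity,ventilation_m3_h,freq_per_min,tidal_L,fn,provenance
sitting,0.54,12,0.75,1,"ICRP 66 reference adult male, sitting; nose breather Fn = 1"
light_exercise,1.5,20,1.25,1,"ICRP 66 reference adult male, light exercise; nose breather Fn = 1"
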