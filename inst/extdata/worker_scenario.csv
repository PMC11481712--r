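activity,air_fraction,provenance
sitting,0.140625,"ICRP 66 reference worker: 2.5 h sitting x 0.54 m3/h = 1.35 m3 of 9.6 m3 shift"
light_exercise,0.859375,"ICRP 66 reference worker: 5.5 h light exercise x 1.5 m3/h = 8.25 m3 of 9.6 m3 shift"
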