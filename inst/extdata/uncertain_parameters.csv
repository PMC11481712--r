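name,family,p1,p2,p3,binding,provenance
Fn,triangular,0.4,1,1,fn,"fraction of air inhaled through the nose; triangular min 0.4, mode 1, max 1"
Cae_ET1,lognormal,1,1.82,NA,cae.ET1,"aerodynamic efficiency multiplier, ET1; lognormal GM 1, GSD 1.82"
Cae_ET2,lognormal,1,1.82,NA,cae.ET2,"aerodynamic efficiency multiplier, ET2; lognormal GM 1, GSD 1.82"
Cae_BB,lognormal,1,1.58,NA,cae.BB,"aerodynamic efficiency multiplier, BB; lognormal GM 1, GSD 1.58"
Cae_bb,lognormal,1,1.58,NA,cae.bb,"aerodynamic efficiency multiplier, bb; lognormal GM 1, GSD 1.58"
Cae_AI,lognormal,1,1.3,NA,cae.AI,"aerodynamic efficiency multiplier, AI; lognormal GM 1, GSD 1.3"
Cth_ET1,lognormal,1,1.18,NA,cth.ET1,"thermodynamic efficiency multiplier, ET1; lognormal GM 1, GSD 1.18"
Cth_ET2,lognormal,1,1.18,NA,cth.ET2,"thermodynamic efficiency multiplier, ET2; lognormal GM 1, GSD 1.18"
Cth_BB,lognormal,1,1.23,NA,cth.BB,"thermodynamic efficiency multiplier, BB; lognormal GM 1, GSD 1.23"
Cth_bb,lognormal,1,1.23,NA,cth.bb,"thermodynamic efficiency multiplier, bb; lognormal GM 1, GSD 1.23"
Cth_AI,lognormal,1,1.23,NA,cth.AI,"thermodynamic efficiency multiplier, AI; lognormal GM 1, GSD 1.23"
fd_ETseq,lognormal,0.002,1.73,NA,fd.ETseq,"sequestered fraction of the ET2 deposit; lognormal GM 0.002, GSD 1.73"
fd_BBseq,lognormal,0.002,1.73,NA,fd.BBseq,"sequestered fraction of the BB deposit; lognormal GM 0.002, GSD 1.73"
fd_bbseq,lognormal,0.002,1.73,NA,fd.bbseq,"sequestered fraction of the bb deposit; lognormal GM 0.002, GSD 1.73"
L_ALV_INT,lognormal,0.001,4.5,NA,rate.alv_int,"mechanical clearance ALV to INT; lognormal median 0.001 /d, GSD 4.5"
L_ALV_bb,lognormal,0.002,3.2,NA,rate.alv_bb,"mechanical clearance ALV to bbprime; lognormal median 0.002 /d, GSD 3.2"
L_INT_LNTH,lognormal,0.00003,3,NA,rate.int_lnth,"mechanical clearance INT to LNTH; lognormal median 0.00003 /d, GSD 3"
K_factor,lognormal,1,1.73,NA,kpt,"scale factor on the eight correlated particle-transport rates; lognormal median 1, GSD 1.73"
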