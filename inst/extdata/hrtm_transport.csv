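source,destination,rate_per_day,kpt_scaled,provenance
ET1,Environment,0.6,TRUE,"ICRP 130 fig 3.4 particle transport rates"
ET1,ET2prime,1.5,TRUE,"ICRP 130 fig 3.4 particle transport rates"
ETseq,LNET,0.001,TRUE,"ICRP 130 fig 3.4 particle transport rates"
ET2prime,Oesophagus,100,TRUE,"ICRP 130 fig 3.4 particle transport rates"
BBprime,ET2prime,10,TRUE,"ICRP 130 fig 3.4 particle transport rates"
BBseq,LNTH,0.001,TRUE,"ICRP 130 fig 3.4 particle transport rates"
bbprime,BBprime,0.2,TRUE,"ICRP 130 fig 3.4 particle transport rates"
bbseq,LNTH,0.001,TRUE,"ICRP 130 fig 3.4 particle transport rates"
ALV,bbprime,0.002,FALSE,"ICRP 130 fig 3.4; reference rate, uncertain parameter L_ALV_bb (median 0.002 /d)"
ALV,INT,0.001,FALSE,"ICRP 130 fig 3.4; reference rate, uncertain parameter L_ALV_INT (median 0.001 /d)"
INT,LNTH,0.00003,FALSE,"ICRP 130 fig 3.4; reference rate, uncertain parameter L_INT_LNTH (median 0.00003 /d)"
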