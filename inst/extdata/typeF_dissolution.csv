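source,destination,rate_per_day,kpt_scaled,provenance
ETseq,Blood,30,FALSE,"ICRP 130 default Type F dissolution s_r = 30 /d, all absorbed to blood"
ET2prime,Blood,30,FALSE,"ICRP 130 default Type F dissolution s_r = 30 /d"
BBprime,Blood,30,FALSE,"ICRP 130 default Type F dissolution s_r = 30 /d"
BBseq,Blood,30,FALSE,"ICRP 130 default Type F dissolution s_r = 30 /d"
bbprime,Blood,30,FALSE,"ICRP 130 default Type F dissolution s_r = 30 /d"
bbseq,Blood,30,FALSE,"ICRP 130 default Type F dissolution s_r = 30 /d"
ALV,Blood,30,FALSE,"ICRP 130 default Type F dissolution s_r = 30 /d"
INT,Blood,30,FALSE,"ICRP 130 default Type F dissolution s_r = 30 /d"
LNET,Blood,30,FALSE,"ICRP 130 default Type F dissolution s_r = 30 /d (lymph-node deposit dissolves at the same rate)"
LNTH,Blood,30,FALSE,"ICRP 130 default Type F dissolution s_r = 30 /d (lymph-node deposit dissolves at the same rate)"
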