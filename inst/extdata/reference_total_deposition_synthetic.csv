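amad_um,region,fraction,provenance
1,ET1,0.165,"ICRP-published reference-worker regional deposition, AMAD 1 um; transcribed anchor used for constant calibration"
1,ET2,0.211,"ICRP-published reference-worker regional deposition, AMAD 1 um; transcribed anchor"
1,BB,0.012,"ICRP-published reference-worker regional deposition, AMAD 1 um; transcribed anchor"
1,bb,0.017,"ICRP-published reference-worker regional deposition, AMAD 1 um; transcribed anchor"
1,AI,0.107,"ICRP-published reference-worker regional deposition, AMAD 1 um; transcribed anchor"
5,ET1,0.339,"ICRP-published reference-worker regional deposition, AMAD 5 um; transcribed anchor"
5,ET2,0.399,"ICRP-published reference-worker regional deposition, AMAD 5 um; transcribed anchor"
5,BB,0.018,"ICRP-published reference-worker regional deposition, AMAD 5 um; transcribed anchor"
5,bb,0.011,"ICRP-published reference-worker regional deposition, AMAD 5 um; transcribed anchor"
5,AI,0.053,"ICRP-published reference-worker regional deposition, AMAD 5 um; transcribed anchor"
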