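source,destination,rate_per_day,kpt_scaled,provenance
Oesophagus,Gut,720,FALSE,"lumped alimentary link; fast oesophageal transit (~2 min), full HATM out of scope"
Gut,Blood,5.94,FALSE,"lumped gut transit 6 /d x iodine gut absorption fraction f_A = 0.99 (ICRP 137 iodine)"
Gut,Excreta,0.06,FALSE,"lumped gut transit 6 /d x (1 - f_A), unabsorbed fraction to faecal excreta"
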