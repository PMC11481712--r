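compartment,source_region,provenance
ET1,ET1,"anterior nasal passage source region"
ETseq,ET2,"sequestered extrathoracic deposit assigned to the posterior extrathoracic source"
ET2prime,ET2,"posterior extrathoracic airways source region"
BBprime,BB,"bronchial source region"
BBseq,BB,"bronchial source region (sequestered)"
bbprime,bb,"bronchiolar source region"
bbseq,bb,"bronchiolar source region (sequestered)"
ALV,AI,"alveolar-interstitial source region"
INT,AI,"alveolar-interstitial source region (interstitium)"
LNET,LNET,"extrathoracic lymph nodes"
LNTH,LNTH,"thoracic lymph nodes"
Oesophagus,GIcontents,"alimentary-tract contents source"
Gut,GIcontents,"alimentary-tract contents source"
Blood,Blood,"circulating activity"
Thyroid,Thyroid,"thyroid"
RestOfBody,Other,"distributed organic iodine"
UBcontents,UBcontents,"urinary bladder contents"
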