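source,destination,rate_per_day,kpt_scaled,provenance
Blood,Thyroid,0.831776,FALSE,"classical ICRP iodine recycling model: 30% thyroid uptake, blood iodide T1/2 = 0.25 d (0.3 x ln2/0.25); documented reconstruction"
Blood,UBcontents,1.940812,FALSE,"classical ICRP iodine recycling model: 70% renal clearance, blood iodide T1/2 = 0.25 d (0.7 x ln2/0.25); documented reconstruction"
Thyroid,RestOfBody,0.008664,FALSE,"thyroid organic iodine T1/2 = 80 d (ln2/80); documented reconstruction"
RestOfBody,Blood,0.046210,FALSE,"organic body iodine T1/2 = 12 d, 80% recycled to blood iodide (0.8 x ln2/12); documented reconstruction"
RestOfBody,Excreta,0.011552,FALSE,"organic body iodine T1/2 = 12 d, 20% to faecal excretion (0.2 x ln2/12); documented reconstruction"
UBcontents,Excreta,12,FALSE,"urinary bladder voiding, 12 /d; documented reconstruction"
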