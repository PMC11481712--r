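region,component,path,a,p,provenance
ET1,ae,nose,1.49582e-05,1.00745,"reconstructed impaction constant, argument d_ae^2 Q (um^2 cm3/s); calibrated to ICRP regional anchors"
ET1,th,nose,404.638,1,"reconstructed diffusion constant, argument sqrt(D t) (cm); calibrated to ICRP regional anchors"
ET2,ae,nose,3.42915e-05,1.12506,"reconstructed impaction constant; calibrated to ICRP regional anchors"
ET2,th,nose,154.940,1,"reconstructed diffusion constant; calibrated to ICRP regional anchors"
ET2,ae,mouth,1.71458e-05,1.12506,"reconstructed impaction constant, mouth path (half the nasal constant); not benchmarked (reference worker is a nose breather)"
ET2,th,mouth,77.4699,1,"reconstructed diffusion constant, mouth path; not benchmarked"
BB,ae,any,3.30161e-07,1.39900,"reconstructed impaction constant; calibrated to ICRP regional anchors"
BB,th,any,8.49098e-08,1,"reconstructed diffusion constant; calibration drove this near zero (bronchial diffusion unresolved by the anchors)"
bb,ae,any,5.69435e-02,1,"reconstructed settling constant, argument d_ae^2 t (um^2 s); calibrated to ICRP regional anchors"
bb,th,any,43.8876,1,"reconstructed diffusion constant; calibrated to ICRP regional anchors"
AI,ae,any,2.79338e-02,1,"reconstructed settling constant; calibrated to ICRP regional anchors"
AI,th,any,131.342,1,"reconstructed diffusion constant; calibrated to ICRP regional anchors"
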