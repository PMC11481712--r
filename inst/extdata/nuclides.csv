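nuclide,half_life_days,provenance
I-131,8.0252,"physical half-life of 131-I, 8.0252 d"
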