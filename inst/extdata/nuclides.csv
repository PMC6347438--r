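# Physical half-lives of packaged radionuclides.
# F-18: 109.77 min (NNDC/NUDAT nuclear data); Tc-99m: 6.01 h = 360.6 min.
name,half_life_minutes
F-18,109.77
Tc-99m,360.6
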