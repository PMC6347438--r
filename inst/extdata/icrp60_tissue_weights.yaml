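# Tissue weighting factors w_T transcribed from ICRP Publication 60 (1990),
# as used for effective dose E = sum_T w_T * H_T. Weights sum to 1 including
# the remainder tissue; the remainder dose is the mean dose of the listed
# remainder organs (unweighted by default).
provenance: "ICRP Publication 60, Table 5.2 tissue weighting factors"
weights:
  gonads: 0.20
  colon: 0.12
  lung: 0.12
  red_marrow: 0.12
  stomach: 0.12
  bladder: 0.05
  breast: 0.05
  liver: 0.05
  oesophagus: 0.05
  thyroid: 0.05
  skin: 0.01
  bone_surface: 0.01
  remainder: 0.05
remainder_organs:
  - adrenals
  - brain
  - kidneys
  - muscle
  - pancreas
  - small_intestine
  - spleen
  - thymus
  - uterus
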