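# Radiation dose limits for research uses of radioactive drugs,
# transcribed from 21 CFR 361.1(b)(3) (values in mSv; 3/5 rem single,
# 5/15 rem annual). The restrictive class covers the whole body, active
# blood-forming organs, the lens of the eye, and the gonads.
restrictive:
  single_msv: 30
  annual_msv: 50
other:
  single_msv: 50
  annual_msv: 150
restrictive_organs:
  - whole_body
  - total_body
  - red_marrow
  - bone_marrow
  - blood_forming_organs
  - lens_of_eye
  - lens
  - gonads
  - testes
  - ovaries
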