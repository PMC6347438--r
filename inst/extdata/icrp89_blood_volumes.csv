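# Regional blood-volume distribution, reference adult male, transcribed from ICRP Publication 89 (Table 2.14; fractions of total blood volume).
# Hollow and vascular organs carry their blood in vessels and walls, so each entry is used as a wall/parenchyma source region.
# The unallocated remainder is assigned to rest_of_body by blood_pool_fractions().
organ,fraction
fat,0.050
brain,0.012
stomach,0.010
small_intestine,0.038
large_intestine,0.022
heart_chambers,0.090
heart_wall,0.010
kidneys,0.020
liver,0.100
lungs,0.125
muscle,0.140
pancreas,0.006
red_marrow,0.040
trabecular_bone,0.012
cortical_bone,0.008
skin,0.030
spleen,0.014
thyroid,0.0006
aorta_large_arteries,0.060
large_veins,0.180
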