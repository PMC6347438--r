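# Demonstration dose-calibrator series for one labeling run: washed cell
# fraction, original incubation supernatant, and three wash supernatants,
# all measured at the same clock time (minutes from tracer addition).
compartment,activity_mbq,t_min
cells,20.06,120
supernatant,12.24,120
wash_1,1.02,120
wash_2,0.68,120
wash_3,0.34,120
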