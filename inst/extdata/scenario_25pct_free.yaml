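# Scenario B: poor labeling with 25% of the dose lost as free tracer to
# urine, routed through a dynamic voiding bladder (first-order entry,
# periodic complete voiding).
retained_fraction: 0.75
excreted_fraction: 0.25
bladder_entry_halftime_min: 12
voiding_interval_h: 3.5
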