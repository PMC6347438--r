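# Scenario A: full in-vivo retention; the entire injected dose undergoes
# physical decay in the blood pool.
retained_fraction: 1.0
excreted_fraction: 0.0
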