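# Published adult effective-dose coefficients (mSv per MBq administered)
# used for total-dose and agent-comparison arithmetic.
# fdg_rbc: FDG-labeled erythrocytes, OLINDA/EXM 1.1 adult male, ICRP-60 weights.
# tc99m_rbc: Tc-99m-labeled erythrocytes, ICRP adult coefficient.
# fdg_iv: intravenous FDG, ICRP adult coefficient.
agent,msv_per_mbq
fdg_rbc,3.90E-02
tc99m_rbc,7.0E-03
fdg_iv,1.9E-02
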