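# Pure-population comparison: intact islets vs alpha-only (m_I = 0) vs
# beta-only (m_G = 0), steady-state secretion across glucose.
scenario: cell_elimination
glucose_mM: [1, 4, 7, 15, 30]
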