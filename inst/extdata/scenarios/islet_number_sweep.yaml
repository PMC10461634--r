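# Total 1-h secretion across islet counts and glucose steps from 1 mM,
# batch mode (use mode: perifusion for the flow-washed counterpart).
scenario: islet_number_sweep
mode: batch
glucose_mM: [1, 4, 7, 15, 30]
n_islets: [10, 100, 500]
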