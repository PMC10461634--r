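# A mouse 3 -> 12 mM glucose-step perifusion translated to the human
# glycemic set point (factor 0.6 -> 1.8 -> 7.2 mM) and run with 5000 islets
# to match the mouse experiment's insulin exposure.
scenario: mouse_equivalent_perifusion
n_islets: 5000
glucose_time_min: [0, 8]
glucose_mM: [3, 12]
species_factor: 0.6
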