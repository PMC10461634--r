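# Whole-pancreas steady state under basal inflow: ~1 dL of tissue, a million
# islets, perifused by the organ blood flow (1.3 mL/min/100 g x 90 g).
scenario: whole_pancreas
diabetic: false
volume_ml: 100
n_islets: 1000000
flow_ml_min: 1.17
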