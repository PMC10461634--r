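# Type 1 diabetes limit: beta-cell maximal secretion and basal insulin set
# to zero, so the insulin signal is off and alpha-cells run uninhibited.
scenario: whole_pancreas
diabetic: true
volume_ml: 100
n_islets: 1000000
flow_ml_min: 1.17
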