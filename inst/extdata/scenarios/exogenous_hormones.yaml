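# Perifusion with extra hormone in the inlet: raising insulin suppresses
# glucagon secretion; raising glucagon (hormone: glucagon) potentiates
# insulin, mostly at low glucose.
scenario: exogenous_hormones
hormone: insulin
inlet_pg_per_ml: [50, 500, 5000]
glucose_mM: [1, 4, 7, 15, 30]
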