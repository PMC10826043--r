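agent,dm,m,r,dose_unit,is_combination
acarbose,0.061,1.32,1.00,mM,FALSE
kaempferol,4.84,1.18,1.00,mM,FALSE
propolis,1.07,0.512,1.00,mg/mL,FALSE
acarbose+kaempferol,2.01,0.935,0.99,mM,TRUE
acarbose+propolis,0.274,0.443,0.99,mM+mg/mL,TRUE
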