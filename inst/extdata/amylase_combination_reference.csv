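pair,agent_a,agent_b,level,fa_obs,ci_printed,dose_a_printed,dose_b_printed,dri_a_printed,dri_b_printed
acarbose+propolis,acarbose,propolis,0.10,0.235,0.601,0.025,0.106,2.16,7.28
acarbose+propolis,acarbose,propolis,0.30,0.448,0.903,0.052,0.710,1.62,3.50
acarbose+propolis,acarbose,propolis,0.50,0.651,0.920,0.097,3.61,1.60,3.39
acarbose+propolis,acarbose,propolis,0.70,0.840,0.748,0.212,27.3,1.84,4.88
acarbose+propolis,acarbose,propolis,0.90,0.910,1.71,0.348,98.3,1.09,1.25
acarbose+kaempferol,acarbose,kaempferol,0.10,0.260,0.795,0.027,1.99,2.39,2.66
acarbose+kaempferol,acarbose,kaempferol,0.30,0.537,0.900,0.068,5.49,2.12,2.33
acarbose+kaempferol,acarbose,kaempferol,0.50,0.711,0.972,0.119,10.4,1.97,2.15
acarbose+kaempferol,acarbose,kaempferol,0.70,0.860,0.922,0.239,22.6,2.07,2.27
acarbose+kaempferol,acarbose,kaempferol,0.90,0.910,1.82,0.348,34.5,1.09,1.11
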