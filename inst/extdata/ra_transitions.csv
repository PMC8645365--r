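state,Remission,Low,Moderate,Severe,Death
Remission,0.500,0.310,0.119,0.070,0.001
Low,0.262,0.388,0.306,0.040,0.004
Moderate,0.070,0.217,0.550,0.155,0.008
Severe,0.020,0.040,0.307,0.621,0.012
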