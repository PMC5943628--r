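00	albuterol	12
01	asthma	9
10	tremor	7
11	severe	5
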