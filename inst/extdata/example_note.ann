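T1	Medication 13 22	Albuterol
T2	Dosage 23 30	2 puffs
T3	Frequency 36 41	q4-6h
T4	Indication 50 56	asthma
T5	Severity 79 85	severe
T6	ADE 86 92	tremor
R1	Dosage Arg1:T1 Arg2:T2
R2	Frequency Arg1:T1 Arg2:T3
R3	Indication Arg1:T1 Arg2:T4
R4	Adverse Arg1:T1 Arg2:T6
R5	Severity Arg1:T5 Arg2:T6
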