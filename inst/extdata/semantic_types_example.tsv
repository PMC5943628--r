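albuterol	bronchodilator
albuterol	pharmacologic_substance
asthma	disease_or_syndrome
tremor	sign_or_symptom
severe	qualitative_concept
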