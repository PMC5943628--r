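She receives Albuterol 2 puffs p.o. q4-6h for her asthma . She later developed severe tremor .
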