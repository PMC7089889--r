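case,FX,FY,FZ
LC1,101.19,-836.19,-29.20
LC2,-804.05,-1957.53,-141.95
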