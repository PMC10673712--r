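,Positive,Negative,NC
Positive,8,2,0
Negative,1,18,0
NC,0,0,2
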