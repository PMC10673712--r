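,Positive,Negative,NC
Positive,36,3,0
Negative,5,50,2
NC,1,8,4
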