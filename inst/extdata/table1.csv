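,Positive,Negative,NC
Positive,196,10,1
Negative,15,173,3
NC,17,23,11
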