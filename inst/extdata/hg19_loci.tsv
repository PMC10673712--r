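name	chrom	start	end
CCNE1	chr19	30302805	30315215
ERBB2	chr17	37844393	37884915
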