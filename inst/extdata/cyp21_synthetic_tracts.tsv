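start	end	label
624	634	intron2_tract
3080	3080	utr3_tract
3102	3186	utr3_tract
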