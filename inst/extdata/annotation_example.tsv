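start	end	label
27	144	ECD
145	175	TM1
176	190	ICL1
191	225	TM2
226	235	ECL1
236	270	TM3
271	285	ICL2
286	320	TM4
321	335	ECL2
336	370	TM5
371	380	ICL3
381	405	TM6
406	415	ECL3
416	440	TM7
441	460	CTR
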