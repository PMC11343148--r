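condition	replicate	slope	intercept_realized
Control	1	1	-2.003285325
Control	2	1	-1.789715046
Control	3	1	-1.897253915
Control	4	1	-1.641733622
Opto	1	1	-1.843956307
Opto	2	1	-2.135417172
Opto	3	1	-1.637375239
Opto	4	1	-1.61063678
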