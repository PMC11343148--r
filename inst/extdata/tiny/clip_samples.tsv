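sample	assay	condition	replicate
CLIP_Control_1	CLIP	Control	1
CLIP_Control_2	CLIP	Control	2
CLIP_Control_3	CLIP	Control	3
CLIP_Control_4	CLIP	Control	4
CLIP_Opto_1	CLIP	Opto	1
CLIP_Opto_2	CLIP	Opto	2
CLIP_Opto_3	CLIP	Opto	3
CLIP_Opto_4	CLIP	Opto	4
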