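sample	assay	condition	replicate
RiboIP_Control_1	RiboTag-IP	Control	1
RiboInput_Control_1	RiboTag-Input	Control	1
RiboIP_Control_2	RiboTag-IP	Control	2
RiboInput_Control_2	RiboTag-Input	Control	2
RiboIP_Control_3	RiboTag-IP	Control	3
RiboInput_Control_3	RiboTag-Input	Control	3
RiboIP_Opto_1	RiboTag-IP	Opto	1
RiboInput_Opto_1	RiboTag-Input	Opto	1
RiboIP_Opto_2	RiboTag-IP	Opto	2
RiboInput_Opto_2	RiboTag-Input	Opto	2
RiboIP_Opto_3	RiboTag-IP	Opto	3
RiboInput_Opto_3	RiboTag-Input	Opto	3
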