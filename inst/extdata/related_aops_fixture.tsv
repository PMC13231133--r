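aop_id	event_id	event_type	event_title	downstream_event_ids
AOP:443	MIE:112	MIE	antagonism, estrogen receptor	AO:1982
AOP:443	AO:1982	AO	metastatic breast cancer	
AOP:595	MIE:112	MIE	antagonism, estrogen receptor	AO:520
AOP:595	AO:520	AO	decreased sperm quantity	
AOP:429	KE:386	KE	decrease of neuronal network function	AO:1941
AOP:429	AO:1941	AO	memory loss	
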