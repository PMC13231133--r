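aop_id	event_id	event_type	event_title	downstream_event_ids
AOP:522	MIE:112	MIE	antagonism, estrogen receptor	KE:2207
AOP:522	KE:2207	KE	inhibition, ERK1/2 signaling pathway	KE:2208
AOP:522	KE:195	KE	inhibition, NMDARs	KE:2208
AOP:522	KE:2208	KE	aberrant, synaptic formation and plasticity	KE:386
AOP:522	KE:386	KE	decrease of neuronal network function	AO:2209
AOP:522	AO:2209	AO	autism-like behavior	
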