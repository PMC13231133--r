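event_id	term_kind	term	evidence_filter	term_name
MIE:112	gene	GENE:2099		ESR1
MIE:112	gene	GENE:2100		ESR2
MIE:112	phenotype	GO:0030520		intracellular estrogen receptor signaling pathway
MIE:112	phenotype	GO:0030284		nuclear estrogen receptor activity
KE:2207	gene	GENE:5594		MAPK1
KE:2207	gene	GENE:5595		MAPK3
KE:2207	phenotype	GO:0070371		ERK1 and ERK2 cascade
KE:2207	phenotype	GO:0004707		MAP kinase activity
KE:195	gene_pattern	GRIN*		glutamate ionotropic receptor NMDA-type genes
KE:195	phenotype	GO:0004972		NMDA glutamate receptor activity
KE:195	phenotype	GO:0017146		NMDA selective glutamate receptor complex
KE:195	phenotype	GO:0098989		NMDA selective glutamate receptor signaling pathway
KE:195	phenotype	GO:2000310		regulation of NMDA receptor activity
KE:2208	phenotype	GO:0045202		synapse
KE:2208	phenotype	GO:0007416		synapse assembly
KE:2208	phenotype	GO:0050808		synapse organization
KE:2208	phenotype	GO:0099536		synaptic signaling
KE:386	phenotype	GO:0007399		nervous system development
KE:386	phenotype	GO:0050877		nervous system process
AO:2209	disease	MESH:D000067877	marker_mechanism	Autism Spectrum Disorder
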