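# excerpt of the disease poly-hierarchy around the autism branch
id	name	parent_ids	tree_numbers
MESH:D000067877	Autism Spectrum Disorder		C10.228.140.079
MESH:D001321	Autistic Disorder	MESH:D000067877	C10.228.140.079.100
MESH:D020817	Asperger Syndrome	MESH:D000067877	C10.228.140.079.050
MESH:C538235	Adenylosuccinate lyase deficiency	MESH:D000067877	
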