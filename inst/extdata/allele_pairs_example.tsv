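gene_id	allele_id
g002	g002v
g006	g006v
g014	g014v
g018	g018v
g023	g023v
g024	g024v
g025	g025v
g032	g032v
g039	g039v
g040	g040v
g042	g042v
g044	g044v
g046	g046v
g048	g048v
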