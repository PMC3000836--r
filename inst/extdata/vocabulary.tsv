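organism	NCBITaxon:9606	Homo sapiens
organism	NCBITaxon:10090	Mus musculus
organism-part	UBERON:0000178	blood
organism-part	UBERON:0002371	bone marrow
organism-part	UBERON:0002106	spleen
cell-type	CL:0000451	dendritic cell
cell-type	CL:0000784	plasmacytoid dendritic cell
cell-type	CL:0000235	macrophage
cell-type	CL:0000576	monocyte
environment	CHEBI:16412	lipopolysaccharide stimulation
environment	CHEBI:133833	resiquimod stimulation
environment	CHEBI:134674	poly(I:C) stimulation
environment	ENV:unstimulated	unstimulated culture
experiment-type	OBI:0001463	transcription profiling by array
experiment-type	OBI:0000070	functional assay
experiment-type	OBI:0000916	flow cytometry assay
experiment-type	OBI:0000615	protein expression assay
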