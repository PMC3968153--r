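geneA	v1
geneA	v2
geneA	v3
geneA	v4
geneA	v5
geneA	v6
geneA	v7
geneA	v8
geneA	v9
geneA	v10
geneA	v11
geneA	v12
geneA	v13
geneB	v14
geneB	v15
geneB	v16
geneB	v17
geneB	v18
geneB	v19
geneB	v20
geneB	v21
geneB	v22
geneB	v23
geneB	v24
geneB	v25
geneB	vc1
geneB	vc2
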