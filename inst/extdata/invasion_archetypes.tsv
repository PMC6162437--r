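subtype	proliferation	crypt_base	mesenchymal	emt_activation	caf	stromal	invasive_front	central_tumor	epithelial
proliferative	1	1	-1	-1	-1	-1	-1	1	0
collective	1	0	-1	-1	-1	-1	-1	0	1
crypt_like	1	0	1	0	1	1	0	1	0
EMT	-1	0	1	1	1	1	0	-1	0
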