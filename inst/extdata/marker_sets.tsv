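subtype	genes
CD4_T	CD4,IL7R,CCR7,TCF7,CD3D,CD3E
CD8_T	CD8A,CD8B,GZMK,GZMB,NKG7,CD3D
Treg	FOXP3,IL2RA,CTLA4,IKZF2,TNFRSF4
NK_like	NCAM1,KLRD1,GNLY,NKG7,KLRF1,FCGR3A
Exhaustion	PDCD1,CTLA4,HAVCR2,LAG3,TIGIT,TOX
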