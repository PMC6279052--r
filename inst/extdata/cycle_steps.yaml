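antigen_presentation:
- B2M
- HLA-A
- HLA-B
apoptosis_resistance:
- BIRC3
- TNFAIP3
- TRAF1
- TNFRSF10D
- TNFRSF6B
cytotoxicity:
- GZMA
- GZMB
- PRF1
immunosuppression:
- IL10
- TGFB1
- TGFB2
t_cell_engagement:
- CD4
- CD8A
- CTLA4
- PDCD1
- CD274
- PDCD1LG2
- IFNG
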