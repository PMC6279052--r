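rules:
  M1:
    op: any_up
    genes:
    - IL10
    - TGFB1
    - TGFB2
  M2:
    op: or
    args:
    - op: any_up
      genes: CTLA4
    - op: and
      args:
      - op: any_up
        genes: PDCD1
      - op: any_up
        genes:
        - CD274
        - PDCD1LG2
    - op: any_up
      genes: IFNG
  M3:
    op: at_least_k_up
    genes:
    - BIRC3
    - TNFAIP3
    - TRAF1
    - TNFRSF10D
    k: 2
  M4:
    op: any_up
    genes: TNFRSF6B
  M5:
    op: and
    args:
    - op: any_not_up
      genes:
      - B2M
      - HLA-A
      - HLA-B
    - op: any_not_up
      genes:
      - CD4
      - CD8A
    - op: or
      args:
      - op: any_up
        genes:
        - GZMA
        - GZMB
        - PRF1
      - op: any_up
        genes: TGFB1
  M6:
    op: all_not_up
    genes:
    - B2M
    - HLA-A
    - HLA-B
    - CD4
    - CD8A
    - GZMA
    - GZMB
    - PRF1
    - TGFB1
synonyms:
  PD-1: PDCD1
  PD-L1: CD274
  PD-L2: PDCD1LG2
  DcR3: TNFRSF6B
  TRAILR4: TNFRSF10D
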