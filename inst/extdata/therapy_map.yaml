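M1: anti-TGF-beta1
M2:
  CTLA4: anti-CTLA4
  PD1: anti-PD-1
  IFNG: anti-IFN-gamma
M3: none listed
M4: anti-DcR3
M5: DC vaccine
M6: DC vaccine + chemotherapy
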