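# Sidecar configuration for the synthetic example amplicons.
# These sequences and the diagnostic table are SYNTHETIC examples of the
# file formats; replace them with your assay's amplicons and the
# subfamily diagnostic positions for real analyses.
amplicons:
  L1rep:
    primer_offset: 0
    notes: synthetic example of an L1 reporter 3'-end amplicon
  GAPDH:
    primer_offset: 10
    notes: synthetic example control amplicon
  PABPC4:
    primer_offset: 10
    notes: synthetic example control amplicon
  L1_3end:
    primer_offset: 0
    subfamily: L1-HS
    notes: synthetic consensus window carrying example subfamily diagnostics
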