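# Example murosearch pipeline configuration.
# stems may be given inline (stems:) or as a FASTA path (stems_fasta:).
stems:
  - AEm
  - AEmA
  - AEmG
max_units: 3
precursor_ppm: 5
hcd_ppm: 20
etd_da: 0.5
xic_ppm: 10
wildcard: false
merge_isd: true
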