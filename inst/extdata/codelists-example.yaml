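# Example code-list configuration.
# Each entry maps a source database's raw codes to CDISC submission values.
# kind: ct     -> targets a named controlled-terminology list (ct_name)
# kind: custom -> study-specific list (e.g. Oxford-classification scores)
codelists:
  - oid: CL.SEX
    kind: ct
    ct_name: SEX
    entries:
      "1": "M"
      "2": "F"
  - oid: CL.NY
    kind: ct
    ct_name: NY
    entries:
      "1": "Y"
      "0": "N"
  - oid: CL.OXM
    kind: custom
    entries:
      "0": "M0"
      "1": "M1"
  - oid: CL.OXT
    kind: custom
    entries:
      "0": "T0"
      "1": "T1"
      "2": "T2"
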