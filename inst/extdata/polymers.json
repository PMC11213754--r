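[
  {"name": "PE", "formula": "C2H4"},
  {"name": "PET", "formula": "C10H8O4"},
  {"name": "PCL", "formula": "C6H10O2"},
  {"name": "cellulose", "formula": "C6H10O5"}
]
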