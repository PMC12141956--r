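[
  {"DOID:1612": "breast cancer", "CHEBI:3387": "Carbamazepine"},
  {"DOID:2841": "asthma", "CHEBI:10110": "Zidovudine"},
  {"DOID:2487": "hypercholesterolemia", "CHEBI:5118": "Fluoxetine"}
]
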