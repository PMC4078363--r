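{
  "ra_prefixes": {
    "OHIP_DX": ["714"],
    "ICD9": ["714"],
    "ICD10": ["M05", "M06"]
  },
  "other_rheum_prefixes": {
    "OHIP_DX": ["715", "274", "725", "720", "710", "696", "727", "446", "447"],
    "ICD9": ["715", "274", "725", "720", "710", "696", "727", "446", "447"],
    "ICD10": ["M15", "M16", "M17", "M18", "M19", "M10", "M30", "M31", "M32", "M33", "M34", "M35", "M45", "M46", "M65", "M70", "M71", "L40"]
  },
  "msk_specialties": ["rheumatology", "orthopedic surgery", "internal medicine"],
  "drug_class_map": ["DMARD", "DMARD", "DMARD", "DMARD", "DMARD", "DMARD", "BIOLOGIC", "BIOLOGIC", "BIOLOGIC", "BIOLOGIC", "GLUCOCORTICOSTEROID", "GLUCOCORTICOSTEROID", "GLUCOCORTICOSTEROID", "NSAID_COXIB", "NSAID_COXIB", "NSAID_COXIB", "NSAID_COXIB"]
}
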