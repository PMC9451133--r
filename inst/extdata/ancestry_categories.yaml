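# Controlled vocabulary for sample ancestry, seeded from the GWAS Catalog
# standardized ancestry framework categories. Configurable: pass your own
# list to validate_metadata(ancestry_vocabulary=). Tokens outside the list
# are WARNING-level findings, not errors.
ancestry_categories:
  - African American or Afro-Caribbean
  - African unspecified
  - Asian unspecified
  - Central Asian
  - East Asian
  - European
  - Greater Middle Eastern (Middle Eastern, North African or Persian)
  - Hispanic or Latin American
  - Native American
  - Not reported
  - Oceanian
  - Other
  - Other admixed ancestry
  - South Asian
  - South East Asian
  - Sub-Saharan African
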