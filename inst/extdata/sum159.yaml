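# SUM159 breast-cancer cell line: luminal (L), basal (B), stem (S).
# Published growth/transition estimates read under the column convention
# recorded in table1_mapping.yaml.  Rates in 1/day.
labels: [L, B, S]
growth:
  L: 0.73
  B: 0.85
  S: 0.69
transitions:
  "L->B": 0.42
  "L->S": 0.04
  "B->S": 0.012
  "S->L": 0.14
  "S->B": 0.33
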