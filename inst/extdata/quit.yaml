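# Application: six-component web-based smoking-cessation intervention.
# Baseline: the implemented 16-run regular 2^(6-2) design (E=ABC, F=ACD).
# Proposal: a 12-run strength-2 orthogonal array from the Paley type-I
# Hadamard matrix of order 12 (q=11), first 6 columns.
name: quit
baseline:
  type: regular
  k: 4
  generators: E=ABC,F=ACD
proposal:
  type: paley1
  q: 11
  cols: 6
k_values: [3, 4]
expectations:
  runs:
    baseline: 16
    proposal: 12
  reduction_pct: 25
  strength:
    baseline: 3
    proposal: 2
  coverage:
    baseline:
      "3": 100
      "4": 80
    proposal:
      "3": 100
      "4": 100
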