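# Application: six-drug antiviral combination screening (HSV-1).
# Baseline: the resolution-VI 2^(6-1) regular design (F=ABCDE), 32 runs.
# Proposal: a 28-run strength-2 orthogonal array from the Paley type-II
# Hadamard matrix of order 28 (q=13), first 6 columns — four fewer runs.
name: hsv1
baseline:
  type: regular
  k: 5
  generators: F=ABCDE
proposal:
  type: paley2
  q: 13
  cols: 6
k_values: [3, 4]
expectations:
  runs:
    baseline: 32
    proposal: 28
  strength:
    baseline: 5
    proposal: 2
  coverage:
    baseline:
      "3": 100
      "4": 100
    proposal:
      "3": 100
      "4": 100
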