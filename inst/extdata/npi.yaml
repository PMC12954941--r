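# Application: 16 non-pharmaceutical influenza interventions (simulation).
# Baseline: a 2^(16-7) regular design, 512 runs. The original study's seven
# generators are unpublished; the words below are a documented
# reconstruction (seven distinct length-3 generator words over 9 base
# factors, giving defining words of even length >= 4, hence resolution IV:
# main effects clear of two-factor interactions). Self-checks pin only run
# counts and the 18% reduction, never the specific words.
# Proposal: a 420-run Paley type-I design (q=419), 16 factor columns.
name: npi
baseline:
  type: regular
  k: 9
  generators: J=ABC,K=ADE,L=AFG,M=BDH,N=BEI,O=CDI,P=CFH
proposal:
  type: paley1
  q: 419
  cols: 16
k_values: [4]
# full enumeration of C(16,4) = 1820 subsets per design is minutes-scale in
# interpreted code; coverage here is a fixed-seed sample (the guarantee
# tests in the package enumerate more aggressively)
sample_subsets:
  baseline: {seed: 11, size: 150}
  proposal: {seed: 11, size: 150}
expectations:
  runs:
    baseline: 512
    proposal: 420
  reduction_pct: 18
  strength:
    baseline: 3
    proposal: 2
  coverage:
    proposal:
      "4": 100
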