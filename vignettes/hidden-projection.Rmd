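---
title: "Hidden projection analysis of two-level screening designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hidden projection analysis of two-level screening designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiddenproj)
```

## The model and what the package decides

A two-level screening study observes a response at N runs, each run a
combination of n factors coded −1/+1. The working model at the screening
stage is main effects plus two-factor interactions (ME+2FI), with
higher-order interactions assumed negligible:

$$ y = \beta_0 + \sum_i \beta_i x_i + \sum_{i<j} \beta_{ij} x_i x_j + \varepsilon. $$

Interest usually narrows after the experiment to a subset S of m factors.
The ME+2FI model over S is estimable exactly when the N × p model matrix
`[1 | x_i, i ∈ S | x_i x_j, i<j ∈ S]`, p = 1 + m + m(m−1)/2, has full
column rank. The package's central statistic is **full-rank coverage**:
the percentage of the `choose(n, m)` subsets whose model matrix is full
rank. This is a property of the design alone — it needs no response data —
and it is what distinguishes design families:

* **Regular fractions** (`build_regular()`): a generator word like
  `E = ABC` makes the E column the elementwise product of A, B, C. The
  induced defining contrast subgroup (`defining_contrast_subgroup()`)
  determines everything: resolution = minimum word length, and two effect
  words are aliased (identical columns) exactly when their product lies in
  the subgroup. Aliasing is all-or-nothing.
* **Non-regular orthogonal-array designs** (`hadamard_to_oa()` applied to
  `paley_type1()`, `paley_type2()`, `sylvester()`): strength 2 guarantees
  pairwise balance; aliasing of interactions is partial, which is what
  rescues rank in projections.

A strength-t array has every t-column submatrix containing all 2^t level
combinations equally often; `verify_strength()` checks this exhaustively
(no sampling) and reports the maximal t with a concrete witness on
failure. Equal counts at level t force 2^t | N, which is why a 12-run
array cannot exceed strength 2 even in principle.

The run-size guarantees applied by `cheng_guarantee()` are the two
sufficient conditions used throughout: a strength-2 array with n ≥ 4 and
N ≢ 0 (mod 8) has every 4-factor projection estimable; a strength-3 array
with n ≥ 5 and N ≢ 0 (mod 16) every 5-factor projection. The package
treats these as predictions and re-verifies them by enumeration; the test
suite confirms 100% coverage at the guaranteed size for the 12-, 20- and
28-run arrays (fully enumerated) and the 420-run array (fixed-seed sample
of 200 subsets plus all subsets containing the first factor).

## Parameters that matter

| Parameter | Meaning | Default / constraint |
|---|---|---|
| `k` (base factors) | run count of a regular fraction is 2^k | any k ≥ 1 |
| generator words | defining relations, e.g. `E=ABC`; signed forms (`-ABC`) supported | unsigned assumed `+` |
| `q` (Paley) | odd prime; type I needs q ≡ 3 (mod 4), order q+1; type II needs q ≡ 1 (mod 4), order 2(q+1) | prime only, no prime powers |
| `n` / `cols` | factors kept from the q (or 2q+1) candidate columns | first n after dropping the all-ones column |
| `t` (strength) | balance level verified exhaustively | 2 for all Hadamard-derived designs here |
| `k_values` | projection sizes compared | case studies use 3, 4 |

Column selection from a Hadamard matrix is deliberately the simplest
deterministic rule — the first `n` columns after dropping the all-ones
column — because the run-size guarantee is column-choice invariant for
strength-2 arrays; an explicit `columns` argument exists for auditing other
selections, and the suite also exercises a non-contiguous choice.

Level coding is fixed: files in the 0/1 orthogonal-array-catalogue dialect
are recoded 0 → −1, 1 → +1 on read, and the internal canonical coding is
always −1/+1. Effect words are canonicalized as label sets in factor order
(`AB` ≡ `BA`); model-matrix columns are ordered intercept, main effects,
then interactions, each block in label order, so every report is
deterministic and diff-stable.

## Numerical choices

**Exact rank.** Coverage percentages like 80% = 12/15 must not depend on a
floating tolerance, so rank is computed over the rationals by Gaussian
elimination modulo several ~2^25 primes. Rank mod p never exceeds the
rational rank, and if every prime in the set under-reported, each would
divide a fixed nonzero maximal minor; the primes are chosen so their
product exceeds the Hadamard bound m^(m/2) on any minor of a ±1 matrix
with m = min(dim), which is impossible. The maximum over the prime set is
therefore the exact rank — deterministically, not probabilistically — and
all modular products stay below 2^51, exact in double arithmetic. (A
fraction-free Bareiss elimination was rejected: its intermediate minors can
exceed 2^53 for the larger model matrices, silently breaking exactness.)
A floating SVD rank with tolerance 1e-8 × σ_max is computed as an
independent cross-check; the acceptance suite asserts agreement on every
model matrix it touches. When p > N full rank is impossible; such
projections are reported as rank deficient rather than raising an error.

**Strength counting.** Level combinations are counted by exact integer
tabulation over every t-subset of columns; the N ∤ 2^t shortcut only
short-circuits scans that must fail, and the failure witness is still a
real count from the design.

**Ties and degenerate inputs.** Empty generator sets yield the full
factorial with resolution flagged `Inf`; the identity word prints as `I`;
an intercept column is named `(Intercept)` so a factor literally labelled
`I` (the 9th default label) cannot collide with it.

## The case studies and their reconstructions

Three shipped YAML configs (`inst/extdata/`) encode comparisons between an
implemented regular design and a proposed non-regular alternative:

* **quit** — 16-run 2^(6−2) with `E=ABC, F=ACD` (resolution IV) versus the
  12-run strength-2 array from the order-12 Paley type-I matrix (q = 11).
  Expected: coverage 100/80 versus 100/100 at k = 3/4, a 25% run
  reduction, and deficient subsets exactly {A,B,C,E}, {A,C,D,F},
  {B,D,E,F} — each the complement-free trace of one defining word.
* **hsv1** — 32-run resolution-VI 2^(6−1) (`F=ABCDE`) versus the 28-run
  array from the Paley type-II matrix (q = 13): four fewer runs, both
  strength-verified.
* **npi** — 512-run 2^(16−7) versus the 420-run Paley type-I design
  (q = 419): an 18% (rounded) run reduction. The original study's seven
  generator words are not public; the config ships a documented
  reconstruction (seven distinct length-3 generator words over nine base
  factors, so every defining word has even length ≥ 4 and the design is
  resolution IV, i.e. main effects clear of two-factor interactions). The
  self-checks pin only run counts and the reduction, never the specific
  words, because any such choice gives the same accounting.

The case-study runner re-derives every expectation from the constructed
designs at run time and exits nonzero on mismatch, so the configs are
executable claims, not documentation.

## What a green test does and does not establish

There is no synthetic response data here: all statements are combinatorial
properties of design matrices, recomputed exhaustively (or, for the
420-run design's 1820 four-factor subsets, on a fixed-seed sample where
noted). A passing suite establishes estimability — no ME or 2FI is a
perfect linear combination of the others in the covered projections. It
does **not** establish statistical power, robustness to heterogeneous
units, or anything about three-factor interactions, which the screening
model assumes negligible. Strength 2 balances pairs, not triples; a
strength-2 array can and does have unbalanced 3-column projections while
still passing every rank test.

## Known limitations

* Prime `q` only in the Paley constructions; GF(p^k) arithmetic is out of
  scope since no shipped run size needs it. Composite or wrong-residue `q`
  raises an error naming the failed condition.
* Factors have exactly two levels; no blocking, no mixed-level arrays.
* No optimality search (minimum aberration, generalized resolution): the
  package compares fixed, named designs.
* Full enumeration of `projection_coverage()` is O(choose(n, k)) exact
  rank computations; for n = 16, k ≥ 4 callers should pass a `subsets`
  sample, as the npi config does.
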