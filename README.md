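# hiddenproj

Two-level screening designs for multi-factor studies — regular fractional
factorials, non-regular orthogonal-array (Hadamard/Paley) designs, and the
hidden-projection analysis that decides between them.

## The problem

Screening studies in public health, behavioral intervention research, and
drug-combination trials often start with many candidate factors (message
framing, personalization depth, individual drugs, policy levers, ...), each
tested at two levels coded −1/+1. A full factorial with *n* factors needs
2^*n*
runs; practical studies use fractions. The classical choice is a **regular
fractional factorial** 2^(n−g), defined by generator words such as
`E = ABC`: cheap and tidy, but every pair of effects is either orthogonal
or *completely aliased*. If analysis later narrows to a subset of factors,
a regular design can leave a two-factor interaction perfectly confounded
with a main effect — the two model columns are identical, and no amount of
data separates them.

**Non-regular designs** taken from orthogonal arrays avoid this rigidity.
An orthogonal array OA(N, 2^n, t) is an N×n ±1 matrix in which every
*t*-column submatrix contains all 2^t level combinations equally often.
Strength-2 arrays derived from Hadamard matrices exist at run sizes (12,
20, 28, ...) unavailable to regular designs, and they enjoy a **hidden
projection property**: for suitable N, *every* k-factor projection supports
estimation of all main effects and two-factor interactions (2FIs). The
operational criterion is full column rank of the N × (1 + m + m(m−1)/2)
model matrix `[1 | main effects | 2FIs]` over each m-factor subset; the
package reports the percentage of subsets achieving it ("full-rank
coverage"). A sufficient condition: a strength-2 array with n ≥ 4 whose run
count N is *not* a multiple of 8 has 100% coverage at k = 4 (and a
strength-3 array with N not a multiple of 16 at k = 5).

Rank is computed **exactly over the integers** (modular elimination with a
certified prime set — no floating tolerance in the headline percentages),
with an SVD-based floating cross-check.

## Worked example

Compare the 16-run regular design with generators `E=ABC, F=ACD` (as used
in a six-component smoking-cessation intervention) against a 12-run
strength-2 orthogonal array derived from the Paley type-I Hadamard matrix
of order 12:

```r
library(hiddenproj)

reg <- build_regular(generator_set(4, c(E = "ABC", F = "ACD")))
oa  <- hadamard_to_oa(paley_type1(11), 6)

verify_strength(oa, 2)
#> Strength t = 2: holds (maximal strength 2)

projection_coverage(reg, 4)
#> k = 4 projections (all 15 subsets): 12 full rank, coverage 80.0%
#>   deficient: ABCE, ACDF, BDEF

compare_designs(list(regular = reg, oa12 = oa), k_values = c(3, 4),
                baseline = "regular")
#> | Design  | Runs | Max strength | Run reduction vs baseline |
#> |---------|------|--------------|---------------------------|
#> | regular | 16   | 3            | (baseline)                |
#> | oa12    | 12   | 2            | 25%                       |
#>
#> | Subset size | regular: full-rank (%) | oa12: full-rank (%) |
#> |-------------|------------------------|---------------------|
#> | 3 factors   | 100%                   | 100%                |
#> | 4 factors   | 80%                    | 100%                |
```

Reading: both designs estimate any 3-factor ME+2FI model, but for 3 of the
15 four-factor subsets ({A,B,C,E}, {A,C,D,F}, {B,D,E,F}) the regular
design's defining words alias interactions with each other, while the
12-run array — with 25% fewer runs — keeps every 4-factor projection
full rank (12 is not a multiple of 8, so the strength-2 guarantee applies).

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "hiddenproj", package = "hiddenproj"))')
Rscript $CLI construct paley1 --q 11 --cols 6 --out oa12.csv
Rscript $CLI strength oa12.csv --t 2
Rscript $CLI project oa12.csv --k 4 --list-deficient
Rscript $CLI case-study $(Rscript -e 'cat(hiddenproj::case_study_config_path("quit"))')
```

Exit codes: 0 success, 1 verification/expectation mismatch, 2 usage or
config error. Three case-study configs ship in `inst/extdata/`:
`quit.yaml` (16-run regular vs 12-run array), `hsv1.yaml` (32-run
resolution-VI regular vs 28-run Paley type-II array), and `npi.yaml`
(512-run 2^(16−7) vs 420-run Paley design from q = 419, an 18% run
reduction).

## Scope

Two-level factors only; no blocked or mixed-level designs, no
minimum-aberration search, no quaternary-code constructions. Paley
constructions require prime q (prime powers are not implemented; all
shipped run sizes are reachable with prime q). See
`vignettes/hidden-projection.Rmd` for methods and design choices.
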