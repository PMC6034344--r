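---
title: "Selecting balanced, error-tolerant barcode subsets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting balanced, error-tolerant barcode subsets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indexsel)
```

## The selection problem

A sequencing facility keeps a pool of `M` validated sample-index barcodes,
all of length `L` nucleotides, and must pick `n` of them for each run. Two
criteria separate good subsets from bad ones. First, demultiplexing
tolerates up to `m` substitution errors per index read only if all chosen
barcodes are pairwise at least `2m + 1` apart; the package default
`min_distance = 3` therefore tolerates one error. Second, on two-laser
Illumina chemistry the A/C (red) and G/T (green) channels should each light
up in about half the clusters at every index cycle, and basecalling and
nucleotide consumption both prefer all four bases to be used evenly.

`indexsel` formulates the choice as a mixed-integer linear program over
binary indicators `x_i` (barcode `i` selected or not) and solves it
exactly, rather than screening random subsets that merely satisfy the
distance threshold.

## The balance cost and its linearization

With `n_l^X` the number of selected barcodes carrying nucleotide `X` at
position `l`, and `N^X` the global totals, the objective is the unweighted
sum of absolute deviations

* `|n_l^A + n_l^C - n/2| + |n_l^G + n_l^T - n/2|` per position
  (laser-group balance; these terms steer the solution when perfect
  four-way balance is unattainable),
* `|n_l^X - n/4|` for each of the four nucleotides per position,
* `|N^X - nL/4|` for the four global totals.

All terms carry equal weight: the cost is a plain sum, and the global
targets are the equal shares `nL/4` of the total nucleotide count —
the only reading consistent with the positional targets. When every
single-nucleotide positional term vanishes the group terms vanish too, so
cost 0 is equivalent to `n ≡ 0 (mod 4)` with every position carrying each
nucleotide exactly `n/4` times. For odd `n` the positional cost is bounded
away from zero (each position contributes at least `4 × 0.25`), although
the *global* balance can still be perfect whenever `nL` is divisible
by 4 — selecting many barcodes therefore evens out total nucleotide usage
even when per-cycle perfection is impossible.

Each absolute value `|e|` enters the linear program through a continuous
auxiliary variable `t` with the constraint pair `t ≥ e` and `t ≥ -e`, and
the objective minimizes the sum of the auxiliaries. Six terms per position
plus four global terms give `6L + 4` auxiliaries and `12L + 8` balance
constraints — for standard 8-nt indexes, 48 positional auxiliaries with 96
constraints plus 4 global auxiliaries with 8 constraints. These counts
depend on `L` only, never on the pool size:

```{r counts}
s <- build_selection_ilp(selection_problem(example_barcode_sets()$A, 8))
c(aux_positional = s$n_aux_positional,
  constraints_positional = s$n_balance_constraints_positional,
  aux_global = s$n_aux_global,
  constraints_global = s$n_balance_constraints_global)
```

The remaining constraint families are `x_j + x_k ≤ 1` for every candidate
pair below the distance threshold, `sum(x) = n`, and `x_i = 1` for barcodes
fixed by augment mode.

## Exact arithmetic

The targets `n/2`, `n/4` and `nL/4` are rational, so every cost term is an
integer multiple of 0.25. `balance_cost()` works in scaled integer
"quarter counts" (`|g - n/2|` as `2|2g - n|`, `|c - n/4|` as `|4c - n|`)
and divides by 4 once at the end; quarters are exactly representable in
floating point, so `cost == 0` comparisons are exact, not within-epsilon.
Inside the ILP the fractional targets are handled natively because the
auxiliaries are continuous. The reported `objective_value` of a solution is
always this exact recomputation from the selected sequences; the solver's
floating-point objective is kept separately and cross-checked.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `metric` | `"hamming"` | substitutions only; `"levenshtein"` also counts indels |
| `min_distance` | 3 nt | minimum pairwise distance; `2m + 1` corrects `m` errors (Hamming) |
| `n` | — | subset size; perfect balance needs `n ≡ 0 (mod 4)` |
| `time_limit` | 10 s | branch-and-bound wall clock; on expiry the best incumbent is returned as `feasible_time_limited` |
| `branch_depth_limit` | 0 (off) | honored only if the backend supports it; the bundled HiGHS backend does not and warns |
| `seed` | `NULL` | opaque initialization hint for backends that take one |

The Levenshtein option uses the plain global edit distance with no free end
gaps. Because index reads have a fixed length, an indel in a real read also
shifts every downstream cycle, so Levenshtein distances can be optimistic
about practical error tolerance; the `tolerated_mismatches` guarantee is
reported for the Hamming metric only.

## Solver backend and numerical choices

The model — binaries, continuous auxiliaries, two-sided linear constraints,
linear objective, time limit — is handed to SciPy's `milp()` (the HiGHS
branch-and-bound solver) through a bundled Python helper; batches of models
share one interpreter start-up. Decisions worth knowing:

* **Tie-breaking.** Distinct subsets often share the optimal cost;
  which one is returned is backend-dependent (HiGHS itself is
  deterministic for a fixed model). Tests therefore assert objective
  values, never the identity of the chosen subset.
* **Rounding.** Binary values are read back with `round()`; solutions are
  then re-verified independently (size, all pairwise distances, fixed
  inclusion, exact cost) and an invalid solution is an error, never a
  silent result.
* **Presolve.** HiGHS presolve occasionally fails with a solve error on
  models with fractional constraint targets; the backend retries the same
  model with presolve disabled before giving up.
* **Infeasibility.** When the distance threshold plus cardinality admit no
  subset, status `infeasible` is reported with the number of forbidden
  pairs — a finding, not a crash.
* **Fixed-set conflicts.** In augment mode a forbidden pair entirely inside
  the committed set would make the model trivially infeasible; the package
  fails fast naming the pair, with `allow_fixed_conflicts = TRUE` to
  knowingly proceed (the pair constraint is then dropped, since both
  members are mandated anyway).
* **Check mode never runs the ILP.** Setting `n = M` and solving would
  declare a user's existing set "infeasible" when it merely violates the
  threshold; computing the diagnostics directly yields identical reports
  and a verdict (`compatible` or not) instead.

## What the synthetic generator emulates — and what it does not

`generate_candidate_pool()` stands in for a facility's candidate list. A
planted subset (size a multiple of 4) is built column-wise: each position
is an independent random permutation of the balanced multiset
`A,C,G,T` repeated `planted_n/4` times, rejection-sampled until all
pairwise Hamming distances reach the threshold, then verified post hoc
(cost exactly 0, distances) rather than trusted by construction. Decoys are
drawn with a skewed composition (`decoy_bias`) so that swapping them in
worsens balance. Generation is a deterministic function of the seed and
leaves the caller's RNG stream untouched.

Real candidate lists differ in ways the generator does not model: they are
pre-screened for PCR and synthesis constraints (no homopolymers,
GC bounds, no self-complementarity), their pairwise-distance distribution
is shaped by the design tool that produced them, and sequencing errors,
index hopping and color-space effects are not simulated at all. Passing
tests on generated pools therefore demonstrates correctness of the
optimization — that the returned subset is the exact optimum under the
stated cost and constraints — not that the cost function captures every
failure mode of a real run.

## Problem sizes and verification strategy

Exhaustive enumeration over all `C(M, n)` subsets is tractable for
`M ≤ 10`, `n ≤ 5`, and the test suite uses it as an independent oracle on
200 random instances (lengths 2–6 nt, thresholds 0–3, both metrics),
requiring exact agreement on both feasibility and the optimal objective.
End-to-end selection tests use generated pools of 24–48 candidates with
planted optima of known cost 0, and the four bundled 8-nt example sets
(8, 12, 16 and 24 barcodes; all cost 0 at minimum Hamming distance 3)
serve as fixed worked examples. Typical facility-scale problems — a few
hundred candidates, `n` between 10 and 24 — solve in seconds; the
all-pairs distance screen is `O(M²)` and the intended scale is pools up to
a few thousand candidates, not the enumeration of all `4^8` possible
8-mers (de novo design tools are the right instrument there).

## Known limitations

* Dual indexing (combining a P5 and a P7 set multiplicatively) is not
  modeled; each index set must be optimized separately.
* The balance cost targets two-channel Illumina chemistry; platforms with
  different detection schemes would need different group terms.
* With the time limit hit, the incumbent is returned and labeled
  `feasible_time_limited`; optimality is then not guaranteed and the exit
  status of the CLI reflects it.
* Quality-aware or color-space distances, sample sheets and FASTQ handling
  are out of scope; input and output are plain FASTA.
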