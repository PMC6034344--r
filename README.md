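# indexsel

Optimal selection of sequencing barcode (sample-index) subsets by integer
linear programming.

## The problem

Multiplexed high-throughput sequencing pools many libraries into one run,
each labeled with a short DNA barcode. A sequencing facility typically owns
a candidate set of a few hundred validated barcodes and, for every run,
must pick however many the experiment needs. Two things make one subset
better than another:

* **Error tolerance.** To correct up to *m* substitution errors when
  demultiplexing, every pair of barcodes in use must be at least 2*m*+1
  apart in sequence space (Hamming or Levenshtein distance). The default
  threshold of 3 tolerates one error.
* **Nucleotide balance.** Illumina instruments read A/C with one laser and
  G/T with the other, and basecalling degrades when the composition at an
  index cycle is skewed. Ideally each of A, C, G, T appears in *n*/4 of the
  *n* barcodes at every position.

Random subsets that satisfy the distance threshold can still have very
different balance, so `indexsel` treats the choice as an optimization
problem.

## The model

Let `x_i ∈ {0,1}` indicate whether candidate *i* (of *M*, all of length
*L*) is selected, with `Σ x_i = n`. Writing `n_l^X` for the number of
selected barcodes carrying nucleotide `X` at position `l`, the objective
minimized is

```
Σ_{l=1..L} [ |n_l^A + n_l^C − n/2| + |n_l^G + n_l^T − n/2|
           + |n_l^A − n/4| + |n_l^C − n/4| + |n_l^G − n/4| + |n_l^T − n/4| ]
           + Σ_X |N^X − nL/4|
```

— per-position laser-group balance, per-position single-nucleotide
balance, and global balance of the four totals `N^X`, all equally
weighted. Each absolute value `|e|` is linearized with a continuous
auxiliary variable `t` and the constraint pair `t ≥ e`, `t ≥ −e`, giving
`6L + 4` auxiliaries and `12L + 8` balance constraints regardless of pool
size (48 auxiliaries and 96 positional constraints for standard 8-nt
indexes). Every candidate pair closer than the distance threshold adds
`x_j + x_k ≤ 1`. The resulting mixed-integer program is solved exactly by
branch and bound (HiGHS, via SciPy's `milp`); a cost of 0 — attainable only
when `n` is a multiple of 4 — means perfect balance at every position.

Three modes cover facility practice: **select** a fresh subset,
**check** an existing set (e.g. whether two libraries with committed
indexes can be pooled), and **augment** a committed set with new compatible
barcodes.

## Worked example

Select 12 barcodes out of a generated pool of 48 candidates (the generator
plants a perfectly balanced 12-subset, so the optimum is known):

```r
library(indexsel)
fx  <- generate_candidate_pool(M = 48, L = 8, planted_n = 12,
                               min_distance = 3, seed = 42)
res <- select_barcodes(fx$pool, n = 12, metric = "hamming", min_distance = 3)
summary(res)
#> Barcode selection: status optimal
#>   12 barcodes selected, balance cost 0
#> Barcode pool: 12 barcodes of length 8 nt
#>   cand11       GGCGCGTG
#>   cand17       ATTTTAAC
#>   ...
#> Nucleotide-balance cost
#>   positional laser-group (A/C vs G/T): 0
#>   positional single-nucleotide:        0
#>   global nucleotide balance:           0
#>   total:                               0
#>   min pairwise hamming distance: 3
```

Status `optimal` with total cost 0 means the solver found a subset in
which every one of the 8 positions carries each nucleotide exactly 3
times, and no pair is closer than 3 mismatches. Checking an incompatible
set instead:

```r
check_barcodes(c("AAAA", "AAAT", "CGCG"), min_distance = 3)
#> Barcode set check: 3 barcodes of 4 nt, hamming distance >= 3 required
#>   verdict: NOT compatible
#>   min pairwise distance: 1
#>   violating pairs:
#>     bc1 vs bc2: distance 1
#>   balance cost: 26.5 (positional group 8 + single 10.5 + global 8)
```

The named pair is one mismatch apart, so one sequencing error could
misassign reads between those two samples.

A command-line front end with scriptable exit codes (0 optimal/compatible,
1 time-limited/incompatible, 2 infeasible, 3 input error) ships in
`inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","indexsel.R",package="indexsel"))')" \
    select --candidates candidates.fasta --n 12 --out chosen.fasta
```

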