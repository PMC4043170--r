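# clonewave

Deterministic and stochastic modelling of multiple neutral mutations in
hierarchically organized tissues, with human haematopoiesis as the
reference system.

Renewing tissues are arranged as differentiation hierarchies: a few slow
stem cells feed ~31 progenitor compartments whose division rates grow
geometrically (`r_i = γ^i r_0`, γ = 1.26) up to a mature-cell output of
~10^11 cells per day. A dividing cell differentiates (probability ε, both
daughters move downstream), mutates (probability u, founding a unique new
clone), or self-renews. Because ε + u > 1/2 in healthy tissue, any non-stem
clone is a transient **clonal wave**: it expands, travels down the
hierarchy and washes out. The package quantifies what such a wave leaves
behind:

* **Closed-form wave dynamics** `N_i^k(t)` for any number of mutations
  (Bateman-type sums with polynomial corrections, generated exactly for
  arbitrary k), with an ODE integrator as independent oracle.
* **Reproductive capacity** `W_i^k = α/(2α−1) · (2ε/(2α−1))^(i−1) ·
  (u/(2α−1))^k · C(i+k−1, k)` — total progeny of one founder cell, rate
  independent, exponentially suppressed per extra mutation.
* **Expected clonal diversity** `D_i^(k+1) = u Σ_j W_j^(k+1)` — the
  expected number of distinct mutations carried by (k+1)-mutant clones in
  compartment i — with exact linear error propagation.
* An exact **Gillespie individual-based simulator** with per-cell
  representation, full clone genealogy, census statistics, and Newick
  export of the mutation tree.
* The **childhood-ALL case study**: inversion of the mutant clone's
  differentiation probability from tumour burden and diagnosis-time
  constraints, time-to-load, and predicted passenger-mutation ranges.

The audience is mathematical oncologists and evolutionary modellers of
somatic tissue dynamics; the vignette
(`vignettes/clonal-waves.Rmd`) documents the model, the numerical choices
and the case-study conventions.

## Worked example

```r
library(clonewave)
hp <- hierarchy_params()   # healthy haematopoiesis
hp
#> Hierarchical tissue parameters
#>   compartments: 31 (founder in 1, n0 = 1)
#>   epsilon: 0.85 (constant), u: 1e-06, k_max: 5
#>   rates: r_i = 1.26^i * 0.0025  (r_1 = 0.00315, r_31 = 3.23167)
#>   regime: wave (alpha > 1/2)

capacity_neutral(hp, 31, 0)         # progeny of one cell reaching maturity
#> [1] 441376667713

expected_diversity(hp, 31)          # distinct single mutations it leaves
#> [1] 32.47899

diversity_error_budget(hp, 31, delta_u = 1e-7, delta_eps = 0.01)
#> diversity 32.48; Delta D = 23.98 (u-term 6.496, eps-term 17.49)

expected_diversity(hierarchy_params(epsilon = 0.75), 31)
#> [1] 28255.03
```

One founder cell in compartment 1 produces ~4.4 × 10^11 mature
descendants, among which about 30 distinct single mutations are expected.
The error budget shows the steep ε-sensitivity: an uncertainty of 0.01 in
the differentiation probability moves the expectation by ~17 — and
lowering ε to 0.75 (a mutant with enhanced self-renewal) inflates the
expected diversity a thousandfold to ~2.8 × 10^4, which is how a single
founder lesion can explain very diverse mutation landscapes.

The stochastic engine reproduces the same averages cell by cell:

```r
run <- gillespie_run(preset_params("test-small"), t_end = Inf, seed = 1)
run
#> gillespie_run: 111 events, 0 mutation clones, extinct at t = 1877
```

## Command line

A thin wrapper is installed under `inst/cli/clonewave`:

```sh
Rscript inst/cli/clonewave diversity --preset haematopoiesis --i 31 --k 1
Rscript inst/cli/clonewave trajectory --preset haematopoiesis --n0 1000 --method closed --out wave.tsv
Rscript inst/cli/clonewave simulate --preset test-small --seed 7 --out-prefix run1
Rscript inst/cli/clonewave all-case --n0-founder 100 --burden-min 0.10 --burden-max 0.75
```

Every run writes a JSON manifest with the resolved parameters and seeds so
outputs can be reproduced bit for bit.

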