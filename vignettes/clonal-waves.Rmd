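---
title: "Clonal waves and mutation diversity in hierarchical tissues: model and methods"
author: "clonewave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal waves and mutation diversity in hierarchical tissues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonewave)
```

## The model

Many renewing tissues are organized as a differentiation hierarchy: a few
slowly dividing stem cells feed a chain of progenitor compartments whose
division rates increase towards the mature cells. `clonewave` models the
clonal progeny of a single (possibly mutant) non-stem cell placed in the
first compartment of such a hierarchy. At every division of a cell in
compartment $i$ carrying $k$ mutations one of three things happens:

* **differentiation**, probability $\epsilon_i^k$: both daughters move to
  compartment $i+1$ (cells leaving the last compartment exit the system);
* **mutation**, probability $u$: the cell is replaced by a single cell with
  $k+1$ mutations in the same compartment, founding a new, unique clone
  (infinite-sites assumption);
* **self-renewal**, probability $1-\epsilon_i^k-u$: two cells remain in
  compartment $i$.

Stem cells are not modelled dynamically; the founder clone receives no
further influx. Writing $\alpha = \epsilon + u$ for the departure
probability, the expected occupancies $N_i^k(t)$ obey a linear system in
which class $(i,k)$ gains $2\epsilon\, r_{i-1} N_{i-1}^k$ by influx,
$u\, r_i N_i^{k-1}$ by mutation, and has net local rate
$(1-2\alpha)\, r_i$. The sign of $\alpha - 1/2$ separates two regimes:
for $\alpha > 1/2$ the solution is a transient *clonal wave* that expands,
travels downstream and washes out; for $\alpha < 1/2$ cells accumulate
without bound.

### Parameters

| parameter | meaning | haematopoietic default |
|---|---|---|
| `n_compartments` | differentiation stages | 31 |
| `epsilon` | differentiation probability (scalar or per-$(i,k)$ table) | 0.85 |
| `u` | mutation probability per division | $10^{-6}$ |
| `gamma` | per-compartment rate growth, $r_i=\gamma^i r_0$ | 1.26 |
| `r0` | stem-cell division rate per time unit | 1/400 |
| `n0` | founder cells in compartment 1 | 1 |
| `k_max` | mutation-count truncation | 5 |

One model time unit is one stem-cell division; with $r_0 = 1/400$, 400
units make a year, which the helpers `model_time_to_months()` /
`months_to_model_time()` convert. The defaults reproduce a daily mature-cell
output of order $10^{11}$–$10^{12}$ cells from roughly 400 stem cells, the
standard parametrization of human haematopoiesis.

## Closed forms and their oracle

For constant $\epsilon$ and pairwise distinct rates the cascade solves in
closed form. `closed_form_unmutated()` evaluates the chain solution

$$N_i^0(t) = n_0 \prod_{j<i} (2\epsilon r_j) \sum_{j\le i}
  \frac{e^{(1-2\alpha) r_j t}}{\prod_{l \ne j} (1-2\alpha)(r_j - r_l)},$$

with products accumulated in log space so that all 31 compartments evaluate
in double precision. For $k \ge 1$ the mutation steps re-use a compartment's
exponent, which turns the coefficients into polynomials in $t$;
`closed_form_multimutant()` generates these coefficients for *any* mutation
count by exact recursive integration of $t^m e^{at}$ sources, reproducing
the printed small-$k$ combinatoric coefficients as special cases. The
numerical integrator `integrate_dynamics()` (lsoda, relative tolerance
$10^{-10}$) is an independent oracle: the suite requires agreement to a
relative error of $10^{-6}$ over a matrix of $\epsilon \in \{0.6, 0.75,
0.85\}$, $u \in \{0, 10^{-3}, 10^{-2}\}$, $i \le 5$, $k \le 3$.

Two degenerate situations are handled explicitly. With $\gamma = 1$ the
rates coincide and the Bateman denominators vanish; the closed forms refuse
(relative rate gaps below $10^{-9}$) and point to the integrator. Mutations
out of the truncation class `k_max` leave the tracked system in both the
deterministic and the stochastic engine, so the occupancy of the last class
bounds the truncation error; `k_max = 5` is ample for $u \le 10^{-2}$.

In the founder compartment $N_1^k(t) = n_0 (u r_1 t)^k e^{(1-2\alpha)r_1 t}/k!$,
so the wave peaks at $t_k = k/((2\alpha-1) r_1)$ — equally spaced in $k$ —
with height suppressed by $u^k$. `peak_summary()` returns both the exact
peak height and its Stirling approximation
$n_0 (u/(2\alpha-1))^k / \sqrt{2\pi k}$ (the two differ by the usual
$\sim 1/(12k)$ factor, about 8% at $k = 1$).

## Reproductive capacity

The total progeny a single founder cell ever places in a class, counted at
departure, is its reproductive capacity $W_i^k$. Within one compartment
a cell leaves after $l$ divisions with probability
$\alpha(1-\alpha)^{l-1}$, having grown to $2^{l-1}$ cells, so
$W_1^0 = \alpha/(2\alpha-1)$, diverging when $\alpha \le 1/2$
(`founder_capacity()`). Entering cells arrive by differentiation (two per
departing cell that differentiates) or mutation (one), and are amplified by
their own class's factor; `capacity_table()` runs this double recursion for
arbitrary per-$(i,k)$ parameter tables, in log space, with divergence flags
that propagate downstream. For neutral parameters the recursion telescopes
along lattice paths into

$$W_i^k = \frac{\alpha}{2\alpha-1}
  \left(\frac{2\epsilon}{2\alpha-1}\right)^{i-1}
  \left(\frac{u}{2\alpha-1}\right)^{k} \binom{i+k-1}{k},$$

(`capacity_neutral()`), independent of $\gamma$ and $r_0$: rates set the
clock, not the lineage composition. The two suppression laws follow as
ratios (`hierarchy_ratios()`): the mutant load $W_i^k/W_i^{k-1}$ is
constant at the founder compartment and grows (ever more flatly in $k$)
downstream, and the compartment growth $W_{i+1}^k/W_i^k$ is constant for
unmutated cells. The $t\to\infty$ limit of `cumulative_count()` recovers
$W_i^k$ by exact integration of the closed forms, which the suite checks to
$10^{-4}$.

## Expected clonal diversity

`expected_diversity()` implements the package's diversity statistic

$$D_i^{k+1} = u \sum_{j=1}^{i} W_j^{k+1},$$

the mutation probability times the cumulative reproductive capacity of the
$(k{+}1)$-mutant class over the hierarchy up to compartment $i$. Under the
haematopoietic parametrization it evaluates to about 30 distinct single
mutations in compartment 31 from one founder cell, rising to about
$2.8\times 10^4$ if the founder's differentiation probability drops to
0.75 — roughly one order of magnitude per 0.03 of $\epsilon$. Two readings
of the statistic are worth distinguishing. By the identity
$u W_j^{k+1} = \alpha \cdot (u/\alpha) W_j^{k+1}$, the statistic is (up to
the factor $\alpha$) the expected number of distinct mutation events that
occur *among cells already carrying $k+1$ mutations* — a strict
mutation-event count one generation deeper than the founding events of the
$(k{+}1)$-class itself. The raw founding-event count, $\,(u/\alpha)\sum_j
W_j^k$, is what the stochastic clone census estimates directly (see below);
at the healthy parameter point it is of order $10^6$ for single mutations —
every one of $\sim 10^{12}$ produced cells carries a private mutation with
probability $u$ — and is dominated by clones of a handful of cells founded
in the last compartments. The capacity-weighted statistic $D$ discounts
exactly that dust and tracks the order of magnitude of *sequencing-visible*
subclone counts, which is the comparison the case study makes. The tests
tie the two readings together through the exact identity above rather than
conflating them.

`diversity_error_budget()` propagates parameter uncertainties to $D$ with
exact analytic partial derivatives (verified against central differences in
the suite), combining the two terms additively:
$\Delta D = |\partial_u D|\,\Delta u + |\partial_\epsilon D|\,\Delta\epsilon$.
At the healthy point, $\Delta u = 10^{-7}$ and $\Delta\epsilon = 0.01$ give
contributions of about 6.5 and 17.5 — the $\epsilon$ term dominates, and
both are of the order of the statistic itself, so small parameter shifts
move the expected diversity by factors.

`diversity_with_exclusions()` removes the contributions of chosen
compartments from the sum (clones counted there are dropped, upstream
contributions kept), the operation used to discard the smallest, hardest to
detect clones arising during the last differentiation steps. Because
capacities grow like $(2\epsilon/(2\alpha-1))^j$, the last two compartments
carry most of the count and the exclusion removes roughly 85% of it under
the defaults.

## The leukaemia case study

The case-study pipeline (`all_case_study()`) asks what differentiation
probability a mutant founder clone must have had to explain an observed
tumour burden, and what passenger diversity that implies. Conventions the
package fixes (the observational constraints do not determine them):

* **Reference population.** The healthy background is the flux-balance
  steady state of the same hierarchy fed by `n_stem = 400` stem cells:
  $\bar N_1 = 2\epsilon r_0 n_\mathrm{stem} / ((2\alpha-1) r_1)$ and
  $\bar N_{i+1} = \bar N_i \cdot (2\epsilon/(2\alpha-1))/\gamma$, about
  $2.7\times 10^{11}$ mature cells (`reference_population()`).
* **Burden.** The cancer-cell fraction at time $t$ is
  $N_\mathrm{mut}(t) / (\bar N + N_\mathrm{mut}(t))$ in the mature
  compartment. Summing the class equations over $k$ cancels the mutation
  fluxes, so the mutant total follows the unmutated closed form.
* **Interval semantics.** Time to a given burden is the first crossing
  (`time_to_burden()`, reported in months). The inferred interval
  (`estimate_epsilon_from_burden()`) maps constraint extremes by
  monotonicity: its lower end reaches the *upper* burden limit at the
  *earliest* diagnosis time; its upper end is the largest $\epsilon$ whose
  transient wave attains the *lower* burden limit within the window at all
  (beyond it the peak stays below the limit). Time to burden is U-shaped in
  $\epsilon$ — slow growth near $\alpha = 1/2$, vanishing clones near
  $\epsilon = 1$ — and the inversion deliberately selects the branch
  closest to the healthy value. Bisection tolerance is $10^{-4}$ in
  $\epsilon$.

With founder count 100, burden 10–75% and a 48–77 month window the
inversion returns an interval of roughly $[0.76, 0.83]$, slightly below
the healthy 0.85, reached in roughly 48–59 months — the wave picture:
a modest reduction in differentiation suffices for a clinically visible
clone, and the implied passenger diversity spans two orders of magnitude
across the inferred interval.

## Stochastic engine

`gillespie_run()` simulates the identical process exactly, one cell at a
time: exponential waiting times with total rate $\sum_i r_i n_i$, a
compartment drawn by aggregate rate and a cell uniformly within it
(distributionally identical to per-cell rates, $O(\text{compartments})$
per event), and the three outcomes at their configured probabilities. A
mutation replaces the cell by a single $(k{+}1)$-cell — count-conserving,
so ensemble means match the deterministic fluxes exactly, which the suite
checks at three standard errors over $10^3$ replicates. (The alternative
convention, division with one mutant daughter, would add a net cell per
mutation and bias the means; it is deliberately not implemented.) Every
mutation event founds a recorded clone; `clone_census()` counts distinct
clones ever seen in a compartment (closing over ancestral mutations), and
`export_lineage_newick()` serializes the clone genealogy for standard tree
tooling. Replicates in `replicate_ensemble()` get independent seeds drawn
from a master seed, and runs hitting the population cap are flagged and
excluded from summaries.

What the simulation emulates is the model, not real haematopoiesis: no
cell death outside differentiation, no competition for niches or cytokines,
no driver selection, no stem-cell influx, and neutral passengers only.
Agreement between the engines therefore validates the implementation, not
the biology.

## Test-problem sizes

The test hierarchy (`preset_params("test-small")`) uses 5 compartments and
an inflated mutation probability of $10^{-3}$ so that mutation events occur
at observable rates in small ensembles while the wave regime and all
structural properties are preserved. The suite's stochastic blocks use
$10^2$–$10^3$ replicates; the deterministic checks run the full
31-compartment hierarchy, which the closed forms evaluate in milliseconds.

## Known limitations

* The diversity statistic is a deterministic expectation; run-to-run
  fluctuation of realized clone counts is substantial for small expected
  numbers (the engine exposes it).
* Closed forms require constant $\epsilon$ and distinct rates; per-class
  tables run through `capacity_table()` and the integrator instead.
* The case-study inversion depends on the stated reference-population and
  burden conventions; with different conventions the inferred interval
  shifts by a few hundredths.
* In the accumulation regime only the integrator and capped stochastic
  runs are meaningful; capacities and diversity are flagged divergent.
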