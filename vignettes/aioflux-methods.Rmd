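---
title: "Allocation of inputs in outputs over a space of flux distributions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allocation of inputs in outputs over a space of flux distributions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aioflux)
```

## The problem

When an organ such as the lactating mammary gland is studied at the
input/output level, the measurable quantities are net uptakes of nutrients
from blood and secretion rates of product components (lactose, milk fatty
acids, protein, CO2). A stoichiometric model links them: metabolites are
partitioned into inputs, intermediary *pivots* (assumed not to accumulate)
and outputs, and every irreversible reaction `r_j` contributes the column
`a[, j]` of the stoichiometric matrix `M`. A flux distribution `v >= 0`
is *plausible* when it satisfies

* the steady-state rows `M v = 0` for every balanced species,
* the measured exchange fluxes (inputs and outputs fixed to data),
* homogeneous side constraints `B v = 0` encoding biological knowledge
  (pathway ratios, primer rules).

This set is a convex polyhedron. With organ-level data it is small — for
the mammary model shipped here it has dimension five — but almost never a
single point, so any quantity read off "the" flux distribution is really a
function over this polyhedron.

The quantity of interest here is not a flux but a **yield**: the amount of
a matter component (carbon, by default) entering through one input that is
recovered in each output. We call the resulting outputs-by-inputs matrix
the allocation of inputs in outputs (AIO). Two computations are provided:

1. the exact AIO table for one flux distribution (`aio()`), valid in the
   presence of metabolic cycles, where naive pathway-tracing fails;
2. the minimum and maximum of every AIO cell over the whole polyhedron
   (`aio_range()`, `minmax_nlp()`, `minmax_localsearch()`), which is a
   family of nonlinear programs because the cells are rational functions
   of the fluxes.

## The allocation model

For a reaction `r` with substrate component mass
`S_r = sum_i s_{i,r} c(m_i)`, the proportional-distribution assumption
states that a fraction `In_r(m_k) = s'_{k,r} c(m_k) / S_r` of all
component mass entering `r` is recovered in product `m_k`; these fractions
sum to one for every component-balanced reaction (this is asserted
exhaustively in the tests). Writing `F(m)` for the production throughput
of metabolite `m` under `v` (equal to its consumption at steady state),
the component flow `x[m0](m)` of origin `m0` satisfies the linear fixpoint

```
x[m0](k) = sum_{r producing k} In_r(k) * sum_{i substrate of r}
           (s_{i,r} v_r / F(m_i)) * x[m0](i)  +  injection of m0,
```

i.e. `(I - A) x = b` where `A` has nonnegative entries and column sums at
most one. `D1 = I - A` therefore has unit diagonal and nonpositive
off-diagonal entries — an M-matrix, hence invertible — which is what makes
the allocation *uniquely defined even when cycles recycle carbon
indefinitely* (the geometric series implicit in a cycle is summed exactly
by the linear solve). `build_d_matrices()` exposes `D1` and the input
columns `D2`; `aio()` solves the system column-wise (one solve per input,
cost cubic in the number of component-carrying metabolites) and routes the
pool contents into the sink fluxes. Metabolites with zero throughput are
pruned before the solve and receive zero allocations — the continuous
limit of a vanishing flux.

Three independent oracles verify this machinery without sharing any code
path with it: an exact topological propagation for acyclic flux patterns
(`dag_propagate_aio()`), a Monte-Carlo atom-tracing simulation whose
particles hop from pool to pool with the consumption-share probabilities
(`atom_trace_aio()`), and a dense grid scan for low-dimensional spaces
(`grid_minmax_oracle()`).

## Geometry of the flux space

`flux_space()` reduces the equality system by Gauss–Jordan elimination to
an affine parameterization `v = v0 + N lambda` whose coordinates `lambda`
are a subset of the reaction fluxes (the *independent variables*). Any
maximal independent subset is an equivalent coordinate system; the
`prefer_free` argument moves preferred reactions to the end of the
elimination order so that, when independent, they are the ones reported —
the mammary wrappers prefer the five biologically meaningful cycle fluxes
(gluconeogenic triose recycling, the two oxaloacetate cataplerosis routes,
NADPH oxidation, peptide hydrolysis). Boundedness is decided by recession
LPs, and the reported dimension discounts coordinates frozen by
nonnegativity in both directions.

All linear programming is done in the reduced coordinates (dimension at
most five for the shipped model) through `boot::simplex`, with a
recession-cone pre-check because unbounded objectives must be reported as
a status, not an error. Vertices are enumerated by optimizing linear
objectives: the canonical `±e_i`, all pairwise `±e_i ± e_j` combinations,
then random unit-sphere directions, deduplicating at a relative `1e-6` on
the flux vectors and stopping after a window (default 500; the default
draw budget is 2000) of consecutive non-novel optima. For dimensions up to
about four an exact facet-intersection enumeration (`method = "exact"`)
serves as the brute-force cross-check; extreme rays of unbounded cones are
enumerated the same way on the recession cone. The Chebyshev ball
(largest inscribed ball in the reduced metric) is one more LP; its center
is the canonical interior point.

## Min–max of the allocation coefficients

Each AIO cell is a ratio of polynomials in `lambda`, so its extrema need
not be attained at vertices — the test suite contains a case where the
interior optimum of a cell beats every vertex by over 30%. Two routes are
implemented:

* **NLP multistart** (`minmax_nlp()`): SLSQP over the reduced polytope
  from the Chebyshev center, every vertex (pulled 1% inward), and random
  Dirichlet mixtures; feasibility of the winner is re-verified by
  substitution. Objective evaluations use an exact single-column
  allocation solve (about a millisecond on the shipped model).
* **Boundary local search** (`minmax_localsearch()`): the boundary is
  parameterized by angles around the Chebyshev center (each boundary point
  is the unique exit of a half-line from the center; the exit is computed
  in closed form from the facet inequalities). An initial angular grid of
  step `2*pi/grid_p` (default `grid_p = 8`, capped at 4096 points) is
  scanned, then hill-climbing over the one-angle-at-a-time neighborhood
  proceeds with dichotomic step halving (default depth 10; ties broken by
  scan order toward the lexicographically smallest angles). A radial
  coordinate optionally extends the search to the interior, which is how
  `boundary_vs_interior()` checks that extrema are attained on the
  boundary — they are, for the shipped model, reproducing the qualitative
  finding that optimizers sit on faces (often in their interior, not at
  vertices).

Cells with no directed component-carrying path from input to output
anywhere in the space are reported as `[0, 0]` without optimization.
Convergence is judged at `1e-6` absolute in component-flux units; the two
routes agree within `0.5%` of the input total on the cross-checked cells.
No global-optimality certificate is claimed — the multistart plus the
grid/local-search cross-checks are the evidence.

## The mammary-gland transcription

The shipped fixture is a transcription of a published bovine mammary-gland
stoichiometric model, reconstructed from its printed description (all
exchange fluxes of the three lactation treatments; the eight side
constraints; the primer rules of fatty-acid synthesis; peptide-link costs
of 5 ATP synthesized / 1 ATP hydrolyzed; the 70/30 split of NADPH origin
between the pentose-phosphate and isocitrate-dehydrogenase routes), not
from the original machine-readable file. Reaction ids that appear in the
printed tables are preserved; lumped internal steps carry
transcription-assigned ids flagged in the builder. Several internal
choices are forced by printed results rather than stated explicitly, and
we record them here as design decisions:

* **Cofactor bookkeeping.** ATP, O2 and NH3 are *free balances*: their net
  production is a linear functional of `v` (`atp_balance()`), not a
  constraint. This is what makes the unconstrained spaces unbounded cones
  (the futile cycles burn ATP freely) and the ATP-constrained spaces
  bounded. CO2 is a balanced pivot with a free nonnegative sink — the
  predicted CO2, and an output row of the allocation table.
* **Classic yields.** P/O ratios of 3 (NADH) and 2 (FADH2), 2 ATP per
  acetate activation, 1 ATP-equivalent GTP per TCA turn. Carbon accounting
  is exact (the per-input carbon totals and the predicted CO2 follow from
  the data); ATP-scale magnitudes inherit these conventions and carry a
  few percent of uncertainty, which propagates to every quantity bounded
  by the ATP slack (cycle maxima, peptide-turnover maxima, and the
  displacement-driven ends of the allocation ranges).
* **NADPH oxidation feeds the respiratory chain** at the NADH P/O. The
  vertex combinatorics of the constrained spaces (maximal NADPH oxidation
  coexisting with near-maximal peptide turnover) is only possible if the
  marginal ATP cost of NADPH oxidation is near zero, which pins this
  choice.
* **Glycine synthesis is split** half through serine
  hydroxymethyltransferase and half through the glycine-synthase (CO2 +
  methylene-THF) route: the printed allocation of glycine carbon (about a
  quarter from the TCA/CO2 pool even when the cataplerotic routes are
  closed) admits no other reading.
* **Glycerol enters at the triose pool** through one lumped reaction, and
  triglyceride glycerol-3P is made from the triose pool with
  shuttle-supplied reducing equivalents. Including both directions of a
  cytosolic glycerol-3P dehydrogenase would add a sixth, ATP-neutral free
  cycle, contradicting the observed dimension.
* **Preformed long-chain fatty acid** esterified into milk triglyceride
  (the acylation flux is three times the triglyceride output, more than
  the synthesized C4–C16 supply) is a dedicated passthrough input with
  palmitate-equivalent carbon; it is reported as its own allocation column.
* The long-chain fatty-acid oxidation variant couples C16/C18 oxidation
  to a fraction of the TCA acetyl-CoA flux via one homogeneous side
  constraint; its uptakes are dedicated to oxidation.

With these choices the *structural* results are reproduced exactly: the
five shared independent variables, the unbounded dimension-5 cones, the
bounded dimension-4 spaces under the ATP-balance constraint of 1250
mmol/h/half-udder (a 10% tolerance band behaves as a relaxation), zero
flux-variability minima, the 2-by-4 activation combinatorics of the eight
extreme vertices, lactose drawing all of its carbon from glucose at the
relevant vertices, the fatty-acid precursor shares, and the per-input
carbon totals. ATP-scale magnitudes computed here (for example the
control-treatment ATP optimum of ~2968 mmol/h/half-udder from
`report_atp_comparison()`) are transcription-dependent to within a few
percent, and the same caveat applies to the ends of the min–max allocation
ranges that are limited by cycle capacity rather than carbon bookkeeping.

## The synthetic-network generator

`generate_toy()` emulates the class of networks the method is designed
for: irreversible, component-balanced, with non-accumulating pivots,
optional recycle cycles and a tunable number of free dimensions (realized
as parallel routes). Carbon counts are drawn from 1–6 and stoichiometric
coefficients are set to the carbon ratios, so balance holds by
construction; exchange fluxes are drawn and repaired to feasibility by a
linear solve, and generation retries (bounded) until the realized
dimension matches the request. The toys exercise geometry, cycles and
conservation — they do not imitate any organ's biology, so passing the
synthetic battery demonstrates correctness of the machinery, not fidelity
of any particular model. Problem sizes in the test suite (2–5 pivots, up
to 10 random feasible points per toy, one 10^6-particle tracing run) were
chosen to make the statistical assertions sharp at interactive run times.

## Degenerate inputs and numerical choices

Component-balance validation uses a relative tolerance of `1e-9`
(stoichiometries are small rationals). Fluxes below `1e-9` times the
maximum flux are treated as exact zeros for pruning. A reaction whose
products carry component mass while its substrates carry none is rejected;
a metabolite that is never produced nor consumed has no derivable role and
is rejected at model assembly; reversible SBML reactions are rejected with
instructions to split them. Steady-state violations beyond `1e-6`
(relative) raise errors in the throughput computation. The allocation
solve reports its condition number; the M-matrix structure makes
ill-conditioning a symptom of a modelling error rather than an expected
regime.

## Known limitations

* Carbon positions are not tracked: a cell of the allocation table says
  how much carbon of an input reaches an output, not which atoms. Isotope
  (positional) data can therefore disagree with allocation bounds.
* Min–max values are best-found values under a documented multistart and
  local-search protocol, not certified global optima.
* The vertex count of a sampled enumeration depends on the deduplication
  tolerance when the polytope has near-degenerate vertices; the exact
  facet-intersection route is the arbiter in low dimension.
* The transcription reproduces the documented structure of the original
  mammary model, but its unpublished internal stoichiometry (notably ATP
  yields) can only be approximated, with the consequences quantified
  above.
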