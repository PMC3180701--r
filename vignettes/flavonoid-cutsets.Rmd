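---
title: "Elementary modes, minimal cut sets and knockout flux states for pigment pathways"
author: "fluxcut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elementary modes, minimal cut sets and knockout flux states for pigment pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxcut)
```

## The problem

Anthocyanins — the pelargonidin- and cyanidin-derived glucosides that give
plant tissues their red-to-blue pigmentation — sit at the end of the
flavonoid branch of phenylpropanoid metabolism. Loss of pigmentation is a
common, easily scored adaptation, and it can be achieved by suppressing
many different combinations of biosynthetic genes. Which combinations
suffice, how they compare in their side effects on other flavonoids, and
why evolution repeatedly converges on particular ones (e.g. the
late-pathway pair DFR + ANS) are structural questions about the metabolic
network, not about any single gene.

`fluxcut` answers them with the standard toolkit of metabolic pathway
analysis, applied to a self-contained flavonoid subnetwork:

1. **Subnetwork extraction** — carve a *coherent* subnetwork out of a
   genome-scale network around seed pathway reactions.
2. **Elementary mode (EM) enumeration** — list every support-minimal
   steady-state route of the subnetwork, exactly.
3. **Minimal cut sets (MCSs)** — list every minimal reaction set whose
   simultaneous blocking removes all flux through chosen objective
   reactions (here, the two anthocyanidin 3-O-glucosyltransferase steps).
4. **Fragility coefficients** — rank reactions by the mean reciprocal size
   of the cut sets containing them.
5. **Knockout flux states** — compare a constrained reference flux state
   with the state obtained under each cut, via normalized flux ratios
   averaged per product class.

## Models and assumptions

### Networks and the steady-state condition

A network is a set of compounds and stoichiometric reactions
(`metabolic_network()`). Internal compounds obey exact mass balance
`S v = 0`, where `S` is the stoichiometric matrix over internal compounds;
external compounds are buffered by the rest of metabolism and carry no
balance constraint. Irreversible reactions must run forward (`v >= 0`).

An **elementary mode** is a flux vector satisfying these constraints whose
support (set of active reactions) is minimal. Every steady-state flux is a
nonnegative combination of EMs, so the EM set is a complete catalogue of
what the network can do. A **minimal cut set** for a set of objective
reactions is a minimal reaction set intersecting the support of every EM
that contains an objective reaction; blocking it provably abolishes the
objective flux, and the MCS list is complete in the same sense.

### Coherent subnetwork extraction

Enumerating EMs on a genome-scale network is hopeless (the number of modes
explodes combinatorially), so the analysis runs on a subnetwork that must
be *coherent*: every internal compound of the subnetwork participates in
exactly the same reactions in the subnetwork as in the full network, and
every boundary compound is plausibly buffered (external in the full
network, on a curated buffered list of carriers/nutrients/amino acids, or
a ubiquitous hub compound). `extract_coherent_subnetwork()` iterates
classification, connectivity comparison and traceback from seed reactions
until a fixed point.

Two thresholds interpret "a hub": a compound is reclassified external when
its full-network connectivity is at least `hub_ratio` (default 3) times
its subnetwork connectivity *and* at least `hub_min_connectivity`
(default 10) overall. The published procedure says only that the full
connectivity must greatly exceed the subnetwork one; the defaults make
that judgement explicit and tunable, and the planted-subnetwork generator
exercises both sides of the threshold. Termination is not guaranteed in
general, so extraction aborts when the subnetwork exceeds `max_fraction`
(default 0.8) of the full network.

### Exact enumeration

EM enumeration uses the classical null-space tableau scheme: reversible
reactions are split into forward/backward columns, internal compounds are
eliminated one at a time (cheapest column first) by combining rows of
opposite sign, each elimination followed by a support-subset minimality
test, and the split halves are recombined at the end, discarding the
futile two-cycles that splitting creates. All arithmetic is integer
arithmetic on gcd-reduced rows, so steady state holds *exactly* (the code
asserts `S v == 0`, not a tolerance). Fractional stoichiometries are
first scaled to integers per reaction column (`MASS::fractions` recovers
the exact decimal rationals); the scale factors are folded back into the
mode coefficients so reported fluxes are in the original reaction units.
Canonical form — coprime integers, first nonzero coefficient positive,
orientation fixed by any irreversible support member — makes mode sets
directly comparable.

MCSs are computed by Berge-style incremental transversal (hitting-set)
dualization over the target supports restricted to a candidate reaction
set. The candidate set is an explicit parameter: the published table is
computed over the twelve anthocyanin-pathway reactions
(`abp_candidate_reactions()`), and the default is the union of the target
supports.

### The fragility coefficient

For a reaction `r`, `fc(r)` is the mean of `1/|C|` over the cut sets `C`
containing `r`. A reaction that alone cuts the objective scores 1;
membership only in large cuts dilutes the score. This ranks reactions by
how crucial they are *to the objective*, which differs from participation
(the number of EMs containing the reaction — a pleiotropy proxy): early
pathway steps have high participation, but late steps can have higher
fragility.

### Reference and knockout flux states

The functional analysis needs one representative feasible flux state. The
published analysis let a black-box tool pick an arbitrary feasible state
under the measured-concentration constraints; for reproducibility this
package pins the choice down: `solve_reference_state()` returns the
feasible state of **minimal total flux** (L1 norm), found by a
deterministic two-phase simplex with Bland's anti-cycling rule (written
for this package; it is a dense textbook simplex adequate for the tens of
variables these subnetworks produce, and is itself tested against
brute-force vertex enumeration). Because the pick differs from the
original tool's, only *ratio-level* agreement with published flux figures
can be expected, never absolute rates — which is also why all reports are
ratios. Rates are in mmol/(kg h) throughout; concentrations in mg/kg are
converted by dividing by the molar mass in g/mol
(`convert_concentration()`), under the stated assumption that rates are
proportional to concentrations (the unknown proportionality constant
cancels in every ratio). The lignin pseudo-reaction consumes the
monolignols in the ratio 370 coniferyl : 238 sinapyl : 60 coumaryl
alcohol, and its rate is the lignin biomass fraction (0.15) times the
growth rate (0.18 h^-1), i.e. 0.027 h^-1 (`lignin_growth_flux()`).

A knockout state (`simulate_cut_state()`) re-solves with the cut reactions
fixed at exactly zero and the input fluxes fixed at their reference
values, on the rationale that the rest of metabolism keeps supplying the
subnetwork unchanged. Blocking a measured product necessarily contradicts
its fixed measured rate, so the preliminary constraints are *soft* in this
solve: slack variables absorb the smallest achievable total violation
(stage 1), then total flux is minimized among minimally relaxed states
(stage 2), and every relaxed constraint is reported in the state's
`relaxed` field. Cut zeros and fixed inputs are never relaxed. The design
choice to let *all* preliminary constraints (fixed values and ranges
alike) relax — rather than only range rows — is deliberate: otherwise
every cut blocking a measured product would simply be infeasible.

`ratio_report()` divides each blocked rate by its reference rate; where
the reference rate is zero the ratio is *undefined* (`NA`), not zero, and
is excluded from class averages — 0/0 carries no information. Class
averages are taken over the *end reactions* of each product class: the
reactions directly producing the class's external compounds.

## Numerical choices

* LP feasibility/pivot tolerance: 1e-9. Stage-2 solves allow the stage-1
  slack optimum plus 1e-8, so knockout rates carry noise of order 1e-7 at
  most; tests compare flux ratios at 1e-5.
* Tie-breaking: Bland's rule (smallest eligible index) in the simplex;
  lexicographic reaction order in tableau construction, cut-set sorting
  (size, then lexicographic) and traceback frontiers. Identical inputs
  give bit-identical outputs.
* Degenerate inputs: empty networks enumerate to empty mode sets;
  reactions touching no internal compound are single-reaction modes; an
  EM set with an empty target list yields no cut sets; a target mode whose
  support avoids all candidates raises an "uncuttable mode" error rather
  than silently returning a non-cut.
* EM classification: a mode producing compounds of several classes gets
  the highest-priority class (priority order = class order of the
  `product_class_map`, anthocyanins first in the shipped maps) and is
  flagged; modes with no net external production are futile cycles and
  fall to `"others"`.

## What the synthetic data emulate — and what they do not

The package is fully testable offline because every stage has generators
or fixtures with known answers:

* `gen_linear_chain()` / `gen_branching()` — networks whose EM count is a
  closed formula (`prod(layers)`) and whose cut sets for the sink
  objective are planted by construction.
* `gen_random_network()` — small random networks compared against
  brute-force oracles (all support subsets for EMs; all candidate subsets
  for MCSs). The property batteries run 100 seeded instances of each.
* `gen_full_with_embedded_subnet()` — a coherent subnetwork planted
  inside a larger network with high-degree hub compounds and a disjoint
  decoy component; extraction must recover it exactly.
* `make_mini_abp_fixture()` — a 12-reaction pathway with the anthocyanin
  branch-point structure (one pelargonidin route, two parallel cyanidin
  routes, flavonol side branches) and hand-enumerated modes (6) and cut
  sets (14).
* `synthetic_flavonoid_network()` — a larger stand-in for the real
  flavonoid subnetwork, carrying the canonical identifiers of the twelve
  anthocyanin-pathway reactions plus proanthocyanidin, flavone, flavanone
  (liquiritigenin), benzenoid and monolignol branches, and a demo
  constraint table in the style of the measured-concentration table.
* Packaged plain-text fixtures: the published 22-row cut-set membership
  table, the preliminary-constraint values, the fixed input fluxes and
  the product-class list.

The stand-in reproduces the *branch structure* of the anthocyanin
pathway: restricted to the twelve candidate reactions, its three
anthocyanin mode supports dualize to exactly the published 22 cut sets,
and fragility on them reproduces the published coefficient row. What it
does not reproduce is the full 180-compound / 164-reaction subnetwork:
total EM counts (359 published), per-class EM counts, participation
totals (156 for the chalcone synthase step) and the unaffected-mode
column depend on the complete model, which is distributed as a
supplementary SBML file and is not redistributable inside this package.
The replication test for those counts runs only when `AC8_subnet.sbml`
is placed alongside the package; without the file it fails rather than
silently passing. Passing the synthetic tests therefore shows the
*methods* are correct on networks of known structure, not that any
particular curated model is correct.

The knockout flux patterns checked on the stand-in mirror the published
qualitative findings: blocking the chalcone synthase or isomerase step
zeroes every flavonoid class except the liquiritigenin flavanone route
(whose chalcone-reductase entry bypasses both) while leaving benzenoids
untouched; blocking the two terminal glucosylations zeroes anthocyanins
only, with proanthocyanidin and flavonol averages at or above 1. Exact
published bar heights are not reproducible because the underlying
reference state is under-specified (see above); they are deliberately not
asserted anywhere.

## Worked example

```{r example, eval = FALSE}
library(fluxcut)

sf <- synthetic_flavonoid_network()
ems <- enumerate_ems(sf$network)
ems
targets <- select_target_ems(ems, sf$objective)
mcs <- enumerate_mcs(targets, candidates = abp_candidate_reactions())
mcs <- unaffected_counts(mcs, ems, objective = sf$objective)
round(fragility(mcs), 2)

ref <- solve_reference_state(sf$network, sf$constraints)
blocked <- simulate_cut_state(sf$network, ref, mcs, cut_index = 1)
ratio_report(blocked, ref, sf$class_map, sf$network)
```

## Known limitations

* EM enumeration is exponential in the worst case; the tableau is capped
  (`max_rows`) and the package targets subnetwork scale (hundreds of
  reactions with few modes), not genome scale.
* The simplex is dense and unscaled; it is not meant for thousands of
  variables.
* The hub thresholds and the buffered list are curation, not inference:
  recovering any *particular* published subnetwork depends on the same
  curated inputs its authors used.
* Cut sets treat reactions independently even when they share an enzyme;
  gene labels are reporting metadata only, which matches the published
  convention but means an "enzyme-level" cut analysis requires mapping
  reactions to genes first.
* The unaffected-mode universe is configurable precisely because
  published counts mix universes; no single convention is forced.
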