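---
title: "Predicting cross-feeding in a two-member consortium by coupled flux balance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cross-feeding in a two-member consortium by coupled flux balance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossfeedr)
```

## The question

Some probiotic lactobacilli — *Lactobacillus rhamnosus* GG being the
prominent example — cannot grow in milk: they degrade neither casein nor
lactose, and they are auxotrophic for several cofactors.  Pairing such a
strain with a proteolytic, lactose-fermenting *Streptococcus thermophilus*
turns milk into a viable growth substrate for both.  `crossfeedr` asks,
from genome-scale metabolic models alone: *which* metabolites flow between
the two members, which transfers are *essential* for the consortium, and
which form *redundant* groups where any one member of the group suffices?

## The model

Each member is a constraint-based metabolic model: a stoichiometric matrix
$S$ over metabolites and reactions, flux bounds $lb \le v \le ub$
(mmol gDW$^{-1}$ h$^{-1}$), and a lumped biomass reaction whose flux is the
growth rate $\mu$ (h$^{-1}$).  Flux balance analysis (FBA) maximises
$c^\top v$ subject to $S v = 0$ and the bounds, with $c$ selecting the
biomass column.  A growth medium enters through exchange-reaction lower
bounds: a component with maximum uptake $u$ opens its exchange to $-u$
(negative exchange flux is uptake; secretion stays open at the upper
bound).

The community model merges two members into one system.  Cytosolic
metabolites, reactions and genes are namespaced with the member tag
(`TAG__`), extracellular metabolites are merged on their compartment-free
base id into a single shared pool, each extracellular metabolite gets
exactly one community exchange reaction carrying the medium bounds, and one
extra constraint row enforces **balanced growth**,
$v_{bio,A} - v_{bio,B} = 0$.  A consortium of constant composition requires
equal specific growth rates; we implement the coupling as a hard equality
(the simplest reading — a fixed-ratio constraint would generalise it, and
the objective $\max v_{bio,A}$ is equivalent to maximising the sum under
the equality).

## The interaction screen

A metabolite is *shared* when one member can put it into the shared pool
and the other can take it out.  The uptake side must be a transport
reaction able to consume the extracellular species.  For the secretion side
we accept any member-owned reaction able to produce the extracellular
species, not only transports: the streptococcal casein protease acts on the
cell wall, so peptide release is an extracellular conversion rather than a
transport, yet it is precisely the "provides peptides" route the screen
must see.

For each shared metabolite and direction the screen records three things:

1. **Transfer flux** — the recipient's net uptake at the parsimonious FBA
   (pFBA) optimum.  Plain FBA optima are usually degenerate; pFBA picks the
   flux vector minimising $\sum_j |v_j|$ among those achieving at least
   $(1 - 10^{-6})$ of the optimum, which removes futile cycles and gives a
   canonical, solver-independent flux assignment.
2. **Essentiality** — all transport reactions of the *recipient* for that
   metabolite are knocked out (bounds fixed to zero) and the community FBA
   is re-solved; the transfer is essential iff growth falls below
   $10^{-6}$.  The paper-gap here is which side to disable; recipient-side
   knockout isolates the consumer's dependence, which is the question the
   narrated conclusions answer ("needs to be provided by…").  Donor-side
   knockouts are available via `side = "donor"` for sensitivity analysis.
3. **Direction robustness** — flux variability analysis (FVA) of the
   recipient's net uptake while holding at least 99.9% of the optimum; the
   direction is robust iff the interval does not straddle zero, so a
   reported direction never rests on solver arbitrariness.

Redundancy (OR) groups — sets of transfers jointly but not individually
essential, such as two interchangeable purine sources — are found by
`auto_groups()`: exhaustive enumeration of subsets (size 2 up to 3,
lexicographic) of the individually non-essential shared metabolites,
keeping minimal jointly-essential sets.  Two deliberate choices: the
candidate pool is *all* individually non-essential shared metabolites,
including those carrying zero flux at the reference optimum — a redundancy
group member can be idle in one particular optimal flux distribution while
still being an interchangeable supplier (with pFBA, one purine source
typically carries the whole flux and the other rests); and the size cap of
3 matches the largest group structure we target (three interchangeable
carbon sources) while keeping the enumeration safely below its $2^{15}$
subset guard.

## Orthology-based draft reconstruction

Draft models are built by transferring reactions from a curated reference
model through an ortholog map.  The map can come from any external tool (a
three-column TSV), or from the built-in alignment-free criterion:
similarity is the Jaccard index of two proteins' k-mer sets (default
$k = 5$), and a pair is accepted iff the two sequences are each other's
*unique* best hit with similarity at least `min_score` (default 0.3) — a
deterministic bidirectional-best-hit criterion adequate at desk scale.  A
gene-associated reference reaction is kept iff its gene rule evaluates
TRUE with mapped genes present and unmapped genes absent (conservative:
absence of evidence drops an AND-branch).  Non-gene-associated reactions
(exchanges, spontaneous steps) are added wholesale, whole subsystems can be
copied verbatim where pathway detail is carried over rather than
re-derived, and the biomass reaction is always carried since growth is not
orthology-transferable.

## The LP backend

All analyses reduce to linear programs over a few hundred variables.  The
package pins its own compiled bounded-variable two-phase primal simplex
(RcppArmadillo, dense algebra, Dantzig pricing with a Bland's-rule
fallback for degenerate cases; the solver identity is recorded in run
manifests).  Correctness is not taken on faith: the test suite checks every
optimal solution against its feasibility certificate
($\lVert S v\rVert_\infty \le 10^{-6}$, bounds within $10^{-6}$) and
verifies the optimum against `fba_enumerate_optimum()`, an independent
brute-force enumeration of all basic solutions, on twenty seeded random
systems.  Numerical conventions: steady-state and bound tolerance
$10^{-6}$; growth below $10^{-6}$ counts as abolished; unspecified reaction
bounds default to $[-1000, 1000]$ for reversible and $[0, 1000]$ for
irreversible reactions (the usual big-M convention); ties in tables and
enumerations are broken lexicographically so every report is byte-identical
across runs.

## The curated milk fixture

`make_milk_fixture()` returns the deterministic mini-pair used in the
examples and tests (also shipped as files under
`inst/extdata/milk_consortium_mini/`).  Its design condenses the biology
into the smallest network that expresses it:

* the milk medium has ten components — lactose, milk peptides, six
  B-vitamins, phosphate and water — each nutrient at a common uptake bound
  of 10 mmol gDW$^{-1}$ h$^{-1}$ (the milk description is nutrient-level,
  so a single representative bound is used; water is carried without a
  stoichiometric role);
* the ST-like member imports lactose, cleaves it, ferments the glucose
  moiety with fixed succinate and glycerol by-products, and exports the
  galactose moiety it cannot catabolise — so galactose, succinate and
  glycerol secretion are stoichiometrically forced at any growing optimum,
  not solver accidents;
* its cell-wall protease converts milk peptides into free peptides in the
  shared pool, feeding both members;
* the LR-like member has no lactose transporter and no protease, is a
  strict folate and purine auxotroph (supply via a folate transporter and
  interchangeable xanthine/guanine salvage), and catabolises galactose,
  succinate or glycerol interchangeably;
* biomass on both sides is one lumped reaction consuming a fixed bundle of
  carbon, amino acids, folate, purine, vitamins and phosphate — the
  smallest structure that expresses auxotrophy.

Because every bottleneck is explicit, the fixture's optima have closed
forms the tests pin exactly: the ST member alone grows at
$\mu = 40/10.3 \approx 3.883$ (40 carbon units from 10 lactose against a
10.3-carbon drain per growth unit), the community at
$\mu = 40/10.6 \approx 3.774$ (the extra 0.3 carbon pays for the partner's
folate and purine supply), and knocking out the galactose transfer leaves
exactly $\mu = 2$ (20 remaining carbon units from succinate and glycerol
against the recipient's 10-carbon demand).

One fixture choice deserves a note.  The rescue experiment — the auxotroph
grows on supplemented milk although not on milk — is modelled with an
enriched medium adding glucose, free amino acids, folate and guanine.
Sugar and amino acids alone cannot rescue a strict folate/purine
auxotroph; the supplement mirrors yeast-extract-style enrichment, which
supplies vitamins and nucleobases along with the nitrogen source.

## The synthetic generator and what passing tests mean

`make_toy_pair()` generates seeded random pairs with *planted* ground
truth: member A catabolises the medium's only substrate and can synthesise
and export every transfer metabolite; member B needs each planted
essential transfer plus one precursor per planted OR-group (obtainable
from any group member) and cannot touch the substrate; extra shared
metabolites are transportable but useless; noise reactions are reversible
conversions between fresh dead-end metabolites, mass-balanced and provably
unable to carry steady-state flux (the generator additionally verifies
growth is unchanged before accepting them).  The generator's core contract
— the screen recovers exactly the planted truth, precision = recall = 1
across seeds — is the package's main acceptance property.

These fixtures are deliberately small (tens of reactions per member; the
acceptance checks run twenty seeded pairs and twenty random LPs, sizes
chosen so the whole suite completes in seconds).  Passing them shows the
*machinery* is sound: merging, coupling, knockout bookkeeping, degeneracy
handling, group enumeration.  It does not show that a real genome-scale
reconstruction is accurate: real models bring annotation errors, gap-filled
reactions, cofactor bookkeeping, thermodynamically infeasible cycles and
biomass compositions measured at best approximately — none of which the
generator emulates.

## Known limitations

* Two members only; no abundance optimisation (members couple 1:1), no
  dynamic or spatial structure, no kinetics — product inhibition (e.g.
  galactose accumulation disadvantaging the producer) is outside
  stoichiometric scope.
* Knockouts are reaction-level; gene-level deletions through boolean GPR
  compilation are not implemented.
* The SBML dialect is a Level 3 core subset with bounds as reaction-local
  parameters; no units, annotations beyond free text, or full-spec
  validation.
* Milk peptides are pooled into one pseudo-metabolite; peptide-resolved
  modelling would refine the nitrogen economy.
* The genome summary's GC convention (ambiguity codes excluded from
  numerator and denominator, `gc_denominator = "acgt"`) is a documented
  choice; published GC percentages rarely state theirs, and the
  alternative (`"all"`) is offered.

## A worked run

```{r run, eval = FALSE}
fx <- make_milk_fixture()
community <- build_community(fx$st, fx$lr, fx$medium)
report <- screen_interactions(community)
groups <- auto_groups(community)
interaction_table(report, groups)
```

The interaction table lists folate and peptides as essential transfers
from the ST member to the LR member, galactose/succinate/glycerol as the
redundant carbon-source group, and xanthine/guanine as the redundant
purine group — all with the ST member providing and the LR member
consuming.
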