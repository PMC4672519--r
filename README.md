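# crossfeedr

Cross-feeding inference in two-member microbial communities by flux
balance analysis.

## What this is for

Defined bacterial co-cultures — yoghurt starters, probiotic consortia,
synthetic communities — often work because one member feeds the other.  A
textbook case: a probiotic *Lactobacillus rhamnosus* strain that cannot
grow in milk (it degrades neither casein nor lactose and is auxotrophic
for folate and purines) propagates readily when paired with a proteolytic,
lactose-fermenting *Streptococcus thermophilus*.  `crossfeedr` predicts
such interactions from genome-scale metabolic models: it builds a coupled
two-member community model, finds the metabolites one member can supply to
the other, and classifies each transfer as essential or redundant by
systematic transport knockouts.  It is aimed at microbiologists and
systems biologists designing or dissecting small defined consortia.

## The method

Each member is a constraint-based model: stoichiometric matrix `S`, flux
bounds `lb ≤ v ≤ ub` (mmol/gDW/h), and a biomass reaction whose flux is
the growth rate μ (1/h).  Flux balance analysis solves

```
max  cᵀv   s.t.   S v = 0,   lb ≤ v ≤ ub
```

with `c` on the biomass column; the medium enters through exchange-reaction
lower bounds.  The community model namespaces each member, merges the
extracellular metabolites into one shared pool with a single exchange per
metabolite, and adds a balanced-growth coupling row `v_bioA − v_bioB = 0`
(a stable consortium needs equal specific growth rates).  The screen then,
for every shared metabolite:

* records its transfer flux at the parsimonious-FBA optimum (pFBA picks
  the minimum-total-flux vector among near-optimal ones, removing
  degeneracy),
* knocks out the recipient's transport reactions and re-solves — growth
  below 1e-6 means the transfer is **essential**,
* checks by flux variability analysis that the transfer direction holds in
  all near-optimal flux distributions,
* and discovers **redundancy groups** (sets jointly but not individually
  essential, e.g. interchangeable purine sources) by exhaustive minimal
  subset enumeration.

Draft models can be built from a reference model via an ortholog map
(k-mer Jaccard bidirectional best hits, or any external tool's pair
table), with non-gene-associated reactions and selected subsystems copied
over.  All linear programs run on the package's compiled bounded-variable
simplex, which the test suite verifies against an independent brute-force
vertex-enumeration oracle.  A small utility also reports standard genome
assembly statistics (contigs, Mbp, GC%).

## Worked example

The package ships a curated two-member milk fixture (an ST-like member and
an LR-like auxotroph; also available as JSON/TSV files under
`inst/extdata/milk_consortium_mini/`):

```r
library(crossfeedr)
fx <- make_milk_fixture()

mono_growth(fx$st, fx$medium)   # 3.883495  — grows in milk alone
mono_growth(fx$lr, fx$medium)   # 0         — cannot grow in milk alone

community <- build_community(fx$st, fx$lr, fx$medium)
report <- screen_interactions(community)
groups <- auto_groups(community)
interaction_table(report, groups)
```

```
          compound     provides     consumes essential robust    flux                        group
1         Peptides ST_C106_mini LR_yoba_mini      TRUE   TRUE  3.7736                         <NA>
2       Folic acid ST_C106_mini LR_yoba_mini      TRUE   TRUE  0.3774                         <NA>
3        Galactose ST_C106_mini LR_yoba_mini     FALSE   TRUE 10.0000 galactose+glycerol+succinate
4        Succinate ST_C106_mini LR_yoba_mini     FALSE   TRUE 10.0000 galactose+glycerol+succinate
5         Glycerol ST_C106_mini LR_yoba_mini     FALSE   TRUE  7.7358 galactose+glycerol+succinate
6 Xanthine/Guanine ST_C106_mini LR_yoba_mini     FALSE   TRUE  0.7547             guanine+xanthine
```

Reading: the coupled community grows at μ = 3.774 for both members.
Peptides and folate must be supplied by the ST member (knocking out the
recipient's transporters abolishes growth).  Galactose, succinate and
glycerol are all transferred but individually dispensable — they form the
redundant carbon-source group (jointly essential), and xanthine/guanine
form the redundant purine group.  Flux units are mmol/gDW/h at the pFBA
optimum.

The same pipeline runs from the shell via
`Rscript inst/scripts/crossfeed.R run --model-a … --model-b … --medium …`,
and `run_pipeline()` writes the interaction table, group table, community
flux report and a run manifest with the solver identity and seed.

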