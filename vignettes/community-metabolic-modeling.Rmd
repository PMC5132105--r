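---
title: "Community metabolic network reconstruction: models, methods and design choices"
author: "CommFBA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community metabolic network reconstruction: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CommFBA)
```

# The modeling problem

A genome-scale metabolic model is a stoichiometric matrix $S$ (metabolites
$\times$ reactions), flux bounds $lb \le v \le ub$ (mmol·gDW⁻¹·h⁻¹), and a
biomass pseudo-reaction draining precursor metabolites in fixed ratios.
Under the quasi-steady-state assumption, feasible metabolic states satisfy
$S v = 0$, and flux balance analysis (FBA) predicts growth as the maximum
attainable biomass flux. A *media condition* sets the bounds of exchange
reactions: each exchange is written in export orientation, so a compound
with maximum uptake $u$ and maximum excretion $e$ has exchange bounds
$(-u, +e)$, and compounds absent from the media cannot be taken up.

For a community of $N$ member species, two architectures are supported:

* **Mixed-bag** ("supra-organism"): all cytosolic reactions are pooled into
  one compartment `c0`. Reactions with identical canonical stoichiometry
  collapse into one; the member biomass equations are combined by summing
  their coefficients and rescaling by $N$. This architecture answers
  environment-community questions but cannot resolve which species does
  what.
* **Compartmentalized**: member $i$'s network lives in its own cytosol
  `c<i>`; all members share one extracellular compartment `e0` through
  which — and only through which — metabolites can pass between species.
  Each member keeps its own biomass reaction, rewritten to produce a
  species-biomass pseudo-metabolite, and a community biomass reaction
  drains $1/N$ of each. This coupling means the community objective is
  zero whenever any member cannot grow, which is what makes obligate
  dependencies visible.

The package's central claim to usefulness is **community-level
gapfilling**: when the candidate reaction database is instantiated once
per species compartment (plus transporter templates connecting each
cytosol to `e0`), the minimal-cost repair of the *community* biomass can
delegate functions between members. If exporting a partner's surplus
metabolite is cheaper than granting a member the full biosynthetic route,
the parsimony criterion selects the cross-feeding repair — and the
predicted interactions follow from the model structure rather than from
prior knowledge of the partnership.

# Algorithms

## Linear programming

All flux computations reduce to bounded LPs, solved by an internal
two-phase bounded-variable primal simplex (dense; the basis system is
re-solved at every pivot, trading speed for numerical robustness at the
package's problem sizes of tens to a few hundred variables). Entering
variables follow the Dantzig rule with smallest-index tie-breaking, and
Bland's rule engages after a run of degenerate pivots, guaranteeing
termination on the highly degenerate $b = 0$ systems that steady-state
models produce. LP tolerance is $10^{-9}$; optimal solutions satisfy
per-metabolite residuals below $10^{-9}$ (and in practice near machine
precision). The suite cross-checks the simplex against brute-force vertex
enumeration and against `boot::simplex` on random instances.

Parsimonious FBA (pFBA) fixes the objective at its optimum and minimizes
$\sum_i |v_i|$ via the standard split $v = p - q$, $p, q \ge 0$. LP
variables are ordered lexicographically by reaction id, so alternative
optima are resolved identically across platforms and member orderings.

## Exact parsimony gapfilling

Gapfilling seeks $\min \sum_r c_r z_r$ over candidate indicator variables
$z$ such that the target objective reaches $\varepsilon$ with the selected
candidates open. Reversible database entries are offered as two directed
candidates (each at the entry's cost; a single steady-state solution only
ever uses one direction). Rather than a big-M MILP — whose LP relaxation
is nearly uninformative because $z \ge |v|/M$ is tiny — the search is an
exact branch-and-bound over candidate sets: each node carries forced-in
and forbidden sets; infeasibility of the LP with all remaining candidates
open prunes the branch; the branching candidate is taken from the support
of a minimal-total-candidate-flux solution at objective $=\varepsilon$;
and feasible nodes are reduced to irreducible sets before being scored.
Cost bounds prune dominated branches, and ties among equal-cost optima are
broken by the lexicographically smallest sorted (compartment, reaction,
direction) tuple, so results are deterministic. On every fixture instance
the search provably matches `bruteForceGapfill`, which enumerates database
entry subsets in increasing cost (guarded to 15 entries).

## Transcriptomic flux fitting

Gene activity calls come from a percentile threshold: the 10th percentile
(type-7 linear interpolation between order statistics, so the $k$-th of
$n$ sorted values sits at quantile $(k-1)/(n-1)$) of the expression of
universal-role housekeeping genes. Genes at or above threshold are "on"
(the tie goes to "on" — the convention must pick a side and inclusive-on
is fixed here), below are "off", unprofiled genes are unknown. Reaction
activity is three-valued GPR evaluation; reactions without genes
(gapfilled, exchange, biomass) are unknown and excluded from the
confusion matrix, but gapfilled reactions carrying flux are tallied as
their own per-pathway category.

The fit maximizes the number of honored calls — flux of at least $\delta$
through active reactions, zero flux through inactive ones — subject to
biomass $\ge \varepsilon$. This maximum is computed exactly by
branch-and-bound over conflict sets: if enforcing all remaining calls is
infeasible, a minimal infeasible subset (found by deletion filtering) is
extracted and the search branches on which of its members to give up;
direction choices for reversible active reactions are explored by
depth-first search (they are rare). A final pFBA-style stage minimizes
total flux at the achieved agreement, and agreement flags are reported
from the actual fluxes.

Consistency reports classify each GPR-bearing reaction by
(|flux| $\ge \delta$) $\times$ (expression on/off), giving four categories
whose percentages sum to 100; the accuracies are
active $= \frac{+F{+}E}{+F{+}E \; + \; -F{+}E}$,
inactive $= \frac{-F{-}E}{-F{-}E \; + \; +F{-}E}$, and
overall $= +F{+}E \; + \; -F{-}E$ (as percentages of classified
reactions). Degenerate denominators yield `NA` rather than an error.

# Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| default flux bound | 100 | mmol·gDW⁻¹·h⁻¹ | keeps all LPs finite; far above fixture scale |
| LP tolerance | 1e-9 | — | separates pivoting noise from structural zeros |
| growth threshold | 1e-6 | flux | below this, an "optimum" is numerical noise |
| gapfill target $\varepsilon$ | 0.01 | flux | well above the growth threshold, so repairs cannot rely on numerically marginal flux |
| flux-activity $\delta$ | 1e-3 | flux | flux/no-flux classification cut; must exceed solver tolerance |
| interaction tolerance | 1e-6 | flux | minimum reported transfer |
| expression percentile | 10 | % | threshold position within the universal-role distribution |
| candidate costs | 1.0 per entry/direction | — | unit costs; configurable per database entry |

All of these are arguments of the corresponding functions, and
`runConfig()`/`readRunConfig()` centralize them for command-line runs
(YAML file overridden by flags; every CLI run writes a provenance JSON
with package version, seed, parameters and input hashes).

# The synthetic consortium

The fixture generator builds a two-member phototroph–heterotroph
consortium shaped after hot-spring mat partnerships between a
photoautotrophic cyanobacterium and an obligately aerobic heterotroph that
lacks nitrate assimilation:

* The **phototroph** (15 core reactions) imports photons, CO2, nitrate and
  water; a lumped photosystem yields ATP, NADPH and O2 (with an ATP:NADPH
  ratio of 2:1, above the 1.5 demanded by fixation, standing in for cyclic
  photophosphorylation — without the surplus the network could not make
  net ATP); lumped Calvin-cycle fixation yields glucose; nitrate is
  reduced to ammonia; alanine and a vitamin-like cofactor are synthesized
  in two steps each; reversible uniports can secrete glucose, ammonia and
  O2.
* The **heterotroph** (12 core reactions) respires sugars aerobically but
  is missing its glucose importer and both biosynthetic routes (alanine,
  vitamin) — annotation-gap style lesions — and has no nitrate pathway at
  all. It grows on acetate-containing rich media, not on glucose-minimal
  or autotrophic media.
* The **candidate database** (15 entries: 10 reactions + 5 transporter
  templates) contains the deleted reactions, a photoautotrophy
  alternative, nitrate assimilation, and three distractors that can never
  enter a minimal repair. Its size keeps exhaustive enumeration cheap, so
  the exact search is oracle-verified on every instance.

Carriers (ATP/ADP, NAD(P)H) use single-letter pseudo-elements so that
every non-exchange, non-biomass reaction is elementally balanced and the
balance checker is a meaningful fixture test. Biomass consumes glucose,
alanine, the vitamin and ATP. On autotrophic media the designed outcomes
are: community gapfill = 3 transporters (phototroph exports alanine and
vitamin; heterotroph gains a glucose importer), cost 3, versus 9 for
repairing the heterotroph alone; the mixed-bag merge of the same drafts
needs no repair at all (the pooled cytosol already contains every
pathway); and interaction counts under the three construction strategies
are 5 (pre-gapfilled members, strategy A), 6 (merge-then-gapfill, B) and 6
(rich pre-gapfill + post-gapfill, C), realizing the expected ordering
A ≤ B ≤ C: more community-level gapfilling predicts at least as many
exchanges. On this fixture strategies B and C converge to the same final
model — rich-media pre-gapfilling adds nothing because the heterotroph
already grows on rich media — so the top of the ordering is an equality
here; the strict part is pre-gapfilling's deficit.

Expression profiles designate the genes of flux-carrying reactions (pFBA,
$|v| \ge \delta$) as active and draw values from log-normal bands: active
around 200, inactive around 5, with 80 universal-role genes around 100 —
enough roles that the percentile threshold is stable, and an intermediate
band position so the threshold separates the designated sets exactly when
the noise (the common log-scale standard deviation) is zero. At noise 1.0
the bands overlap appreciably and mean recovery over 20 seeds sits near
95–98%. The designated truth covers the model's genes; universal roles are
thresholding scaffolding (the percentile convention necessarily calls the
bottom tenth of them off).

What the generator does *not* emulate: genome-scale network size and
redundancy (thousands of reactions, isozyme-rich GPRs), cofactor and
proton bookkeeping, biomass compositions with tens of precursors,
thermodynamic infeasibilities, noise structure of real RNA-seq (length and
coverage biases, zero inflation), or multi-condition expression designs.
Passing tests therefore demonstrate correctness of the algorithms and the
qualitative community-modeling phenomena — obligate cross-feeding,
parsimony-driven delegation, strategy ordering — not predictive accuracy
on real consortia, where draft networks and community-confounded
expression data keep flux/expression consistency far from perfect even
for curated models.

# Numerical and design decisions

* **Compartment and id conventions**: cytosols `c<i>` (`c0` for
  mixed-bag), one extracellular `e0`; metabolite ids are suffixed with
  their compartment; exchanges are export-oriented (`uptake < 0`).
  Unspecified bounds default to $(-100, 100)$ reversible / $(0, 100)$
  irreversible; zero stoichiometric coefficients are dropped at
  construction so reaction-identity hashing sees a canonical form.
* **Duplicate detection** uses canonical stoichiometry (compartment-
  normalized, direction-normalized so the lexicographically smallest
  metabolite id has a negative coefficient, entries sorted), never
  reaction ids: members from different pipelines may name identical
  biochemistry differently. Bounds of merged duplicates take the union
  interval; GPRs the OR. In compartmentalized mode only exchange
  reactions collapse; species transporters remain per-compartment (the
  alternative — collapsing identical transporters across species — would
  erase exactly the species resolution the architecture exists for).
* **Community biomass weighting** is equal ($1/N$) by default, mirroring
  the mixed-bag rescaling rule; `buildCompartmentalized(weights =)`
  provides an abundance-weighted variant.
* **Interaction extraction uses pFBA**, not plain FBA: FBA fluxes are
  degenerate and would make the exchange map an accident of pivoting
  order. A flux-variability mode (`mode = "fva"`) additionally reports
  exchanges merely *possible* at the community optimum. Transfer flux is
  min(producer secretion, consumer uptake), so media-supplied consumption
  is never attributed to a partner; compounds can still appear when both a
  genuine producer and the media feed the same pool, which is reported as
  the recycled share only.
* **Degenerate inputs**: models that fail validation can still be built
  and inspected (`validateModel` returns violations instead of raising);
  already-growing models gapfill to an empty result of cost zero;
  unreachable targets raise "no gapfill solution"; infeasible FBA returns
  a `FluxSolution` with status `"infeasible"` rather than an error;
  degenerate accuracy denominators yield `NA`.
* **Problem sizes**: the shipped analyses run on models of 20–90
  reactions, databases of ≤ 15 entries and communities of 2 members; the
  full test suite (including 25 oracle-verified gapfill instances and a
  20-seed recovery simulation) completes in about two minutes on one CPU,
  and `scripts/acceptance.R` in about half a minute.

# Known limitations

* The dense simplex and exact searches target tens-to-hundreds of
  variables; genome-scale models (thousands of reactions) would need a
  sparse factorized LP backend and a MILP solver with stronger relaxations.
* Gapfilling costs are unit-valued by default; annotation-likelihood
  weighting is out of scope.
* No thermodynamic or charge-balance constraints; formulas are used for
  elemental audit only.
* Dynamic (kinetic) community modeling is out of scope: everything here is
  quasi-steady-state.
* Community expression integration maps one merged gene table onto member
  models via their gene sets; genes shared verbatim between members would
  be indistinguishable (the fixtures use disjoint gene namespaces).
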