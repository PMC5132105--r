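# CommFBA

Community-data-driven reconstruction and flux analysis of microbial
community metabolic networks, in R.

Many environmental consortia cannot be dissected into axenically
cultivable members, so the conventional route to a community metabolic
model — curate each species' network to high quality, then combine — is
often unavailable. `CommFBA` implements the complementary, community-first
approach: merge draft single-species genome-scale models into one
community model, let **community-level gapfilling** repair the merged
network (so that metabolic functions may be delegated between species when
cross-feeding is the most parsimonious repair), predict the resulting
interspecies metabolite exchanges by flux balance analysis, and score the
model's flux predictions against gene-expression-derived activity calls.

## What it computes

For a metabolic network with stoichiometric matrix *S* and flux vector
*v*, all analyses build on the steady-state flux cone
*S v = 0*, *lb ≤ v ≤ ub*:

* **FBA / pFBA** — maximize the biomass flux; parsimonious FBA then
  minimizes Σ|v| at the fixed optimum, yielding a deterministic flux
  pattern (`runFBA`).
* **Community merging** — *mixed-bag* models pool all reactions into one
  shared cytosol (duplicates collapse on canonical stoichiometry; GPR
  rules are OR-merged; biomass equations are summed and rescaled by the
  number of members), while *compartmentalized* models keep one cytosol
  per member sharing a single extracellular compartment, with a community
  biomass that drains 1/N of each member's biomass — coupling community
  growth to every member (`buildMixedBag`, `buildCompartmentalized`).
* **Parsimony gapfilling** — find a provably minimal-cost set of candidate
  database reactions whose addition makes biomass ≥ ε on a given medium;
  at the community level the database is instantiated once per species
  compartment plus transporter templates, so cross-feeding repairs compete
  with self-sufficiency (`gapfill`, `communityGapfill`,
  `bruteForceGapfill` as an exhaustive oracle). Three construction
  strategies — pre-gapfill members (A), merge-then-gapfill (B), rich-media
  pre-gapfill plus post-gapfill (C) — are provided by `runStrategy`.
* **Interaction prediction** — from a pFBA solution of the community
  model, every extracellular compound with one member's net secretion and
  another's net uptake above tolerance is reported as a transfer, with
  flux min(secretion, uptake) (`identifyInteractions`).
* **Expression integration** — genes are called on/off at the 10th
  percentile of 80 universal-role (housekeeping) gene expression values;
  reaction activity follows by three-valued GPR evaluation; transcriptomic
  FBA finds fluxes agreeing with as many calls as possible without
  starving the model; consistency reports give the four-category
  flux x expression confusion matrix and its accuracies
  (`callGeneActivity`, `reactionActivity`, `transcriptomicFBA`,
  `consistencyReport`).

No external solver is required: the package ships its own bounded-variable
simplex and an exact candidate-set branch-and-bound for the gapfilling and
flux-fitting searches.

A deterministic synthetic fixture — a photoautotroph that fixes CO2 and
nitrate and can secrete sugar, amino acid, vitamin and O2, paired with an
obligate aerobic heterotroph missing its sugar importer and several
biosynthesis steps — exercises the full workflow without any downloads
(`makeToyPhototroph`, `makeToyHeterotroph`, `makeToyDatabase`,
`makeExpressionProfile`).

## Worked example

```r
library(CommFBA)

ph  <- makeToyPhototroph()     # grows on autotrophic media
het <- makeToyHeterotroph()    # obligately dependent on a partner there
db  <- makeToyDatabase()

cm  <- buildCompartmentalized(list(ph, het))$model
predictGrowth(cm, autotrophicMedia())$growth
#> [1] FALSE                    # drafts cannot grow together

gf <- communityGapfill(cm, db, autotrophicMedia())
gf
#> GapfillResult (cgf on 'autotrophic')
#>   3 reaction(s) added, total cost 3; objective 1.54762
#>   TPT_ala[c1,fwd], TPT_vit[c1,fwd], TPT_glc[c2,rev]

identifyInteractions(gf@model, autotrophicMedia())
#>   compound    producer    consumer       flux
#> 1      ala  phototroph heterotroph 2.32142857
#> 2      co2 heterotroph  phototroph 1.78571429
#> 3      glc  phototroph heterotroph 0.29761905
#> 4      h2o heterotroph  phototroph 1.78571429
#> 5       o2  phototroph heterotroph 1.78571429
#> 6      vit  phototroph heterotroph 0.07738095
```

The community repair is pure cross-feeding: rather than granting the
heterotroph a 9-reaction autotrophic lifestyle (the cost of repairing it
alone on the same medium), the gapfiller adds three transporters so the
phototroph exports sugar, amino acid and vitamin that the heterotroph
already knows how to use — and the predicted exchange map shows organic
carbon, fixed nitrogen, the vitamin and O2 flowing to the heterotroph,
with CO2 recycled back.

A command-line interface wrapping the same functions is provided in
`inst/scripts/commfba` (subcommands `fixtures`, `merge`, `fba`,
`interactions`, `gapfill`, `expr-call`, `expr-fba`, `expr-report`).

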