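#' @importClassesFrom Matrix dgCMatrix
NULL

# Compartment id convention used throughout:
#   "c<i>"  cytosol of species i (i >= 1); "c0" the merged mixed-bag cytosol
#   "e0"    the single shared extracellular compartment
#   "b0"    pseudo-compartment for community biomass bookkeeping
# Metabolite ids are "<compound>_<compartment id>"; exchange reactions are
# written in export orientation (uptake is negative flux).

#' MetabolicModel: a constraint-based metabolic network
#'
#' Container for a genome-scale (or toy) metabolic network: compartments,
#' metabolites, reactions with flux bounds and gene-protein-reaction (GPR)
#' rules, a sparse stoichiometric matrix, and one or more biomass reactions.
#'
#' Slots hold plain data.frames so that malformed models can be constructed
#' and then diagnosed with [validateModel()]; only structural consistency
#' (matching dimensions and names) is enforced at construction time.
#'
#' @slot id model identifier.
#' @slot compartments data.frame with columns `id`, `label`
#'   (one of "cytosol", "extracellular", "biomass"), `species_index`.
#' @slot metabolites data.frame with columns `id`, `name`, `formula`
#'   (elemental composition or NA; "" means massless), `charge`,
#'   `compartment`.
#' @slot reactions data.frame with columns `id`, `name`, `lb`, `ub`,
#'   `gpr` (boolean rule string, "" for none), `pathway`, `source_tag`
#'   (draft, gapfilled, exchange, biomass or transport).
#' @slot S sparse stoichiometric matrix, metabolites x reactions
#'   (negative coefficient = consumed).
#' @slot biomassIds ids of the biomass reaction(s).
#' @export
setClass("MetabolicModel",
  representation(
    id = "character",
    compartments = "data.frame",
    metabolites = "data.frame",
    reactions = "data.frame",
    S = "dgCMatrix",
    biomassIds = "character"
  )
)

setValidity("MetabolicModel", function(object) {
  msg <- character()
  if (length(object@id) != 1L) msg <- c(msg, "id must be a single string")
  if (nrow(object@S) != nrow(object@metabolites))
    msg <- c(msg, "S row count != number of metabolites")
  if (ncol(object@S) != nrow(object@reactions))
    msg <- c(msg, "S column count != number of reactions")
  if (!identical(rownames(object@S), object@metabolites$id))
    msg <- c(msg, "S rownames must equal metabolite ids")
  if (!identical(colnames(object@S), object@reactions$id))
    msg <- c(msg, "S colnames must equal reaction ids")
  if (length(msg)) msg else TRUE
})

#' CommunityModel: a multi-species metabolic model
#'
#' A [MetabolicModel-class] whose compartments are mapped to member species.
#' Mixed-bag models keep a single merged cytosol ("c0"); compartmentalized
#' models keep one cytosol per member ("c1", "c2", ...). Both share one
#' extracellular compartment ("e0") and carry a community biomass reaction
#' that is the default FBA objective.
#'
#' @slot speciesIndex data.frame mapping `compartment` to `species` and
#'   `member_model` ids.
#' @slot memberBiomassIds named character, one biomass reaction per member
#'   (named by member model id).
#' @slot communityBiomassId id of the community biomass reaction.
#' @slot nMembers number of member models merged.
#' @slot memberExchanges named list: exchange reaction ids contributed by
#'   each member (used for exact member extraction).
#' @export
setClass("CommunityModel",
  contains = "MetabolicModel",
  representation(
    speciesIndex = "data.frame",
    memberBiomassIds = "character",
    communityBiomassId = "character",
    nMembers = "integer",
    memberExchanges = "list"
  )
)

setValidity("CommunityModel", function(object) {
  msg <- character()
  if (length(object@communityBiomassId) != 1L)
    msg <- c(msg, "communityBiomassId must be a single id")
  if (!object@communityBiomassId %in% object@reactions$id)
    msg <- c(msg, "communityBiomassId not among reactions")
  if (object@nMembers < 1L) msg <- c(msg, "nMembers must be >= 1")
  if (length(msg)) msg else TRUE
})

#' MediaCondition: a growth environment
#'
#' Allowed extracellular compounds with maximum uptake and excretion fluxes
#' (mmol/gDW/h). Applying a media to a model sets the bounds of its exchange
#' reactions: compounds absent from the media cannot be taken up.
#'
#' @slot name media name.
#' @slot entries data.frame with columns `compound`, `max_uptake`,
#'   `max_excretion` (both >= 0).
#' @export
setClass("MediaCondition",
  representation(name = "character", entries = "data.frame")
)

setValidity("MediaCondition", function(object) {
  e <- object@entries
  msg <- character()
  if (!all(c("compound", "max_uptake", "max_excretion") %in% names(e)))
    return("entries needs columns compound, max_uptake, max_excretion")
  if (anyDuplicated(e$compound)) msg <- c(msg, "duplicate compounds in media")
  if (any(e$max_uptake < 0) || any(e$max_excretion < 0))
    msg <- c(msg, "uptake/excretion limits must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ReactionDatabase: candidate reactions for gapfilling
#'
#' Template reactions not yet bound to a compartment: each stoichiometry
#' entry names a compound plus a role ("c" cytosolic, "e" extracellular),
#' and is instantiated into a concrete compartment when offered to the
#' gapfiller. Compounds listed in `transporterCompounds` additionally
#' generate one reversible uniport candidate (cytosol <-> e0) per species.
#'
#' @slot reactions data.frame `id`, `name`, `lb`, `ub`, `pathway`.
#' @slot stoich long data.frame `reaction`, `compound`, `role`, `coef`.
#' @slot compounds data.frame `id`, `name`, `formula`, `charge`.
#' @slot transporterCompounds compounds with a transporter template.
#' @slot costs named numeric, cost > 0 per database entry (default 1).
#' @export
setClass("ReactionDatabase",
  representation(
    reactions = "data.frame",
    stoich = "data.frame",
    compounds = "data.frame",
    transporterCompounds = "character",
    costs = "numeric"
  )
)

setValidity("ReactionDatabase", function(object) {
  msg <- character()
  if (any(object@costs <= 0)) msg <- c(msg, "costs must be > 0")
  if (!all(object@stoich$reaction %in% object@reactions$id))
    msg <- c(msg, "stoich references unknown reaction")
  if (!all(names(object@costs) %in%
           c(object@reactions$id,
             paste0("TPT_", object@transporterCompounds, recycle0 = TRUE))))
    msg <- c(msg, "cost for unknown candidate")
  if (length(msg)) msg else TRUE
})

#' FluxSolution: result of an FBA-type optimization
#'
#' @slot status "optimal" or "infeasible".
#' @slot objective objective flux at the optimum (NA when infeasible).
#' @slot fluxes named flux vector (mmol/gDW/h), one entry per reaction.
#' @slot objectiveId reaction that was optimized.
#' @export
setClass("FluxSolution",
  representation(
    status = "character",
    objective = "numeric",
    fluxes = "numeric",
    objectiveId = "character"
  )
)

#' GapfillResult: reactions added to restore growth
#'
#' @slot additions data.frame `id` (database entry), `reaction_id` (id in
#'   the repaired model), `compartment`, `direction` ("fwd" or "rev"),
#'   `cost`.
#' @slot totalCost summed cost of the additions.
#' @slot strategy provenance label ("igf", "cgf" or "igf+cgf").
#' @slot media media name the target objective was restored on.
#' @slot objectiveValue biomass flux achieved after integration.
#' @slot model the repaired model (added reactions carry
#'   `source_tag = "gapfilled"`).
#' @export
setClass("GapfillResult",
  representation(
    additions = "data.frame",
    totalCost = "numeric",
    strategy = "character",
    media = "character",
    objectiveValue = "numeric",
    model = "MetabolicModel"
  )
)

#' ExpressionProfile: per-gene expression with on/off calls
#'
#' Gene activity is thresholded at a percentile of the expression values of
#' a set of universally active housekeeping roles; genes at or above the
#' threshold are "on", below are "off", absent from the table are "unknown".
#'
#' @slot values named nonnegative expression values.
#' @slot universalGenes gene ids of the universal-role set.
#' @slot percentile percentile used for the threshold (default 10).
#' @slot threshold derived expression threshold.
#' @slot calls named character: "on" / "off" per profiled gene.
#' @export
setClass("ExpressionProfile",
  representation(
    values = "numeric",
    universalGenes = "character",
    percentile = "numeric",
    threshold = "numeric",
    calls = "character"
  )
)

#' ConsistencyReport: flux/expression confusion matrix
#'
#' Four-category breakdown of reactions with a defined activity call:
#' flux and expression (+F+E), neither (-F-E), flux without expression
#' (+F-E), expression without flux (-F+E); plus the derived accuracies and
#' a per-pathway tally that additionally counts active gapfilled reactions.
#'
#' @slot counts named integer, the four category counts.
#' @slot percentages named numeric, the four categories as % of classified
#'   reactions.
#' @slot accuracies named numeric: `active`, `inactive`, `overall` (%).
#' @slot nClassified number of reactions with a defined activity call.
#' @slot pathways data.frame per-pathway counts of the five categories.
#' @export
setClass("ConsistencyReport",
  representation(
    counts = "integer",
    percentages = "numeric",
    accuracies = "numeric",
    nClassified = "integer",
    pathways = "data.frame"
  )
)
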