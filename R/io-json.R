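# Native flat-JSON model dialect. Schema (all fields required unless noted):
#   id            : string
#   compartments  : [{id, label, species_index}]
#   metabolites   : [{id, name, formula|null, charge|null, compartment}]
#   reactions     : [{id, name, lb, ub, gpr, pathway|null, source_tag,
#                     stoichiometry: {metabolite id: coefficient}}]
#   biomass       : [reaction ids]
#   community     : optional block for community models (species_index,
#                   member_biomass_ids, community_biomass_id, n_members,
#                   member_exchanges)

#' Write a model to the native JSON dialect
#'
#' @param model a [MetabolicModel-class] (or [CommunityModel-class]).
#' @param path output path.
#' @export
writeModelJSON <- function(model, path) {
  rx <- model@reactions
  rx_list <- lapply(seq_len(nrow(rx)), function(i) {
    st <- reactionStoich(model, rx$id[i])
    list(id = rx$id[i], name = rx$name[i], lb = rx$lb[i], ub = rx$ub[i],
         gpr = rx$gpr[i], pathway = rx$pathway[i], source_tag = rx$source_tag[i],
         stoichiometry = as.list(st))
  })
  out <- list(
    id = model@id,
    compartments = model@compartments,
    metabolites = model@metabolites,
    reactions = rx_list,
    biomass = as.list(model@biomassIds)
  )
  if (is(model, "CommunityModel")) {
    out$community <- list(
      species_index = model@speciesIndex,
      member_biomass_ids = as.list(model@memberBiomassIds),
      community_biomass_id = model@communityBiomassId,
      n_members = model@nMembers,
      member_exchanges = model@memberExchanges
    )
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", na = "null")
  invisible(path)
}

#' Read a model from the native JSON dialect
#'
#' @param path file path.
#' @return a [MetabolicModel-class], or a [CommunityModel-class] when the
#'   file carries a community block.
#' @export
readModelJSON <- function(path) {
  j <- jsonlite::read_json(path)
  cmp <- do.call(rbind, lapply(j$compartments, function(x)
    data.frame(id = x$id, label = x$label,
               species_index = as.integer(x$species_index %||% 0L),
               stringsAsFactors = FALSE)))
  mets <- do.call(rbind, lapply(j$metabolites, function(x)
    data.frame(id = x$id, name = x$name %||% x$id,
               formula = if (is.null(x$formula)) NA_character_ else x$formula,
               charge = if (is.null(x$charge)) NA_integer_ else as.integer(x$charge),
               compartment = x$compartment, stringsAsFactors = FALSE)))
  rxns <- do.call(rbind, lapply(j$reactions, function(x)
    data.frame(id = x$id, name = x$name %||% x$id,
               lb = as.numeric(x$lb), ub = as.numeric(x$ub),
               gpr = x$gpr %||% "",
               pathway = if (is.null(x$pathway)) NA_character_ else x$pathway,
               source_tag = x$source_tag %||% "draft", stringsAsFactors = FALSE)))
  st <- do.call(rbind, lapply(j$reactions, function(x) {
    if (!length(x$stoichiometry)) return(NULL)
    data.frame(reaction = x$id, metabolite = names(x$stoichiometry),
               coef = as.numeric(unlist(x$stoichiometry)),
               stringsAsFactors = FALSE)
  }))
  model <- MetabolicModel(j$id, cmp, mets, rxns, st,
                          biomassIds = as.character(unlist(j$biomass)))
  if (!is.null(j$community)) {
    co <- j$community
    si <- do.call(rbind, lapply(co$species_index, function(x)
      data.frame(compartment = x$compartment, species = x$species,
                 member_model = x$member_model, stringsAsFactors = FALSE)))
    model <- new("CommunityModel", model,
                 speciesIndex = si,
                 memberBiomassIds = unlist(co$member_biomass_ids),
                 communityBiomassId = co$community_biomass_id,
                 nMembers = as.integer(co$n_members),
                 memberExchanges = lapply(co$member_exchanges,
                                          function(x) as.character(unlist(x))))
  }
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a reaction database to JSON
#'
#' @param db a [ReactionDatabase-class].
#' @param path output path.
#' @export
writeDatabaseJSON <- function(db, path) {
  rx_list <- lapply(seq_len(nrow(db@reactions)), function(i) {
    rid <- db@reactions$id[i]
    st <- db@stoich[db@stoich$reaction == rid, , drop = FALSE]
    list(id = rid, name = db@reactions$name[i],
         lb = db@reactions$lb[i], ub = db@reactions$ub[i],
         pathway = db@reactions$pathway[i],
         cost = unname(db@costs[rid]),
         stoichiometry = lapply(seq_len(nrow(st)), function(k)
           list(compound = st$compound[k], role = st$role[k], coef = st$coef[k])))
  })
  out <- list(reactions = rx_list, compounds = db@compounds,
              transporter_compounds = as.list(db@transporterCompounds),
              transporter_costs = as.list(
                db@costs[paste0("TPT_", db@transporterCompounds)]))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Read a reaction database from JSON
#'
#' @param path file path.
#' @return a [ReactionDatabase-class].
#' @export
readDatabaseJSON <- function(path) {
  j <- jsonlite::read_json(path)
  rxns <- do.call(rbind, lapply(j$reactions, function(x)
    data.frame(id = x$id, name = x$name %||% x$id, lb = as.numeric(x$lb),
               ub = as.numeric(x$ub),
               pathway = if (is.null(x$pathway)) NA_character_ else x$pathway,
               stringsAsFactors = FALSE)))
  st <- do.call(rbind, lapply(j$reactions, function(x)
    do.call(rbind, lapply(x$stoichiometry, function(s)
      data.frame(reaction = x$id, compound = s$compound, role = s$role,
                 coef = as.numeric(s$coef), stringsAsFactors = FALSE)))))
  cpds <- do.call(rbind, lapply(j$compounds, function(x)
    data.frame(id = x$id, name = x$name %||% x$id,
               formula = if (is.null(x$formula)) NA_character_ else x$formula,
               charge = if (is.null(x$charge)) NA_integer_ else as.integer(x$charge),
               stringsAsFactors = FALSE)))
  tpt <- as.character(unlist(j$transporter_compounds))
  costs <- setNames(vapply(j$reactions, function(x)
    as.numeric(x$cost %||% 1), numeric(1)),
    vapply(j$reactions, function(x) x$id, character(1)))
  tc <- unlist(j$transporter_costs)
  tcosts <- setNames(rep(1, length(tpt)), paste0("TPT_", tpt, recycle0 = TRUE))
  if (!is.null(tc)) tcosts[names(tc)] <- as.numeric(tc)
  ReactionDatabase(rxns, st, cpds, tpt, c(costs, tcosts))
}

#' Construct a reaction database
#'
#' @param reactions data.frame `id`, `name`, `lb`, `ub`, `pathway`.
#' @param stoich long data.frame `reaction`, `compound`, `role`
#'   ("c" or "e"), `coef`.
#' @param compounds data.frame `id`, `name`, `formula`, `charge`.
#' @param transporterCompounds compounds for which a reversible uniport
#'   template (cytosol <-> extracellular) is offered.
#' @param costs named costs (> 0) per candidate; database entries default
#'   to 1, transporter templates to 1 ("TPT_<compound>" names).
#' @return a [ReactionDatabase-class].
#' @export
ReactionDatabase <- function(reactions, stoich, compounds,
                             transporterCompounds = character(),
                             costs = NULL) {
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$pathway)) reactions$pathway <- NA_character_
  if (is.null(reactions$lb)) reactions$lb <- -BIG_FLUX
  if (is.null(reactions$ub)) reactions$ub <- BIG_FLUX
  compounds <- normalizeMetaboliteTable(
    cbind(compounds, compartment = "template"))
  compounds$compartment <- NULL
  full <- setNames(rep(1, nrow(reactions) + length(transporterCompounds)),
                   c(reactions$id,
                     paste0("TPT_", transporterCompounds, recycle0 = TRUE)))
  if (!is.null(costs)) full[names(costs)] <- costs
  new("ReactionDatabase", reactions = reactions[
        c("id", "name", "lb", "ub", "pathway")],
      stoich = as.data.frame(stoich, stringsAsFactors = FALSE),
      compounds = compounds, transporterCompounds = transporterCompounds,
      costs = full)
}
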