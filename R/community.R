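# Merging single-species models into community models.
#
# Two architectures: mixed-bag (one shared cytosol "c0"; duplicated
# biochemistry collapses) and compartmentalized (one cytosol "c<i>" per
# member; only the extracellular space "e0" and its exchange reactions are
# shared, so cross-species metabolite transfer is explicit).

# ---- canonical reaction identity -----------------------------------------

# Canonical form of a reaction for duplicate detection: metabolite ids are
# first normalized to community compartments, the reaction is oriented so
# that the lexicographically smallest participating metabolite id carries a
# negative coefficient, and entries are sorted by id. Bounds follow the
# orientation flip. Identity is the hash of (id, coefficient) pairs, not
# the reaction id, so models from different pipelines merge on biochemistry.
canonicalReaction <- function(coefs, lb, ub) {
  o <- order(names(coefs))
  coefs <- coefs[o]
  if (coefs[[1]] > 0) {
    coefs <- -coefs
    tmp <- lb; lb <- -ub; ub <- -tmp
  }
  key <- paste(names(coefs), format(unname(coefs), digits = 12, trim = TRUE),
               sep = ":", collapse = "|")
  list(key = key, coefs = coefs, lb = lb, ub = ub)
}

# strip the compartment suffix from a metabolite id
splitMetId <- function(metId, compartmentIds) {
  for (cc in compartmentIds[order(-nchar(compartmentIds))]) {
    suf <- paste0("_", cc)
    hit <- endsWith(metId, suf)
    if (any(hit)) metId[hit] <- paste0(substr(metId[hit], 1,
      nchar(metId[hit]) - nchar(suf)), "\r", cc)
  }
  parts <- strsplit(metId, "\r", fixed = TRUE)
  data.frame(compound = vapply(parts, `[`, "", 1),
             compartment = vapply(parts, function(p) p[2], ""),
             stringsAsFactors = FALSE)
}

# re-home a member model's metabolite ids into community compartments;
# returns a translation table metabolite id -> community id
memberTranslation <- function(member, cytosolTarget) {
  cmp <- member@compartments
  cyt <- cmp$id[cmp$label == "cytosol"]
  exc <- cmp$id[cmp$label == "extracellular"]
  if (length(exc) != 1L)
    stop("member '", member@id, "' must have exactly one extracellular compartment")
  if (length(cyt) < 1L)
    stop("member '", member@id, "' has no cytosolic compartment")
  mets <- member@metabolites
  sp <- splitMetId(mets$id, cmp$id)
  target <- ifelse(mets$compartment %in% exc, "e0", cytosolTarget)
  data.frame(old = mets$id,
             new = paste0(sp$compound, "_", target),
             compartment = target,
             name = mets$name, formula = mets$formula, charge = mets$charge,
             stringsAsFactors = FALSE)
}

orGPR <- function(gprs) {
  gprs <- unique(gprs[nzchar(gprs)])
  if (length(gprs) == 0L) return("")
  if (length(gprs) == 1L) return(gprs)
  paste(sprintf("(%s)", gprs), collapse = " or ")
}

#' Combine member biomass reactions
#'
#' Sums the stoichiometric coefficients of the member biomass reactions per
#' metabolite and rescales by the number of member models, yielding the
#' single community biomass objective of a mixed-bag model.
#'
#' @param biomassList list of named stoichiometry vectors (metabolite id ->
#'   coefficient), one per member, in a shared metabolite namespace.
#' @param n number of member models (>= 1).
#' @return named numeric: the combined, rescaled stoichiometry.
#' @examples
#' mergeBiomass(list(c(X = -1, ATP = -2, bio = 1),
#'                   c(X = -1, Y = -3, bio = 1)), n = 2)
#' @export
mergeBiomass <- function(biomassList, n) {
  if (n <= 0) stop("n must be >= 1")
  tot <- numeric(0)
  for (st in biomassList) {
    for (m in names(st)) tot[m] <- (if (m %in% names(tot)) tot[m] else 0) + st[[m]]
  }
  out <- tot / n
  out[out != 0]
}

# shared scaffolding: gather per-member translated reaction records
memberRecords <- function(member, trans) {
  rx <- member@reactions
  lapply(seq_len(nrow(rx)), function(i) {
    st <- reactionStoich(member, rx$id[i])
    names(st) <- trans$new[match(names(st), trans$old)]
    st <- tapply(st, names(st), sum)[unique(names(st))]  # merge collided ids
    st <- st[st != 0]
    list(id = rx$id[i], name = rx$name[i], lb = rx$lb[i], ub = rx$ub[i],
         gpr = rx$gpr[i], pathway = rx$pathway[i], tag = rx$source_tag[i],
         stoich = st)
  })
}

communityMetaboliteTable <- function(transList) {
  tab <- do.call(rbind, transList)
  tab <- tab[!duplicated(tab$new), , drop = FALSE]
  data.frame(id = tab$new, name = tab$name, formula = tab$formula,
             charge = tab$charge, compartment = tab$compartment,
             stringsAsFactors = FALSE)
}

#' Merge member models into a mixed-bag community model
#'
#' All cytosolic content is re-homed into a single shared cytosol "c0" and
#' extracellular metabolites into "e0". Reactions with identical canonical
#' stoichiometry collapse into one reaction whose GPR is the OR of the
#' members' rules and whose bounds are the union interval. Member biomass
#' reactions are combined with [mergeBiomass()].
#'
#' @param members list of [MetabolicModel-class] (>= 1).
#' @param id id for the community model.
#' @return list with elements `model` (a [CommunityModel-class]) and
#'   `report` (merge statistics: `duplicates`, `gpr_unions`, `members`
#'   data.frame of reaction counts).
#' @export
buildMixedBag <- function(members, id = "mixed_bag") {
  if (length(members) < 1L) stop("need at least one member model")
  seen <- list()          # key -> index into out
  out <- list()
  bio_sts <- list()
  n_dup <- 0L; n_gpr <- 0L
  transList <- list()
  for (mi in seq_along(members)) {
    member <- members[[mi]]
    trans <- memberTranslation(member, "c0")
    transList[[mi]] <- trans
    recs <- memberRecords(member, trans)
    for (rec in recs) {
      if (rec$id %in% member@biomassIds) {
        bio_sts[[length(bio_sts) + 1L]] <- rec$stoich
        next
      }
      can <- canonicalReaction(rec$stoich, rec$lb, rec$ub)
      if (!is.null(seen[[can$key]])) {
        k <- seen[[can$key]]
        n_dup <- n_dup + 1L
        old_gpr <- out[[k]]$gpr
        out[[k]]$gpr <- orGPR(c(old_gpr, rec$gpr))
        if (!identical(out[[k]]$gpr, old_gpr)) n_gpr <- n_gpr + 1L
        out[[k]]$lb <- min(out[[k]]$lb, can$lb)
        out[[k]]$ub <- max(out[[k]]$ub, can$ub)
      } else {
        rid <- rec$id
        used <- vapply(out, `[[`, "", "id")
        if (rid %in% used) rid <- paste0(rid, "_", member@id)
        seen[[can$key]] <- length(out) + 1L
        out[[length(out) + 1L]] <- list(id = rid, name = rec$name,
          lb = can$lb, ub = can$ub, gpr = rec$gpr, pathway = rec$pathway,
          tag = rec$tag, stoich = can$coefs)
      }
    }
  }
  bio <- mergeBiomass(bio_sts, length(members))
  out[[length(out) + 1L]] <- list(id = "bio_community", name = "community biomass",
    lb = 0, ub = BIG_FLUX, gpr = "", pathway = "biomass", tag = "biomass",
    stoich = bio)

  rxns <- do.call(rbind, lapply(out, function(r)
    data.frame(id = r$id, name = r$name, lb = r$lb, ub = r$ub, gpr = r$gpr,
               pathway = r$pathway, source_tag = r$tag, stringsAsFactors = FALSE)))
  st <- do.call(rbind, lapply(out, function(r)
    data.frame(reaction = r$id, metabolite = names(r$stoich),
               coef = unname(r$stoich), stringsAsFactors = FALSE)))
  cmp <- data.frame(id = c("c0", "e0"), label = c("cytosol", "extracellular"),
                    species_index = c(0L, 0L), stringsAsFactors = FALSE)
  mets <- communityMetaboliteTable(transList)
  base <- MetabolicModel(id, cmp, mets, rxns, st, biomassIds = "bio_community")
  model <- new("CommunityModel", base,
    speciesIndex = data.frame(
      compartment = "c0",
      species = paste(vapply(members, modelId, ""), collapse = "+"),
      member_model = paste(vapply(members, modelId, ""), collapse = "+"),
      stringsAsFactors = FALSE),
    memberBiomassIds = setNames(rep("bio_community", length(members)),
                                vapply(members, modelId, "")),
    communityBiomassId = "bio_community",
    nMembers = length(members),
    memberExchanges = list())
  n_member_rxns <- vapply(members, function(m) nrow(m@reactions), 0L)
  report <- list(
    duplicates = n_dup,
    gpr_unions = n_gpr,
    members = data.frame(member = vapply(members, modelId, ""),
                         reactions_before = n_member_rxns,
                         stringsAsFactors = FALSE),
    reactions_after = nrow(rxns)
  )
  list(model = model, report = report)
}

#' Merge member models into a compartmentalized community model
#'
#' Each member's cytosolic content is re-homed to its own compartment
#' ("c1", "c2", ...); extracellular metabolites merge by compound identity
#' into the shared "e0" and duplicate exchange reactions collapse. Species
#' transporters stay per-compartment. Each member keeps its own biomass
#' reaction, rewritten to produce a species biomass pseudo-metabolite; a
#' community biomass reaction drains 1/N of each (equal weighting by
#' default) and is the default objective, which couples community growth to
#' the growth of every member.
#'
#' @param members list of [MetabolicModel-class] (>= 2).
#' @param id id for the community model.
#' @param weights per-member weights for the community biomass (default
#'   equal 1/N).
#' @return list with elements `model` and `report` as for [buildMixedBag()].
#' @export
buildCompartmentalized <- function(members, id = "consortium", weights = NULL) {
  if (length(members) < 2L)
    stop("compartmentalized merging needs at least two member models")
  n <- length(members)
  if (is.null(weights)) weights <- rep(1 / n, n)
  stopifnot(length(weights) == n, all(weights > 0))

  out <- list(); seen_ex <- list()
  transList <- list(); member_ex <- list()
  bio_ids <- character(n)
  n_dup <- 0L
  extra_mets <- NULL
  for (mi in seq_len(n)) {
    member <- members[[mi]]
    ctag <- paste0("c", mi)
    trans <- memberTranslation(member, ctag)
    transList[[mi]] <- trans
    recs <- memberRecords(member, trans)
    ex_ids <- character(0)
    for (rec in recs) {
      if (rec$tag == "exchange") {
        can <- canonicalReaction(rec$stoich, rec$lb, rec$ub)
        if (!is.null(seen_ex[[can$key]])) {
          k <- seen_ex[[can$key]]
          n_dup <- n_dup + 1L
          out[[k]]$lb <- min(out[[k]]$lb, can$lb)
          out[[k]]$ub <- max(out[[k]]$ub, can$ub)
          ex_ids <- c(ex_ids, out[[k]]$id)
        } else {
          seen_ex[[can$key]] <- length(out) + 1L
          out[[length(out) + 1L]] <- list(id = rec$id, name = rec$name,
            lb = can$lb, ub = can$ub, gpr = rec$gpr, pathway = rec$pathway,
            tag = rec$tag, stoich = can$coefs)
          ex_ids <- c(ex_ids, rec$id)
        }
        next
      }
      rid <- paste0(rec$id, "_sp", mi)
      if (rec$id %in% member@biomassIds) {
        bm_met <- paste0("biomass_sp", mi, "_", ctag)
        rec$stoich[bm_met] <- (if (bm_met %in% names(rec$stoich))
          rec$stoich[[bm_met]] else 0) + 1
        extra_mets <- rbind(extra_mets, data.frame(
          id = bm_met, name = paste0("biomass of member ", member@id),
          formula = NA_character_, charge = NA_integer_, compartment = ctag,
          stringsAsFactors = FALSE))
        bio_ids[mi] <- rid
        rec$tag <- "biomass"
      }
      out[[length(out) + 1L]] <- list(id = rid, name = rec$name,
        lb = rec$lb, ub = rec$ub, gpr = rec$gpr, pathway = rec$pathway,
        tag = rec$tag, stoich = rec$stoich)
    }
    member_ex[[modelId(member)]] <- ex_ids
  }
  # community biomass: drain of the species biomass pseudo-metabolites
  comm_st <- setNames(-weights / sum(weights),
                      paste0("biomass_sp", seq_len(n), "_c", seq_len(n)))
  out[[length(out) + 1L]] <- list(id = "bio_community",
    name = "community biomass", lb = 0, ub = BIG_FLUX, gpr = "",
    pathway = "biomass", tag = "biomass", stoich = comm_st)

  rxns <- do.call(rbind, lapply(out, function(r)
    data.frame(id = r$id, name = r$name, lb = r$lb, ub = r$ub, gpr = r$gpr,
               pathway = r$pathway, source_tag = r$tag, stringsAsFactors = FALSE)))
  st <- do.call(rbind, lapply(out, function(r)
    data.frame(reaction = r$id, metabolite = names(r$stoich),
               coef = unname(r$stoich), stringsAsFactors = FALSE)))
  cmp <- rbind(
    data.frame(id = paste0("c", seq_len(n)), label = "cytosol",
               species_index = seq_len(n), stringsAsFactors = FALSE),
    data.frame(id = "e0", label = "extracellular", species_index = 0L,
               stringsAsFactors = FALSE))
  mets <- rbind(communityMetaboliteTable(transList), extra_mets)
  base <- MetabolicModel(id, cmp, mets, rxns, st, biomassIds = "bio_community")
  model <- new("CommunityModel", base,
    speciesIndex = data.frame(
      compartment = paste0("c", seq_len(n)),
      species = vapply(members, modelId, ""),
      member_model = vapply(members, modelId, ""),
      stringsAsFactors = FALSE),
    memberBiomassIds = setNames(bio_ids, vapply(members, modelId, "")),
    communityBiomassId = "bio_community",
    nMembers = n,
    memberExchanges = member_ex)
  report <- list(
    duplicates = n_dup,
    gpr_unions = 0L,
    members = data.frame(member = vapply(members, modelId, ""),
      reactions_before = vapply(members, function(m) nrow(m@reactions), 0L),
      stringsAsFactors = FALSE),
    reactions_after = nrow(rxns)
  )
  list(model = model, report = report)
}

#' Extract one member model from a compartmentalized community
#'
#' Inverse of [buildCompartmentalized()] for a single member: recovers the
#' member's reactions (ids de-suffixed), its metabolites re-homed to a
#' standalone cytosol "c1", and its own exchange reactions.
#'
#' @param community a compartmentalized [CommunityModel-class].
#' @param member member model id.
#' @return a [MetabolicModel-class].
#' @export
extractMember <- function(community, member) {
  si <- community@speciesIndex
  row <- si[si$member_model == member, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown member '", member, "'")
  ctag <- row$compartment
  mi <- sub("^c", "", ctag)
  suffix <- paste0("_sp", mi)

  rx <- community@reactions
  mine <- endsWith(rx$id, suffix)
  ex_mine <- rx$id %in% community@memberExchanges[[member]]
  keep <- rx[mine | ex_mine, , drop = FALSE]

  bm_met <- paste0("biomass_sp", mi, "_", ctag)
  recs <- lapply(seq_len(nrow(keep)), function(i) {
    st <- reactionStoich(community, keep$id[i])
    st <- st[names(st) != bm_met]
    names(st) <- sub(paste0("_", ctag, "$"), "_c1", names(st))
    rid <- if (endsWith(keep$id[i], suffix))
      substr(keep$id[i], 1, nchar(keep$id[i]) - nchar(suffix)) else keep$id[i]
    tag <- keep$source_tag[i]
    list(id = rid, name = keep$name[i], lb = keep$lb[i], ub = keep$ub[i],
         gpr = keep$gpr[i], pathway = keep$pathway[i], tag = tag, stoich = st)
  })
  rxns <- do.call(rbind, lapply(recs, function(r)
    data.frame(id = r$id, name = r$name, lb = r$lb, ub = r$ub, gpr = r$gpr,
               pathway = r$pathway, source_tag = r$tag, stringsAsFactors = FALSE)))
  st <- do.call(rbind, lapply(recs, function(r)
    data.frame(reaction = r$id, metabolite = names(r$stoich),
               coef = unname(r$stoich), stringsAsFactors = FALSE)))
  used <- unique(st$metabolite)
  mets <- community@metabolites
  mets$id2 <- sub(paste0("_", ctag, "$"), "_c1", mets$id)
  mets <- mets[mets$id2 %in% used & mets$id != bm_met, , drop = FALSE]
  mets$id <- mets$id2; mets$id2 <- NULL
  mets$compartment[mets$compartment == ctag] <- "c1"
  cmp <- data.frame(id = c("c1", "e0"), label = c("cytosol", "extracellular"),
                    species_index = c(1L, 0L), stringsAsFactors = FALSE)
  bio <- community@memberBiomassIds[[member]]
  bio <- substr(bio, 1, nchar(bio) - nchar(suffix))
  MetabolicModel(member, cmp, mets, rxns, st, biomassIds = bio)
}
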