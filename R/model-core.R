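# Construction and core manipulation of MetabolicModel objects.

# default flux bound magnitude (mmol/gDW/h); keeps every LP finite
BIG_FLUX <- 100

VALID_SOURCE_TAGS <- c("draft", "gapfilled", "exchange", "biomass", "transport")

normalizeReactionTable <- function(rxns) {
  rxns <- as.data.frame(rxns, stringsAsFactors = FALSE)
  stopifnot("id" %in% names(rxns))
  n <- nrow(rxns)
  if (is.null(rxns$name)) rxns$name <- rxns$id
  if (is.null(rxns$reversible)) rxns$reversible <- TRUE
  if (is.null(rxns$lb)) rxns$lb <- NA_real_
  if (is.null(rxns$ub)) rxns$ub <- NA_real_
  rxns$lb <- ifelse(is.na(rxns$lb), ifelse(rxns$reversible, -BIG_FLUX, 0), rxns$lb)
  rxns$ub <- ifelse(is.na(rxns$ub), BIG_FLUX, rxns$ub)
  if (is.null(rxns$gpr)) rxns$gpr <- ""
  rxns$gpr[is.na(rxns$gpr)] <- ""
  if (is.null(rxns$pathway)) rxns$pathway <- NA_character_
  if (is.null(rxns$source_tag)) rxns$source_tag <- "draft"
  rownames(rxns) <- NULL
  rxns[c("id", "name", "lb", "ub", "gpr", "pathway", "source_tag")]
}

normalizeMetaboliteTable <- function(mets) {
  mets <- as.data.frame(mets, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "compartment") %in% names(mets)))
  if (is.null(mets$name)) mets$name <- mets$id
  if (is.null(mets$formula)) mets$formula <- NA_character_
  if (is.null(mets$charge)) mets$charge <- NA_integer_
  rownames(mets) <- NULL
  mets[c("id", "name", "formula", "charge", "compartment")]
}

#' Construct a metabolic model
#'
#' Builds a [MetabolicModel-class] from tabular inputs. Stoichiometry is
#' supplied in long form; zero coefficients are dropped so that reaction
#' identity hashing (used when merging community models) sees a canonical
#' form. Unspecified bounds default to (-100, 100) for reversible and
#' (0, 100) for irreversible reactions.
#'
#' @param id model id.
#' @param compartments data.frame with `id`, `label`, `species_index`.
#' @param metabolites data.frame with at least `id` and `compartment`;
#'   optional `name`, `formula`, `charge`.
#' @param reactions data.frame with at least `id`; optional `name`,
#'   `lb`, `ub`, `reversible`, `gpr`, `pathway`, `source_tag`.
#' @param stoich long data.frame `reaction`, `metabolite`, `coef`.
#' @param biomassIds ids of biomass reaction(s).
#' @return a MetabolicModel.
#' @export
MetabolicModel <- function(id, compartments, metabolites, reactions, stoich,
                           biomassIds = character()) {
  mets <- normalizeMetaboliteTable(metabolites)
  rxns <- normalizeReactionTable(reactions)
  compartments <- as.data.frame(compartments, stringsAsFactors = FALSE)
  if (is.null(compartments$species_index)) compartments$species_index <- 0L
  stoich <- stoich[stoich$coef != 0, , drop = FALSE]
  bad_m <- setdiff(stoich$metabolite, mets$id)
  if (length(bad_m))
    stop("stoichiometry references unknown metabolite(s): ",
         paste(bad_m, collapse = ", "))
  bad_r <- setdiff(stoich$reaction, rxns$id)
  if (length(bad_r))
    stop("stoichiometry references unknown reaction(s): ",
         paste(bad_r, collapse = ", "))
  S <- Matrix::sparseMatrix(
    i = match(stoich$metabolite, mets$id),
    j = match(stoich$reaction, rxns$id),
    x = stoich$coef,
    dims = c(nrow(mets), nrow(rxns)),
    dimnames = list(mets$id, rxns$id)
  )
  new("MetabolicModel", id = id, compartments = compartments,
      metabolites = mets, reactions = rxns,
      S = methods::as(Matrix::drop0(S), "CsparseMatrix"),
      biomassIds = biomassIds)
}

#' @describeIn MetabolicModel-class model id
#' @param object a MetabolicModel
#' @export
setMethod("modelId", "MetabolicModel", function(object) object@id)

#' @describeIn MetabolicModel-class reaction table
#' @export
setMethod("reactions", "MetabolicModel", function(object) object@reactions)

#' @describeIn MetabolicModel-class metabolite table
#' @export
setMethod("metabolites", "MetabolicModel", function(object) object@metabolites)

#' @describeIn MetabolicModel-class compartment table
#' @export
setMethod("compartments", "MetabolicModel", function(object) object@compartments)

#' @describeIn MetabolicModel-class sparse stoichiometric matrix
#' @export
setMethod("stoichiometry", "MetabolicModel", function(object) object@S)

#' @describeIn MetabolicModel-class biomass reaction ids
#' @export
setMethod("biomassIds", "MetabolicModel", function(object) object@biomassIds)

#' @describeIn MetabolicModel-class all gene ids appearing in GPR rules
#' @export
setMethod("genes", "MetabolicModel", function(object) {
  sort(unique(unlist(lapply(object@reactions$gpr, gprGenes))))
})

# stoichiometry of one reaction as a named coefficient vector
reactionStoich <- function(model, rid) {
  col <- model@S[, rid]
  col[col != 0]
}

extracellularCompartments <- function(model) {
  model@compartments$id[model@compartments$label == "extracellular"]
}

# reactions touching only extracellular metabolites
isExchangeLike <- function(model) {
  exc <- model@metabolites$id[
    model@metabolites$compartment %in% extracellularCompartments(model)]
  only_e <- rep(FALSE, ncol(model@S))
  if (nrow(model@S)) {
    touches <- abs(model@S) > 0
    n_tot <- Matrix::colSums(touches)
    n_exc <- Matrix::colSums(touches[model@metabolites$id %in% exc, , drop = FALSE])
    only_e <- n_tot > 0 & n_exc == n_tot
  }
  setNames(only_e, model@reactions$id)
}

#' Validate a metabolic model
#'
#' Checks every structural invariant of the data model and returns a
#' character vector of human-readable violations (empty when the model is
#' well formed). Violations are returned rather than raised so that draft
#' models can be inspected and repaired.
#'
#' @param object a [MetabolicModel-class].
#' @return character vector of violation descriptions.
#' @export
setMethod("validateModel", "MetabolicModel", function(object) {
  v <- character()
  cmp <- object@compartments; mets <- object@metabolites; rxns <- object@reactions
  if (anyDuplicated(cmp$id))
    v <- c(v, paste0("duplicate compartment id: ",
                     paste(unique(cmp$id[duplicated(cmp$id)]), collapse = ", ")))
  if (anyDuplicated(mets$id))
    v <- c(v, paste0("duplicate metabolite id: ",
                     paste(unique(mets$id[duplicated(mets$id)]), collapse = ", ")))
  if (anyDuplicated(rxns$id))
    v <- c(v, paste0("duplicate reaction id: ",
                     paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", ")))
  bad_cmp <- setdiff(mets$compartment, cmp$id)
  for (cc in bad_cmp) {
    ms <- mets$id[mets$compartment == cc]
    v <- c(v, paste0("metabolite(s) ", paste(ms, collapse = ", "),
                     " reference undeclared compartment '", cc, "'"))
  }
  n_exc <- sum(cmp$label == "extracellular")
  if (n_exc != 1L)
    v <- c(v, paste0("model must have exactly one extracellular compartment (found ",
                     n_exc, ")"))
  for (i in seq_len(nrow(mets))) {
    f <- mets$formula[i]
    if (!is.na(f)) {
      ok <- tryCatch({ parseFormula(f); TRUE }, error = function(e) FALSE)
      if (!ok) v <- c(v, paste0("metabolite '", mets$id[i],
                                "' has unparseable formula '", f, "'"))
    }
  }
  bad_b <- rxns$id[rxns$lb > rxns$ub]
  for (r in bad_b)
    v <- c(v, paste0("reaction '", r, "' has lower_bound > upper_bound"))
  empty <- rxns$id[Matrix::colSums(abs(object@S) > 0) == 0]
  for (r in empty)
    v <- c(v, paste0("reaction '", r, "' has empty stoichiometry"))
  bad_tag <- rxns$id[!rxns$source_tag %in% VALID_SOURCE_TAGS]
  for (r in bad_tag)
    v <- c(v, paste0("reaction '", r, "' has invalid source_tag"))
  exch <- isExchangeLike(object)
  mism1 <- rxns$id[rxns$source_tag == "exchange" & !exch[rxns$id]]
  for (r in mism1)
    v <- c(v, paste0("reaction '", r,
                     "' tagged exchange but involves intracellular metabolites"))
  mism2 <- rxns$id[rxns$source_tag %in% c("draft", "transport", "gapfilled") &
                     exch[rxns$id]]
  for (r in mism2)
    v <- c(v, paste0("reaction '", r,
                     "' involves only extracellular metabolites but is not tagged exchange"))
  missing_bio <- setdiff(object@biomassIds, rxns$id)
  for (r in missing_bio)
    v <- c(v, paste0("biomass reaction '", r, "' not present in model"))
  if (length(object@biomassIds) < 1L)
    v <- c(v, "model declares no biomass reaction")
  for (i in seq_len(nrow(rxns))) {
    ok <- tryCatch({ parseGPR(rxns$gpr[i]); TRUE }, error = function(e) FALSE)
    if (!ok) v <- c(v, paste0("reaction '", rxns$id[i],
                              "' has unparseable GPR '", rxns$gpr[i], "'"))
  }
  v
})

#' Net elemental balance of a reaction
#'
#' Sums coefficient x element-count over all participating metabolites.
#' An all-zero result means the reaction is elementally balanced. Exchange
#' and biomass reactions are boundary/pseudo reactions and are exempt by
#' convention: for these a zero-length vector is returned.
#'
#' @param model a [MetabolicModel-class].
#' @param reactionId reaction to balance.
#' @return named numeric vector of net element counts (empty for exempt
#'   reactions). Errors if a participating metabolite lacks a formula.
#' @export
elementalBalance <- function(model, reactionId) {
  stopifnot(reactionId %in% model@reactions$id)
  tag <- model@reactions$source_tag[model@reactions$id == reactionId]
  if (tag %in% c("exchange", "biomass"))
    return(structure(numeric(0), exempt = TRUE))
  coefs <- reactionStoich(model, reactionId)
  met_formula <- setNames(model@metabolites$formula, model@metabolites$id)
  formulaBalance(coefs, met_formula)
}

# --- small structural editors used by merging and gapfilling ---------------

addReactionsToModel <- function(model, rxns, stoich, newMets = NULL,
                                newCompartments = NULL) {
  mets <- model@metabolites
  if (!is.null(newMets) && nrow(newMets)) {
    newMets <- normalizeMetaboliteTable(newMets)
    newMets <- newMets[!newMets$id %in% mets$id, , drop = FALSE]
    mets <- rbind(mets, newMets)
  }
  cmp <- model@compartments
  if (!is.null(newCompartments) && nrow(newCompartments)) {
    newCompartments <- newCompartments[!newCompartments$id %in% cmp$id, , drop = FALSE]
    if (nrow(newCompartments)) cmp <- rbind(cmp, newCompartments)
  }
  rxns <- normalizeReactionTable(rxns)
  if (any(rxns$id %in% model@reactions$id))
    stop("reaction id(s) already present: ",
         paste(intersect(rxns$id, model@reactions$id), collapse = ", "))
  all_rxns <- rbind(model@reactions, rxns)
  old_long <- Matrix::summary(model@S)
  long <- data.frame(
    metabolite = c(model@metabolites$id[old_long$i], stoich$metabolite),
    reaction = c(model@reactions$id[old_long$j], stoich$reaction),
    coef = c(old_long$x, stoich$coef),
    stringsAsFactors = FALSE
  )
  out <- MetabolicModel(model@id, cmp, mets, all_rxns, long, model@biomassIds)
  rewrapCommunity(model, out)
}

# keep community bookkeeping when structural edits rebuild the base model
rewrapCommunity <- function(orig, rebuilt) {
  if (!is(orig, "CommunityModel")) return(rebuilt)
  new("CommunityModel", rebuilt,
      speciesIndex = orig@speciesIndex,
      memberBiomassIds = orig@memberBiomassIds,
      communityBiomassId = orig@communityBiomassId,
      nMembers = orig@nMembers,
      memberExchanges = orig@memberExchanges)
}

removeReactionsFromModel <- function(model, ids) {
  keep <- !model@reactions$id %in% ids
  m2 <- model
  m2@reactions <- model@reactions[keep, , drop = FALSE]
  rownames(m2@reactions) <- NULL
  m2@S <- model@S[, keep, drop = FALSE]
  m2@biomassIds <- setdiff(model@biomassIds, ids)
  m2
}

setReactionBounds <- function(model, ids, lb = NULL, ub = NULL) {
  idx <- match(ids, model@reactions$id)
  stopifnot(!anyNA(idx))
  if (!is.null(lb)) model@reactions$lb[idx] <- lb
  if (!is.null(ub)) model@reactions$ub[idx] <- ub
  model
}
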