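# Steady-state LP analyses: FBA, parsimonious FBA, growth calls,
# auxotrophy prediction and interspecies interaction extraction.

GROWTH_THRESHOLD <- 1e-6       # growth-call cutoff on the objective flux
INTERACTION_TOL <- 1e-6        # minimum flux for a reported metabolite transfer

# Build LP data from a model. Variables are ordered lexicographically by
# reaction id so that alternative-optimum tie-breaking is reproducible
# across platforms and member orderings.
modelLP <- function(model) {
  ord <- order(model@reactions$id, method = "radix")
  rx <- model@reactions[ord, , drop = FALSE]
  A <- as.matrix(model@S[, ord, drop = FALSE])
  list(A = A, b = rep(0, nrow(A)), lb = rx$lb, ub = rx$ub, ids = rx$id)
}

#' Run (parsimonious) flux balance analysis
#'
#' Maximizes the objective reaction flux subject to steady-state mass
#' balance (S v = 0) and flux bounds. With `parsimonious = TRUE` a second
#' stage minimizes the total absolute flux while holding the objective at
#' its optimum, removing degenerate flux cycles (pFBA).
#'
#' @param object a [MetabolicModel-class].
#' @param media optional [MediaCondition-class] applied before solving.
#' @param objective objective reaction id (defaults to the first biomass
#'   reaction; for community models, the community biomass).
#' @param parsimonious run the pFBA second stage.
#' @return a [FluxSolution-class].
#' @export
setMethod("runFBA", "MetabolicModel",
          function(object, media = NULL, objective = NULL,
                   parsimonious = FALSE) {
  if (!is.null(media)) object <- applyMedia(object, media)
  if (is.null(objective)) {
    objective <- if (is(object, "CommunityModel")) object@communityBiomassId
                 else object@biomassIds[1]
  }
  lp <- modelLP(object)
  if (!objective %in% lp$ids) stop("objective '", objective, "' not in model")
  n <- length(lp$ids)
  cvec <- as.numeric(lp$ids == objective)
  sol <- solveLP(cvec, lp$A, lp$b, lp$lb, lp$ub, maximize = TRUE)
  if (sol$status != "optimal")
    return(new("FluxSolution", status = "infeasible", objective = NA_real_,
               fluxes = setNames(rep(NA_real_, n), lp$ids),
               objectiveId = objective))
  v <- sol$x
  if (parsimonious) {
    v <- pfbaStage(lp, cvec, sol$objective)
  }
  v[abs(v) < 1e-10] <- 0
  new("FluxSolution", status = "optimal", objective = sol$objective,
      fluxes = setNames(v, lp$ids), objectiveId = objective)
})

# pFBA second stage: minimize total |v| at fixed optimal objective.
# Splits v = p - q with p, q >= 0 (shifted so both parts live in finite
# nonnegative boxes); minimal p + q equals |v| at any vertex optimum.
pfbaStage <- function(lp, cvec, opt) {
  n <- ncol(lp$A)
  p_lb <- pmax(lp$lb, 0); p_ub <- pmax(lp$ub, 0)
  q_lb <- pmax(-lp$ub, 0); q_ub <- pmax(-lp$lb, 0)
  A2 <- cbind(lp$A, -lp$A)
  A2 <- rbind(A2, c(cvec, -cvec))           # objective fixed at its optimum
  b2 <- c(lp$b, opt)
  sol <- solveLP(rep(1, 2 * n), A2, b2, c(p_lb, q_lb), c(p_ub, q_ub),
                 maximize = FALSE)
  if (sol$status != "optimal")
    stop("pFBA stage unexpectedly infeasible")
  sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
}

#' Predict growth on a media
#'
#' @param object a [MetabolicModel-class].
#' @param media a [MediaCondition-class].
#' @param objective objective reaction id (default biomass).
#' @param threshold minimum objective flux called growth (default 1e-6).
#' @return list with `growth` (logical) and `objective` (numeric).
#' @export
setMethod("predictGrowth", "MetabolicModel",
          function(object, media, objective = NULL,
                   threshold = GROWTH_THRESHOLD) {
  sol <- runFBA(object, media, objective = objective)
  obj <- if (sol@status == "optimal") sol@objective else 0
  list(growth = sol@status == "optimal" && obj >= threshold, objective = obj)
})

#' Predict auxotrophies by single-compound dropout
#'
#' For each compound of a rich media in which the model grows, growth is
#' re-tested with that compound's uptake closed. Compounds whose removal
#' abolishes growth are required nutrients (auxotrophies). Interchangeable
#' nutrients (either of two rescuing the other) are not reported.
#'
#' @param object a [MetabolicModel-class].
#' @param media a rich [MediaCondition-class] supporting growth.
#' @param threshold growth-call threshold.
#' @return character vector of required compound ids.
#' @export
setMethod("predictAuxotrophies", "MetabolicModel",
          function(object, media, threshold = GROWTH_THRESHOLD) {
  base <- predictGrowth(object, media, threshold = threshold)
  if (!base$growth)
    stop("model '", object@id, "' does not grow on media '", media@name, "'")
  required <- character(0)
  for (cpd in media@entries$compound) {
    m2 <- media
    m2@entries$max_uptake[m2@entries$compound == cpd] <- 0
    g <- predictGrowth(object, m2, threshold = threshold)
    if (!g$growth) required <- c(required, cpd)
  }
  required
})

# species membership of every reaction in a compartmentalized community:
# the species whose cytosol the reaction touches (NA for exchanges)
reactionSpecies <- function(community) {
  si <- community@speciesIndex
  cyt <- si$compartment
  met_cmp <- setNames(community@metabolites$compartment,
                      community@metabolites$id)
  sp <- rep(NA_character_, nrow(community@reactions))
  tt <- abs(community@S) > 0
  for (k in seq_along(cyt)) {
    mets_k <- community@metabolites$id[met_cmp == cyt[k]]
    hit <- Matrix::colSums(tt[rownames(tt) %in% mets_k, , drop = FALSE]) > 0
    sp[hit] <- si$member_model[k]
  }
  setNames(sp, community@reactions$id)
}

#' Identify interspecies metabolite exchanges
#'
#' Runs parsimonious FBA on the community biomass and, for every
#' extracellular compound, computes each member's net transport flux with
#' the shared extracellular space. A compound is reported as an interaction
#' when one member's net secretion and another member's net uptake both
#' exceed the tolerance; the transfer flux is min(secretion, uptake), so
#' media-supplied consumption without any secretion is never attributed to
#' cross-feeding.
#'
#' @param object a compartmentalized [CommunityModel-class].
#' @param media a [MediaCondition-class] on which the community grows.
#' @param tol interaction tolerance (default 1e-6 flux units).
#' @param mode "pfba" (default; deterministic parsimonious flux pattern) or
#'   "fva" (flux-variability classification: also reports exchanges merely
#'   possible at the optimum, flagged in the `status` column).
#' @return data.frame with columns `compound`, `producer`, `consumer`,
#'   `flux` (and `status` for mode "fva"), sorted by compound.
#' @export
setMethod("identifyInteractions", "CommunityModel",
          function(object, media, tol = INTERACTION_TOL,
                   mode = c("pfba", "fva")) {
  mode <- match.arg(mode)
  cyt <- object@speciesIndex$compartment
  if (length(cyt) < 2L)
    stop("species-resolved interactions need a compartmentalized community model")
  sol <- runFBA(object, media, parsimonious = TRUE)
  if (sol@status != "optimal" || sol@objective < GROWTH_THRESHOLD)
    stop("community '", object@id, "' does not grow on media '",
         media@name, "'")
  model <- applyMedia(object, media)
  spec_of <- reactionSpecies(model)
  members <- unique(object@speciesIndex$member_model)
  e_mets <- model@metabolites$id[model@metabolites$compartment == "e0"]
  flux <- sol@fluxes[model@reactions$id]

  # net secretion of each member into e0, per extracellular metabolite
  net <- matrix(0, length(e_mets), length(members),
                dimnames = list(e_mets, members))
  for (sp in members) {
    rids <- names(spec_of)[!is.na(spec_of) & spec_of == sp]
    if (!length(rids)) next
    net[, sp] <- as.vector(model@S[e_mets, rids, drop = FALSE] %*% flux[rids])
  }
  rows <- list()
  for (met in e_mets) {
    prod <- members[net[met, ] > tol]
    cons <- members[net[met, ] < -tol]
    for (p in prod) for (q in cons) {
      rows[[length(rows) + 1L]] <- data.frame(
        compound = compoundOf(met, "e0"), producer = p, consumer = q,
        flux = min(net[met, p], -net[met, q]), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(compound = character(), producer = character(),
               consumer = character(), flux = numeric(),
               stringsAsFactors = FALSE)
  out <- out[order(out$compound, out$producer), , drop = FALSE]
  rownames(out) <- NULL
  if (mode == "pfba") return(out)

  # FVA mode: range of each member's net transport at the fixed optimum
  out$status <- "obligatory"
  lp <- modelLP(model)
  cvec <- as.numeric(lp$ids == sol@objectiveId)
  A2 <- rbind(lp$A, cvec); b2 <- c(lp$b, sol@objective)
  fva_rows <- list()
  for (met in e_mets) {
    for (sp in members) {
      rids <- names(spec_of)[!is.na(spec_of) & spec_of == sp]
      w <- setNames(rep(0, length(lp$ids)), lp$ids)
      w[rids] <- as.vector(model@S[met, rids, drop = FALSE])
      if (all(w == 0)) next
      hi <- solveLP(unname(w), A2, b2, lp$lb, lp$ub, maximize = TRUE)
      lo <- solveLP(unname(w), A2, b2, lp$lb, lp$ub, maximize = FALSE)
      fva_rows[[paste(met, sp)]] <- data.frame(
        met = met, member = sp, lo = lo$objective, hi = hi$objective,
        stringsAsFactors = FALSE)
    }
  }
  rng <- do.call(rbind, fva_rows)
  for (met in unique(rng$met)) {
    sub <- rng[rng$met == met, , drop = FALSE]
    prod <- sub$member[sub$hi > tol]
    cons <- sub$member[sub$lo < -tol]
    for (p in prod) for (q in cons) {
      if (p == q) next
      key <- out$compound == compoundOf(met, "e0") & out$producer == p &
        out$consumer == q
      if (!any(key)) {
        out <- rbind(out, data.frame(
          compound = compoundOf(met, "e0"), producer = p, consumer = q,
          flux = 0, status = "possible", stringsAsFactors = FALSE))
      }
    }
  }
  out <- out[order(out$compound, out$producer), , drop = FALSE]
  rownames(out) <- NULL
  out
})

#' @describeIn FluxSolution-class flux vector
#' @param object a FluxSolution
#' @export
setMethod("fluxes", "FluxSolution", function(object) object@fluxes)

#' @describeIn FluxSolution-class objective value
#' @export
setMethod("objectiveValue", "FluxSolution", function(object) object@objective)

#' @describeIn FluxSolution-class solver status
#' @export
setMethod("solverStatus", "FluxSolution", function(object) object@status)
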