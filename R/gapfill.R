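# Parsimony gapfilling: add a provably minimal-cost set of candidate
# database reactions so that a target objective becomes feasible on a given
# media. The search is an exact branch-and-bound over candidate sets:
# nodes carry a set of forced-in and forbidden candidates, LP feasibility
# with all remaining candidates open prunes hopeless branches, and a
# parsimonious flux stage picks the branching candidate. Community-level
# gapfilling instantiates the database once per species compartment (plus
# transporter templates linking each cytosol to "e0"), so cross-feeding
# solutions compete with — and, when cheaper, beat — self-sufficiency.

GAPFILL_EPSILON <- 0.01   # biomass flux a repaired model must reach

# ---- candidate instantiation ---------------------------------------------

# Instantiate database reactions (and transporter templates) into concrete
# compartments of a model. Returns the extended model plus a candidate
# table (candidate model-reaction id, database entry, compartment,
# direction, cost).
instantiateCandidates <- function(model, database, compartmentIds,
                                  directed = TRUE) {
  exc <- extracellularCompartments(model)
  cand <- list(); rx_rows <- list(); st_rows <- list()
  new_mets <- list()
  cpd_tab <- database@compounds
  noteMet <- function(cpd, cmp) {
    mid <- paste0(cpd, "_", cmp)
    if (!mid %in% model@metabolites$id) {
      k <- match(cpd, cpd_tab$id)
      new_mets[[mid]] <<- data.frame(
        id = mid, name = if (!is.na(k)) cpd_tab$name[k] else cpd,
        formula = if (!is.na(k)) cpd_tab$formula[k] else NA_character_,
        charge = if (!is.na(k)) cpd_tab$charge[k] else NA_integer_,
        compartment = cmp, stringsAsFactors = FALSE)
    }
    mid
  }
  addCand <- function(entry, cmp, stoich, lb, ub, cost, pathway, tag) {
    if (directed) {
      # skip variants already integrated into the model (iterative rounds)
      if (ub > 0 && !paste0(entry, "_", cmp, "_f") %in% model@reactions$id) {
        rid <- paste0(entry, "_", cmp, "_f")
        rx_rows[[rid]] <<- data.frame(id = rid, name = paste0(entry, " (", cmp, ")"),
          lb = 0, ub = ub, gpr = "", pathway = pathway, source_tag = tag,
          stringsAsFactors = FALSE)
        st_rows[[rid]] <<- data.frame(reaction = rid, metabolite = names(stoich),
          coef = unname(stoich), stringsAsFactors = FALSE)
        cand[[rid]] <<- data.frame(candidate = rid, entry = entry,
          compartment = cmp, direction = "fwd", cost = cost,
          stringsAsFactors = FALSE)
      }
      if (lb < 0 && !paste0(entry, "_", cmp, "_r") %in% model@reactions$id) {
        rid <- paste0(entry, "_", cmp, "_r")
        rx_rows[[rid]] <<- data.frame(id = rid, name = paste0(entry, " (", cmp, ", reverse)"),
          lb = 0, ub = -lb, gpr = "", pathway = pathway, source_tag = tag,
          stringsAsFactors = FALSE)
        st_rows[[rid]] <<- data.frame(reaction = rid, metabolite = names(stoich),
          coef = -unname(stoich), stringsAsFactors = FALSE)
        cand[[rid]] <<- data.frame(candidate = rid, entry = entry,
          compartment = cmp, direction = "rev", cost = cost,
          stringsAsFactors = FALSE)
      }
    } else {
      rid <- paste0(entry, "_", cmp)
      if (rid %in% model@reactions$id) return(invisible())
      rx_rows[[rid]] <<- data.frame(id = rid, name = paste0(entry, " (", cmp, ")"),
        lb = lb, ub = ub, gpr = "", pathway = pathway, source_tag = tag,
        stringsAsFactors = FALSE)
      st_rows[[rid]] <<- data.frame(reaction = rid, metabolite = names(stoich),
        coef = unname(stoich), stringsAsFactors = FALSE)
      cand[[rid]] <<- data.frame(candidate = rid, entry = entry,
        compartment = cmp, direction = "both", cost = cost,
        stringsAsFactors = FALSE)
    }
  }

  for (cmp in compartmentIds) {
    for (i in seq_len(nrow(database@reactions))) {
      entry <- database@reactions$id[i]
      st <- database@stoich[database@stoich$reaction == entry, , drop = FALSE]
      mids <- vapply(seq_len(nrow(st)), function(k)
        noteMet(st$compound[k], if (st$role[k] == "e") exc else cmp), "")
      stoich <- setNames(st$coef, mids)
      addCand(entry, cmp, stoich, database@reactions$lb[i],
              database@reactions$ub[i], unname(database@costs[entry]),
              database@reactions$pathway[i], "gapfilled")
    }
    for (cpd in database@transporterCompounds) {
      entry <- paste0("TPT_", cpd)
      stoich <- setNames(c(-1, 1), c(noteMet(cpd, cmp), noteMet(cpd, exc)))
      addCand(entry, cmp, stoich, -BIG_FLUX, BIG_FLUX,
              unname(database@costs[entry]), "transport", "gapfilled")
      # (transporter candidates are tagged "gapfilled" like all additions;
      # their pathway field records "transport")
    }
  }
  cand_tab <- do.call(rbind, cand)
  rx <- do.call(rbind, rx_rows)
  st <- do.call(rbind, st_rows)
  mets <- do.call(rbind, new_mets)
  ext <- addReactionsToModel(model, rx, st, newMets = mets)
  # exchanges (closed to uptake) for any extracellular metabolite the
  # candidates introduced, so excretion never blocks a repair
  ext <- applyMedia(ext, MediaCondition("noop", character(0)))
  list(model = ext, candidates = cand_tab)
}

# LP context for repeated feasibility tests with varying open candidates
gapfillContext <- function(model, database, media, objective, compartmentIds,
                           directed = TRUE) {
  inst <- instantiateCandidates(model, database, compartmentIds,
                                directed = directed)
  ext <- applyMedia(inst$model, media)
  lp <- modelLP(ext)
  cand_idx <- match(inst$candidates$candidate, lp$ids)
  list(lp = lp, candidates = inst$candidates, cand_idx = cand_idx,
       obj_idx = match(objective, lp$ids), model = ext, objective = objective)
}

# maximize the objective with only `open` candidate columns available
ctxSolve <- function(ctx, open) {
  lb <- ctx$lp$lb; ub <- ctx$lp$ub
  closed <- setdiff(seq_along(ctx$cand_idx), open)
  lb[ctx$cand_idx[closed]] <- 0
  ub[ctx$cand_idx[closed]] <- 0
  cvec <- numeric(length(ctx$lp$ids)); cvec[ctx$obj_idx] <- 1
  solveLP(cvec, ctx$lp$A, ctx$lp$b, lb, ub, maximize = TRUE)
}

ctxFeasible <- function(ctx, open, epsilon) {
  sol <- ctxSolve(ctx, open)
  sol$status == "optimal" && sol$objective >= epsilon - 1e-9
}

# parsimonious support at objective = epsilon, used to pick branching
# candidates: which open candidates carry flux in a solution that reaches
# the target with minimal total candidate flux? Directed candidate columns
# are nonnegative, so their flux is minimized directly (no |v| split).
ctxSupport <- function(ctx, open, epsilon) {
  lb <- ctx$lp$lb; ub <- ctx$lp$ub
  closed <- setdiff(seq_along(ctx$cand_idx), open)
  lb[ctx$cand_idx[closed]] <- 0
  ub[ctx$cand_idx[closed]] <- 0
  n <- length(lb)
  obj_row <- numeric(n); obj_row[ctx$obj_idx] <- 1
  A2 <- rbind(ctx$lp$A, obj_row)
  b2 <- c(ctx$lp$b, epsilon)
  cvec <- numeric(n)
  cvec[ctx$cand_idx] <- 1
  sol <- solveLP(cvec, A2, b2, lb, ub)
  if (sol$status != "optimal") return(integer(0))
  open[abs(sol$x[ctx$cand_idx[open]]) > 1e-7]
}

# drop redundant members of a feasible candidate set (lexicographic order)
reduceSet <- function(ctx, set, epsilon) {
  for (e in sort(ctx$candidates$candidate[set])) {
    k <- which(ctx$candidates$candidate == e)
    if (length(setdiff(set, k)) == length(set)) next
    trial <- setdiff(set, k)
    if (ctxFeasible(ctx, trial, epsilon)) set <- trial
  }
  set
}

# deterministic order on candidate sets for tie-breaking among equal-cost
# optima: lexicographically smallest sorted (compartment, entry, direction)
candKey <- function(ctx, set) {
  tab <- ctx$candidates[set, , drop = FALSE]
  paste(sort(paste(tab$compartment, tab$entry, tab$direction)), collapse = ";")
}

# exact branch-and-bound over candidate sets
gapfillSearch <- function(ctx, epsilon, node_cap = 50000L) {
  costs <- ctx$candidates$cost
  ncand <- nrow(ctx$candidates)
  best <- list(cost = Inf, set = NULL, key = "")
  nodes <- 0L

  if (!ctxFeasible(ctx, seq_len(ncand), epsilon))
    stop("no gapfill solution: objective unreachable even with the full database")

  recurse <- function(forced, forbidden) {
    nodes <<- nodes + 1L
    if (nodes > node_cap) stop("gapfill search exceeded the node cap")
    base_cost <- sum(costs[forced])
    open <- setdiff(seq_len(ncand), c(forced, forbidden))
    if (ctxFeasible(ctx, forced, epsilon)) {
      red <- reduceSet(ctx, forced, epsilon)
      cst <- sum(costs[red]); key <- candKey(ctx, red)
      if (cst < best$cost - 1e-9 ||
          (cst < best$cost + 1e-9 && key < best$key)) {
        best <<- list(cost = cst, set = red, key = key)
      }
      return(invisible())
    }
    lbnd <- base_cost + if (length(open)) min(costs[open]) else Inf
    if (lbnd > best$cost + 1e-9) return(invisible())
    if (!length(open)) return(invisible())
    if (!ctxFeasible(ctx, c(forced, open), epsilon)) return(invisible())
    sup <- ctxSupport(ctx, c(forced, open), epsilon)
    sup <- setdiff(sup, forced)
    e <- if (length(sup)) {
      sup[order(ctx$candidates$candidate[sup])][1L]
    } else {
      open[order(ctx$candidates$candidate[open])][1L]
    }
    recurse(c(forced, e), forbidden)
    recurse(forced, c(forbidden, e))
    invisible()
  }
  recurse(integer(0), integer(0))
  if (!is.finite(best$cost))
    stop("no gapfill solution: objective unreachable even with the full database")
  best
}

# integrate chosen directed candidates into the original model
integrateAdditions <- function(model, ctx, set) {
  if (!length(set)) return(model)
  ids <- ctx$candidates$candidate[set]
  keep_rx <- ctx$model@reactions[match(ids, ctx$model@reactions$id), , drop = FALSE]
  st <- do.call(rbind, lapply(ids, function(rid) {
    s <- reactionStoich(ctx$model, rid)
    data.frame(reaction = rid, metabolite = names(s), coef = unname(s),
               stringsAsFactors = FALSE)
  }))
  used_mets <- unique(st$metabolite)
  new_mets <- ctx$model@metabolites[
    ctx$model@metabolites$id %in% setdiff(used_mets, model@metabolites$id), ,
    drop = FALSE]
  out <- addReactionsToModel(model, keep_rx, st, newMets = new_mets)
  # open exchanges for any extracellular metabolites the additions introduced
  applyMedia(out, MediaCondition("noop", character(0)))
}

gapfillResultFrom <- function(model, ctx, best, strategy, media, epsilon) {
  add_tab <- ctx$candidates[best$set, , drop = FALSE]
  add_tab <- add_tab[order(add_tab$compartment, add_tab$entry, add_tab$direction), ,
                     drop = FALSE]
  repaired <- integrateAdditions(model, ctx, best$set)
  sol <- runFBA(repaired, media, objective = ctx$objective)
  if (sol@status != "optimal" || sol@objective < epsilon - 1e-9)
    stop("internal error: integrated gapfill solution does not reach the target")
  additions <- data.frame(
    id = add_tab$entry, reaction_id = add_tab$candidate,
    compartment = add_tab$compartment, direction = add_tab$direction,
    cost = add_tab$cost, stringsAsFactors = FALSE)
  rownames(additions) <- NULL
  new("GapfillResult", additions = additions, totalCost = sum(add_tab$cost),
      strategy = strategy, media = media@name, objectiveValue = sol@objective,
      model = repaired)
}

#' Gapfill a model on a media condition
#'
#' Finds a provably minimal-cost set of database reactions (instantiated in
#' the model's cytosol, plus transporter/exchange templates when the
#' database provides them) whose addition raises the objective flux to at
#' least `epsilon` on the given media. The search is exact; ties among
#' equal-cost optima are broken by the lexicographically smallest
#' (compartment, reaction, direction) set. Reversible database reactions
#' are offered as two directed candidates, each at the entry's cost.
#'
#' @param object a [MetabolicModel-class] that may fail to grow.
#' @param database a [ReactionDatabase-class].
#' @param media a [MediaCondition-class].
#' @param objective objective reaction id (default: first biomass reaction).
#' @param epsilon target objective flux (default 0.01; deliberately above
#'   the 1e-6 growth-call threshold so repairs do not rely on numerically
#'   marginal flux).
#' @param strategy provenance label recorded in the result.
#' @return a [GapfillResult-class]; empty additions if the model already
#'   reaches the target. Errors when even the full database cannot restore
#'   growth.
#' @export
setMethod("gapfill", "MetabolicModel",
          function(object, database, media, objective = NULL,
                   epsilon = GAPFILL_EPSILON, strategy = "igf") {
  if (is.null(objective)) objective <- object@biomassIds[1]
  cyt <- object@compartments$id[object@compartments$label == "cytosol"]
  if (length(cyt) != 1L)
    stop("gapfill targets a single-cytosol model; use communityGapfill ",
         "for community models")
  ctx <- gapfillContext(object, database, media, objective, cyt)
  if (ctxFeasible(ctx, integer(0), epsilon)) {
    sol <- runFBA(object, media, objective = objective)
    return(new("GapfillResult",
               additions = data.frame(id = character(), reaction_id = character(),
                 compartment = character(), direction = character(),
                 cost = numeric(), stringsAsFactors = FALSE),
               totalCost = 0, strategy = strategy, media = media@name,
               objectiveValue = sol@objective, model = object))
  }
  best <- gapfillSearch(ctx, epsilon)
  gapfillResultFrom(object, ctx, best, strategy, media, epsilon)
})

#' Gapfill a community model
#'
#' Community-level gapfilling: the candidate database is instantiated once
#' per species compartment (and transporter templates link every cytosol to
#' the shared extracellular space), so the search may delegate a metabolic
#' function to a partner species whenever the cross-feeding solution is
#' cheaper than self-sufficiency. The objective is the community biomass.
#'
#' @param object a [CommunityModel-class] (mixed-bag or compartmentalized).
#' @param database a [ReactionDatabase-class].
#' @param media a [MediaCondition-class].
#' @param epsilon target community biomass flux (default 0.01).
#' @param strategy provenance label recorded in the result.
#' @return a [GapfillResult-class] whose additions carry their target
#'   compartment.
#' @export
setMethod("communityGapfill", "CommunityModel",
          function(object, database, media, epsilon = GAPFILL_EPSILON,
                   strategy = "cgf") {
  cyt <- object@compartments$id[object@compartments$label == "cytosol"]
  objective <- object@communityBiomassId
  ctx <- gapfillContext(object, database, media, objective, cyt)
  if (ctxFeasible(ctx, integer(0), epsilon)) {
    sol <- runFBA(object, media, objective = objective)
    return(new("GapfillResult",
               additions = data.frame(id = character(), reaction_id = character(),
                 compartment = character(), direction = character(),
                 cost = numeric(), stringsAsFactors = FALSE),
               totalCost = 0, strategy = strategy, media = media@name,
               objectiveValue = sol@objective, model = object))
  }
  best <- gapfillSearch(ctx, epsilon)
  gapfillResultFrom(object, ctx, best, strategy, media, epsilon)
})

#' Gapfill iteratively on multiple media conditions
#'
#' Gapfills on the first media, integrates the additions (whose cost is
#' sunk thereafter), then proceeds to the next media, so the final model
#' grows on every listed condition.
#'
#' @param object a [MetabolicModel-class].
#' @param database a [ReactionDatabase-class].
#' @param mediaList list of [MediaCondition-class].
#' @param ... passed to [gapfill()].
#' @return list of [GapfillResult-class], one per media; the last result's
#'   model grows on all of them.
#' @export
setMethod("gapfillIterative", "MetabolicModel",
          function(object, database, mediaList, ...) {
  if (!length(mediaList)) stop("mediaList must be non-empty")
  out <- list()
  cur <- object
  for (media in mediaList) {
    res <- gapfill(cur, database, media, ...)
    cur <- res@model
    out[[media@name]] <- res
  }
  out
})

#' Brute-force gapfilling oracle
#'
#' Enumerates candidate database entries (each offered with its native
#' reversibility) in order of increasing subset cost and returns all
#' minimum-cost subsets whose addition reaches the target objective.
#' Intended as an exhaustive correctness oracle for [gapfill()] on small
#' databases; guarded to at most 15 candidates.
#'
#' @param model a [MetabolicModel-class].
#' @param database a [ReactionDatabase-class].
#' @param media a [MediaCondition-class].
#' @param objective objective reaction id (default first biomass).
#' @param epsilon target objective flux.
#' @param max_size largest subset cardinality to consider.
#' @param compartment cytosolic compartment to instantiate into (default:
#'   the model's single cytosol).
#' @return list of character vectors (entry ids per minimal solution);
#'   a single empty vector when the model already grows; an empty list when
#'   the target is unreachable within `max_size`.
#' @export
bruteForceGapfill <- function(model, database, media, objective = NULL,
                              epsilon = GAPFILL_EPSILON, max_size = 6L,
                              compartment = NULL) {
  if (is.null(objective)) objective <- model@biomassIds[1]
  if (is.null(compartment)) {
    compartment <- model@compartments$id[model@compartments$label == "cytosol"]
    stopifnot(length(compartment) >= 1L)
  }
  ctx <- gapfillContext(model, database, media, objective, compartment,
                        directed = FALSE)
  ncand <- nrow(ctx$candidates)
  if (ncand > 15L * length(compartment))
    stop("brute-force guard: more than 15 candidate entries per compartment")
  if (ctxFeasible(ctx, integer(0), epsilon)) return(list(character(0)))
  costs <- ctx$candidates$cost
  subsets <- list(); subcost <- numeric(0)
  for (k in seq_len(min(max_size, ncand))) {
    cmb <- combn(ncand, k, simplify = FALSE)
    subsets <- c(subsets, cmb)
    subcost <- c(subcost, vapply(cmb, function(s) sum(costs[s]), 0))
  }
  ord <- order(subcost, vapply(subsets, function(s)
    candKey(ctx, s), ""), method = "radix")
  best <- Inf; sols <- list()
  for (k in ord) {
    s <- subsets[[k]]
    if (subcost[k] > best + 1e-9) break
    if (ctxFeasible(ctx, s, epsilon)) {
      best <- min(best, subcost[k])
      sols[[length(sols) + 1L]] <- sort(ctx$candidates$entry[s])
    }
  }
  sols
}

#' Build a community model under one of three gapfilling strategies
#'
#' Strategy "A" (pre-gapfilling / igf): each member is gapfilled alone on
#' its own media, then the repaired members are merged; no community
#' gapfilling. Strategy "B" (community gapfilling / cgf): the ungapfilled
#' drafts are merged and the community model is gapfilled on the community
#' media. Strategy "C": members are pre-gapfilled on a (rich) media, merged
#' and the community is post-gapfilled on the community media.
#'
#' @param members list of [MetabolicModel-class] drafts.
#' @param database a [ReactionDatabase-class].
#' @param memberMedia list of [MediaCondition-class], one per member
#'   (strategies A and C), or a single media recycled to all members.
#' @param communityMedia [MediaCondition-class] for community gapfilling.
#' @param strategy "A", "B" or "C".
#' @param mode community architecture, "compartments" (default) or "mixed".
#' @param epsilon target objective flux for every gapfill.
#' @return list with `model` (the final [CommunityModel-class]) and
#'   `results` (all [GapfillResult-class] objects, named by stage).
#' @export
runStrategy <- function(members, database, memberMedia = NULL,
                        communityMedia = NULL, strategy = c("A", "B", "C"),
                        mode = c("compartments", "mixed"),
                        epsilon = GAPFILL_EPSILON) {
  strategy <- match.arg(strategy)
  mode <- match.arg(mode)
  if (strategy %in% c("A", "C")) {
    if (is.null(memberMedia)) stop("strategies A and C need memberMedia")
    if (is(memberMedia, "MediaCondition"))
      memberMedia <- rep(list(memberMedia), length(members))
  }
  if (strategy %in% c("B", "C") && is.null(communityMedia))
    stop("strategies B and C need communityMedia")
  results <- list()
  if (strategy %in% c("A", "C")) {
    for (i in seq_along(members)) {
      res <- tryCatch(
        gapfill(members[[i]], database, memberMedia[[i]], epsilon = epsilon,
                strategy = "igf"),
        error = function(e)
          stop("pre-gapfilling of member '", modelId(members[[i]]),
               "' on media '", memberMedia[[i]]@name, "' failed (",
               conditionMessage(e),
               "); the pre-gapfilling strategy is ineffective here"))
      results[[paste0("igf_", modelId(members[[i]]))]] <- res
      members[[i]] <- res@model
    }
  }
  built <- if (mode == "mixed") buildMixedBag(members)
           else buildCompartmentalized(members)
  model <- built$model
  if (strategy %in% c("B", "C")) {
    res <- communityGapfill(model, database, communityMedia, epsilon = epsilon,
                            strategy = if (strategy == "B") "cgf" else "igf+cgf")
    results[[paste0("cgf_", mode)]] <- res
    model <- res@model
  }
  list(model = model, results = results, report = built$report)
}

#' @describeIn GapfillResult-class the added reactions
#' @param object a GapfillResult
#' @export
setMethod("addedReactions", "GapfillResult", function(object) object@additions)

#' @describeIn GapfillResult-class total cost of the additions
#' @export
setMethod("totalCost", "GapfillResult", function(object) object@totalCost)
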