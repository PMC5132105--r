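# Expression integration: on/off gene calls from a housekeeping-percentile
# threshold, three-valued reaction activity through GPR rules, flux fitting
# to activity calls (transcriptomic FBA), and flux/expression consistency
# reports.

FLUX_ACTIVITY_DELTA <- 1e-3   # |flux| at or above this counts as "flux on"

#' Call genes on/off from expression values
#'
#' The threshold is the given percentile (linear interpolation between
#' order statistics, so the k-th of n sorted values sits at quantile
#' (k-1)/(n-1)) of the expression values of a set of universally active
#' housekeeping genes. Genes at or above the threshold are "on", below are
#' "off"; genes absent from the table are unknown.
#'
#' @param values named nonnegative expression values (gene id -> value).
#' @param universalGenes gene ids of universally active roles; at least two
#'   must be present in `values`.
#' @param percentile percentile of the universal-role values used as the
#'   threshold (default 10).
#' @return an [ExpressionProfile-class].
#' @export
callGeneActivity <- function(values, universalGenes, percentile = 10) {
  ug <- intersect(universalGenes, names(values))
  if (length(ug) < 2L)
    stop("need at least two universal-role genes with expression values (found ",
         length(ug), ")")
  if (any(values < 0)) stop("expression values must be nonnegative")
  thr <- unname(quantile(values[ug], percentile / 100, type = 7, names = FALSE))
  calls <- ifelse(values >= thr, "on", "off")
  new("ExpressionProfile", values = values, universalGenes = universalGenes,
      percentile = percentile, threshold = thr,
      calls = setNames(as.character(calls), names(values)))
}

#' @describeIn ExpressionProfile-class per-gene on/off calls
#' @param object an ExpressionProfile
#' @export
setMethod("activityCalls", "ExpressionProfile", function(object) object@calls)

#' @describeIn ExpressionProfile-class derived expression threshold
#' @export
setMethod("activityThreshold", "ExpressionProfile",
          function(object) object@threshold)

#' Reaction activity from gene activity
#'
#' Three-valued GPR evaluation: an OR is active if any input is on, an AND
#' only if all are; a decisive unknown gene propagates to unknown.
#' Reactions without a GPR (including gapfilled, exchange and biomass
#' reactions) are unknown.
#'
#' @param model a [MetabolicModel-class].
#' @param profile an [ExpressionProfile-class] (or a named character vector
#'   of "on"/"off" calls).
#' @return named character vector: "active", "inactive" or "unknown" per
#'   reaction.
#' @export
reactionActivity <- function(model, profile) {
  calls <- if (is(profile, "ExpressionProfile")) profile@calls else profile
  out <- vapply(model@reactions$gpr, function(g) {
    v <- evalGPR(g, calls)
    if (is.na(v)) "unknown"
    else if (v == "on") "active"
    else if (v == "off") "inactive"
    else "unknown"
  }, character(1))
  setNames(out, model@reactions$id)
}

# ---- transcriptomic FBA ---------------------------------------------------

# Bounds implementing enforcement of one classified reaction:
#   inactive: v = 0;  active: |v| >= delta (direction dir for reversibles)
enforceBounds <- function(lb, ub, idx, what, delta, dir = NA) {
  if (what == "inactive") {
    lb[idx] <- 0; ub[idx] <- 0
  } else {
    if (lb[idx] >= 0) lb[idx] <- max(lb[idx], delta)
    else if (ub[idx] <= 0) ub[idx] <- min(ub[idx], -delta)
    else if (identical(dir, "rev")) ub[idx] <- -delta
    else lb[idx] <- delta
  }
  list(lb = lb, ub = ub)
}

# Is enforcing the classified set E feasible (objective >= epsilon)?
# Reversible active reactions require a direction; the few of them are
# explored by depth-first search. Returns NULL or the direction assignment.
enforceFeasible <- function(lp, obj_idx, E, act, delta, epsilon) {
  rev_active <- E[act[E] == "active" & lp$lb[match(E, lp$ids)] < 0 &
                    lp$ub[match(E, lp$ids)] > 0]
  fixed <- E[!E %in% rev_active]
  baseBounds <- function(dirs) {
    lb <- lp$lb; ub <- lp$ub
    for (r in fixed) {
      bb <- enforceBounds(lb, ub, match(r, lp$ids), act[[r]], delta)
      lb <- bb$lb; ub <- bb$ub
    }
    for (r in names(dirs)) {
      bb <- enforceBounds(lb, ub, match(r, lp$ids), "active", delta, dirs[[r]])
      lb <- bb$lb; ub <- bb$ub
    }
    lb[obj_idx] <- max(lb[obj_idx], epsilon)
    list(lb = lb, ub = ub)
  }
  try_dirs <- function(dirs, rest) {
    bb <- baseBounds(dirs)
    cvec <- numeric(length(lp$ids)); cvec[obj_idx] <- 1
    sol <- solveLP(cvec, lp$A, lp$b, bb$lb, bb$ub, maximize = TRUE)
    if (sol$status != "optimal") return(NULL)
    if (!length(rest)) return(dirs)
    r <- rest[1L]
    for (d in c("fwd", "rev")) {
      res <- try_dirs(c(dirs, setNames(d, r)), rest[-1L])
      if (!is.null(res)) return(res)
    }
    NULL
  }
  try_dirs(setNames(character(0), character(0)), rev_active)
}

# minimal infeasible subset of enforced constraints (deletion filter);
# `must` constraints are never dropped
enforceIIS <- function(lp, obj_idx, E, must, act, delta, epsilon) {
  M <- E
  for (c0 in sort(setdiff(E, must))) {
    if (is.null(enforceFeasible(lp, obj_idx, setdiff(M, c0), act, delta,
                                epsilon)))
      M <- setdiff(M, c0)
  }
  M
}

#' Fit fluxes to expression-derived reaction activity
#'
#' Finds a steady-state flux distribution that agrees with as many activity
#' calls as possible — flux of at least `delta` through reactions called
#' active, zero flux through reactions called inactive — while keeping the
#' biomass objective at or above `epsilon`, so the fit can never starve the
#' model. The maximization is exact (branch-and-bound over minimal
#' conflict sets); among maximum-agreement solutions, total absolute flux
#' is minimized. Unknown reactions are left unconstrained.
#'
#' @param model a [MetabolicModel-class].
#' @param media a [MediaCondition-class].
#' @param activity named activity vector from [reactionActivity()].
#' @param epsilon minimum biomass flux retained during fitting
#'   (default 0.01); 0 makes the biomass constraint vacuous.
#' @param delta minimum |flux| for an active reaction (default 1e-3).
#' @param objective objective reaction id (default first biomass).
#' @return list with `solution` (a [FluxSolution-class]), `agreement`
#'   (named logical per classified reaction), `nAgree`, and `nClassified`.
#' @export
transcriptomicFBA <- function(model, media, activity,
                              epsilon = GAPFILL_EPSILON,
                              delta = FLUX_ACTIVITY_DELTA,
                              objective = NULL) {
  if (is.null(objective)) objective <- if (is(model, "CommunityModel"))
    model@communityBiomassId else model@biomassIds[1]
  m2 <- applyMedia(model, media)
  lp <- modelLP(m2)
  obj_idx <- match(objective, lp$ids)
  cvec <- numeric(length(lp$ids)); cvec[obj_idx] <- 1
  base <- solveLP(cvec, lp$A, lp$b, lp$lb, lp$ub, maximize = TRUE)
  if (base$status != "optimal" || base$objective < epsilon - 1e-9)
    stop("model '", model@id, "' cannot reach the biomass target on media '",
         media@name, "'")
  classified <- names(activity)[activity %in% c("active", "inactive")]
  classified <- intersect(classified, lp$ids)
  nC <- length(classified)

  best <- list(nviol = Inf, dirs = NULL, V = NULL)
  recurse <- function(V, must) {
    if (length(V) >= best$nviol) return(invisible())
    E <- setdiff(classified, V)
    dirs <- enforceFeasible(lp, obj_idx, E, activity, delta, epsilon)
    if (!is.null(dirs)) {
      best <<- list(nviol = length(V), dirs = dirs, V = V)
      return(invisible())
    }
    if (length(V) + 1L >= best$nviol) return(invisible())
    iis <- enforceIIS(lp, obj_idx, E, must, activity, delta, epsilon)
    iis <- sort(setdiff(iis, must))
    if (!length(iis)) return(invisible())   # conflict forced by `must`
    for (i in seq_along(iis)) {
      recurse(c(V, iis[i]), c(must, iis[seq_len(i - 1L)]))
    }
    invisible()
  }
  recurse(character(0), character(0))
  if (!is.finite(best$nviol))
    stop("no flux fit found")   # cannot happen: violating all is feasible

  # final solution: enforce the agreeing set, then minimize total flux
  E <- setdiff(classified, best$V)
  lb <- lp$lb; ub <- lp$ub
  rev_active <- names(best$dirs)
  for (r in setdiff(E, rev_active)) {
    bb <- enforceBounds(lb, ub, match(r, lp$ids), activity[[r]], delta)
    lb <- bb$lb; ub <- bb$ub
  }
  for (r in rev_active) {
    bb <- enforceBounds(lb, ub, match(r, lp$ids), "active", delta,
                        best$dirs[[r]])
    lb <- bb$lb; ub <- bb$ub
  }
  lb[obj_idx] <- max(lb[obj_idx], epsilon)
  n <- length(lp$ids)
  p_lb <- pmax(lb, 0); p_ub <- pmax(ub, 0)
  q_lb <- pmax(-ub, 0); q_ub <- pmax(-lb, 0)
  sol <- solveLP(rep(1, 2 * n), cbind(lp$A, -lp$A), lp$b,
                 c(p_lb, q_lb), c(p_ub, q_ub))
  stopifnot(sol$status == "optimal")
  v <- sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
  v[abs(v) < 1e-10] <- 0
  flux <- setNames(v, lp$ids)
  agree <- vapply(classified, function(r) {
    if (activity[[r]] == "active") abs(flux[[r]]) >= delta - 1e-9
    else abs(flux[[r]]) <= 1e-9
  }, logical(1))
  fs <- new("FluxSolution", status = "optimal",
            objective = unname(flux[objective]), fluxes = flux,
            objectiveId = objective)
  list(solution = fs, agreement = agree, nAgree = sum(agree), nClassified = nC)
}

# ---- consistency reporting ------------------------------------------------

categoryAccuracies <- function(ff, nn, fn, nf) {
  tot_a <- ff + nf; tot_i <- nn + fn
  c(active = if (tot_a > 0) 100 * ff / tot_a else NA_real_,
    inactive = if (tot_i > 0) 100 * nn / tot_i else NA_real_,
    overall = 100 * (ff + nn) / (ff + nn + fn + nf))
}

#' Accuracies from four consistency categories
#'
#' Computes the three accuracy summaries from the four flux/expression
#' categories (counts or percentages; the ratios are scale-free):
#' active-gene accuracy = (+F+E) / ((+F+E) + (-F+E)), inactive-gene
#' accuracy = (-F-E) / ((-F-E) + (+F-E)), overall = (+F+E) + (-F-E) over
#' the total.
#'
#' @param ff +Flux +Exp.
#' @param nn -Flux -Exp.
#' @param fn +Flux -Exp.
#' @param nf -Flux +Exp.
#' @return named numeric: `active`, `inactive`, `overall` (percent).
#' @examples
#' accuracyFromCategories(16.1, 37.0, 17.5, 29.5)  # 35.3 / 67.9 / 53.1
#' @export
accuracyFromCategories <- function(ff, nn, fn, nf) {
  categoryAccuracies(ff, nn, fn, nf)
}

#' Flux/expression consistency report
#'
#' Classifies every reaction with a defined activity call by whether it
#' carries flux (|v| >= delta) and whether its genes are expressed, yielding
#' the four-category confusion matrix, its accuracies, and a per-pathway
#' breakdown that additionally counts gapfilled reactions carrying flux.
#'
#' @param solution a [FluxSolution-class] (e.g. from [transcriptomicFBA()]
#'   or [runFBA()]).
#' @param activity named activity vector from [reactionActivity()].
#' @param model the model the solution was computed on.
#' @param delta flux/no-flux classification threshold (default 1e-3).
#' @return a [ConsistencyReport-class].
#' @export
consistencyReport <- function(solution, activity, model,
                              delta = FLUX_ACTIVITY_DELTA) {
  stopifnot(solution@status == "optimal")
  flux <- solution@fluxes
  rx <- model@reactions
  act <- activity[rx$id]
  has_flux <- abs(flux[rx$id]) >= delta
  classified <- act %in% c("active", "inactive")
  ff <- sum(classified & has_flux & act == "active")
  nn <- sum(classified & !has_flux & act == "inactive")
  fn <- sum(classified & has_flux & act == "inactive")
  nf <- sum(classified & !has_flux & act == "active")
  n <- sum(classified)
  counts <- c(`+F+E` = ff, `-F-E` = nn, `+F-E` = fn, `-F+E` = nf)
  perc <- if (n > 0) 100 * counts / n else counts * NA_real_
  acc <- categoryAccuracies(ff, nn, fn, nf)

  pw <- ifelse(is.na(rx$pathway), "unassigned", rx$pathway)
  gf_active <- rx$source_tag == "gapfilled" & has_flux
  tab <- data.frame(pathway = pw,
                    ff = classified & has_flux & act == "active",
                    nn = classified & !has_flux & act == "inactive",
                    fn = classified & has_flux & act == "inactive",
                    nf = classified & !has_flux & act == "active",
                    gapfilled_active = gf_active,
                    stringsAsFactors = FALSE)
  agg <- aggregate(tab[-1], by = list(pathway = tab$pathway), FUN = sum)
  agg$n_reactions <- as.vector(table(pw)[agg$pathway])
  new("ConsistencyReport",
      counts = as.integer(counts) |> setNames(names(counts)),
      percentages = perc, accuracies = acc, nClassified = as.integer(n),
      pathways = agg)
}

#' @describeIn ConsistencyReport-class four category percentages
#' @param object a ConsistencyReport
#' @export
setMethod("categoryPercentages", "ConsistencyReport",
          function(object) object@percentages)

#' @describeIn ConsistencyReport-class active/inactive/overall accuracies
#' @export
setMethod("accuracies", "ConsistencyReport", function(object) object@accuracies)

#' @describeIn ConsistencyReport-class per-pathway category counts
#' @export
setMethod("pathwayBreakdown", "ConsistencyReport",
          function(object) object@pathways)

#' Write a consistency report as TSV files
#'
#' Emits a one-row summary (the four categories and three accuracies) and,
#' optionally, the per-pathway breakdown.
#'
#' @param report a [ConsistencyReport-class].
#' @param path summary TSV path.
#' @param pathwayPath optional per-pathway TSV path.
#' @export
writeConsistencyTSV <- function(report, path, pathwayPath = NULL) {
  s <- data.frame(
    flux_exp_pct = report@percentages[["+F+E"]],
    noflux_noexp_pct = report@percentages[["-F-E"]],
    flux_noexp_pct = report@percentages[["+F-E"]],
    noflux_exp_pct = report@percentages[["-F+E"]],
    accuracy_active_pct = report@accuracies[["active"]],
    accuracy_inactive_pct = report@accuracies[["inactive"]],
    accuracy_overall_pct = report@accuracies[["overall"]],
    n_classified = report@nClassified)
  write.table(s, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(pathwayPath))
    write.table(report@pathways, pathwayPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}
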