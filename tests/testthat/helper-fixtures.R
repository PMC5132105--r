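# Shared fixtures and independent oracles for the test suite.

# fixture objects reused across files (construction is cheap and pure)
fx_ph <- makeToyPhototroph()
fx_het <- makeToyHeterotroph()
fx_db <- makeToyDatabase()

# drop reactions from a model (test-local convenience around the internal)
dropReactions <- function(model, ids) {
  CommFBA:::removeReactionsFromModel(model, ids)
}

# a tiny linear chain model:
#   EX_A (export orientation) <- A_e0 -> uptake; T: A_e0 -> A_c1; B: A->B;
#   BIO: B -> (drain)
chainModel <- function() {
  cmp <- data.frame(id = c("c1", "e0"), label = c("cytosol", "extracellular"),
                    species_index = c(1L, 0L))
  mets <- data.frame(id = c("A_c1", "B_c1", "A_e0"),
                     compartment = c("c1", "c1", "e0"),
                     formula = c("C1", "C1", "C1"))
  rxns <- data.frame(id = c("EX_A", "T_A", "R_AB", "BIO"),
                     lb = c(-10, 0, 0, 0), ub = c(100, 100, 100, 100),
                     source_tag = c("exchange", "transport", "draft", "biomass"))
  st <- data.frame(
    reaction = c("EX_A", "T_A", "T_A", "R_AB", "R_AB", "BIO"),
    metabolite = c("A_e0", "A_e0", "A_c1", "A_c1", "B_c1", "B_c1"),
    coef = c(-1, -1, 1, -1, 1, -1))
  MetabolicModel("chain", cmp, mets, rxns, st, biomassIds = "BIO")
}

# ---- brute-force LP oracle: enumerate basic solutions ---------------------
# For small LPs {max/min c'x : A x = b, lb <= x <= ub}, enumerate all
# candidate vertices (every choice of rank(A) "free" columns, all bound
# combinations for the rest) and return the best objective. Independent of
# the package's simplex.
bruteLPOptimum <- function(obj, A, b, lb, ub, maximize = FALSE) {
  A <- as.matrix(A); n <- ncol(A)
  r <- qr(t(A))$rank
  best <- NULL; best_x <- NULL
  free_sets <- if (r == 0) list(integer(0)) else combn(n, r, simplify = FALSE)
  for (fs in free_sets) {
    nbs <- setdiff(seq_len(n), fs)
    combos <- if (length(nbs) == 0) list(logical(0)) else
      lapply(0:(2^length(nbs) - 1),
             function(k) as.logical(intToBits(k)[seq_along(nbs)]))
    for (cb in combos) {
      x <- numeric(n)
      x[nbs] <- ifelse(cb, ub[nbs], lb[nbs])
      rhs <- b - A[, nbs, drop = FALSE] %*% x[nbs]
      sol <- tryCatch(qr.solve(A[, fs, drop = FALSE], rhs, tol = 1e-10),
                      error = function(e) NULL)
      if (is.null(sol)) next
      x[fs] <- sol
      if (any(x < lb - 1e-7) || any(x > ub + 1e-7)) next
      if (max(abs(A %*% x - b)) > 1e-7) next
      v <- sum(obj * x)
      if (is.null(best) || (maximize && v > best + 1e-12) ||
          (!maximize && v < best - 1e-12)) {
        best <- v; best_x <- x
      }
    }
  }
  list(objective = best, x = best_x)
}

# brute-force FBA on a model: maximize a reaction flux by vertex enumeration
bruteFBA <- function(model, media, objective) {
  m <- applyMedia(model, media)
  lp <- CommFBA:::modelLP(m)
  cvec <- as.numeric(lp$ids == objective)
  res <- bruteLPOptimum(cvec, lp$A, lp$b, lp$lb, lp$ub, maximize = TRUE)
  res$ids <- lp$ids
  res
}

# brute-force minimal total |v| at a fixed objective value: enumerate
# vertices of the split system (p - q parameterization)
bruteMinTotalFlux <- function(model, media, objective, opt) {
  m <- applyMedia(model, media)
  lp <- CommFBA:::modelLP(m)
  n <- length(lp$ids)
  cvec <- as.numeric(lp$ids == objective)
  A2 <- rbind(cbind(lp$A, -lp$A), c(cvec, -cvec))
  b2 <- c(lp$b, opt)
  p_lb <- pmax(lp$lb, 0); p_ub <- pmax(lp$ub, 0)
  q_lb <- pmax(-lp$ub, 0); q_ub <- pmax(-lp$lb, 0)
  res <- bruteLPOptimum(rep(1, 2 * n), A2, b2, c(p_lb, q_lb), c(p_ub, q_ub),
                        maximize = FALSE)
  res$objective
}

# restrict a reaction database to a subset of entries / transporter templates
dbSubset <- function(db, entries = character(0), transporters = character(0)) {
  keep <- db@reactions$id %in% entries
  ReactionDatabase(db@reactions[keep, , drop = FALSE],
                   db@stoich[db@stoich$reaction %in% entries, , drop = FALSE],
                   db@compounds, transporters,
                   costs = db@costs[c(entries, paste0("TPT_", transporters, recycle0 = TRUE))])
}
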