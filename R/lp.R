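# Dense bounded-variable two-phase primal simplex.
#
# Solves   min/max  obj' x   s.t.  A x = b,  lb <= x <= ub
# with all bounds finite. Problem sizes in this package are tiny (tens of
# variables), so the basis system is re-solved from scratch at every pivot:
# slower than factor updates but immune to accumulated round-off.

LP_TOL <- 1e-9

#' Solve a bounded linear program
#'
#' Internal workhorse behind all flux computations. Deterministic: entering
#' variables are chosen by the Dantzig rule with ties broken by smallest
#' column index, and Bland's rule takes over after a run of degenerate
#' pivots, which guarantees termination.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A dense or sparse constraint matrix (m x n), equality rows.
#' @param b right-hand side (length m).
#' @param lb,ub finite variable bounds.
#' @param maximize maximize instead of minimize.
#' @param tol feasibility/optimality tolerance.
#' @return list with elements `status` ("optimal" or "infeasible"),
#'   `objective`, and `x` (primal solution, length n).
#' @keywords internal
#' @noRd
solveLP <- function(obj, A, b, lb, ub, maximize = FALSE, tol = LP_TOL) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m,
            length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solveLP requires finite variable bounds")
  if (any(lb > ub + tol))
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  lb <- pmin(lb, ub)

  cvec <- if (maximize) -obj else obj

  # Extended problem: n structural + m artificial columns.
  nt <- n + m
  lbe <- c(lb, rep(0, m))
  ube <- c(ub, rep(Inf, m))        # artificials capped after phase 1
  Ae <- cbind(A, diag(m))

  # Start: structural variables nonbasic at the bound of smaller magnitude.
  at_upper <- abs(ub) < abs(lb)
  xN <- ifelse(at_upper, ub, lb)
  r <- b - as.vector(A %*% xN)
  sgn <- ifelse(r >= 0, 1, -1)
  Ae[, n + seq_len(m)] <- diag(sgn, m)

  state <- list(
    basis = n + seq_len(m),                   # artificial start basis
    at_ub = c(at_upper, rep(FALSE, m)),       # flag for nonbasic columns
    Ae = Ae, lbe = lbe, ube = ube, m = m, nt = nt
  )

  ph1 <- c(rep(0, n), rep(1, m))
  state <- simplexCore(state, ph1, b, tol)
  if (is.character(state)) stop("simplex failure: ", state)
  xfull <- lpPrimal(state, b)
  if (sum(xfull[n + seq_len(m)]) > 1e-7)
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))

  # Lock artificials at zero for phase 2 (they may linger in the basis at
  # level zero when equality rows are linearly dependent).
  state$ube[n + seq_len(m)] <- 0
  state$lbe[n + seq_len(m)] <- 0
  state$at_ub[n + seq_len(m)] <- FALSE

  state <- simplexCore(state, c(cvec, rep(0, m)), b, tol)
  if (is.character(state)) stop("simplex failure: ", state)
  xfull <- lpPrimal(state, b)
  x <- xfull[seq_len(n)]
  objv <- sum(obj * x)
  list(status = "optimal", objective = objv, x = x)
}

# Primal values of all columns given a simplex state.
lpPrimal <- function(state, b) {
  nb <- setdiff(seq_len(state$nt), state$basis)
  x <- numeric(state$nt)
  x[nb] <- ifelse(state$at_ub[nb], state$ube[nb], state$lbe[nb])
  rhs <- b - as.vector(state$Ae[, nb, drop = FALSE] %*% x[nb])
  x[state$basis] <- solve(state$Ae[, state$basis, drop = FALSE], rhs)
  x
}

# Core bounded-variable simplex loop; returns updated state or an error string.
simplexCore <- function(state, cvec, b, tol, max_iter = 20000L) {
  m <- state$m; nt <- state$nt
  degen_run <- 0L
  for (iter in seq_len(max_iter)) {
    B <- state$Ae[, state$basis, drop = FALSE]
    nb <- setdiff(seq_len(nt), state$basis)
    xnb <- ifelse(state$at_ub[nb], state$ube[nb], state$lbe[nb])
    rhs <- b - as.vector(state$Ae[, nb, drop = FALSE] %*% xnb)
    xB <- tryCatch(solve(B, rhs), error = function(e) NULL)
    if (is.null(xB)) return("singular basis")
    y <- tryCatch(solve(t(B), cvec[state$basis]), error = function(e) NULL)
    if (is.null(y)) return("singular basis")
    d <- cvec[nb] - as.vector(t(state$Ae[, nb, drop = FALSE]) %*% y)

    up <- state$at_ub[nb]
    elig <- (!up & d < -tol) | (up & d > tol)
    if (!any(elig)) {
      state$xB <- xB
      return(state)
    }
    cand <- which(elig)
    if (degen_run > 2L * nt) {
      e_rel <- cand[which.min(nb[cand])]            # Bland
    } else {
      sc <- abs(d[cand])
      e_rel <- cand[order(-sc, nb[cand])[1L]]       # Dantzig, lex ties
    }
    e <- nb[e_rel]
    s <- if (state$at_ub[e]) -1 else 1              # direction of change of x_e
    w <- solve(B, state$Ae[, e])                    # x_B moves by -s*t*w

    # Ratio test: largest step t >= 0 keeping basics and x_e within bounds.
    sw <- s * w
    ratio <- rep(Inf, m)
    hits_ub <- logical(m)
    dec <- sw > tol    # basic decreases toward its lower bound
    inc <- sw < -tol   # basic increases toward its upper bound
    if (any(dec))
      ratio[dec] <- (xB[dec] - state$lbe[state$basis[dec]]) / sw[dec]
    if (any(inc)) {
      ratio[inc] <- (xB[inc] - state$ube[state$basis[inc]]) / sw[inc]
      hits_ub[inc] <- TRUE
    }
    ratio[ratio < 0] <- 0   # guard against slight infeasibility round-off
    t_bound <- state$ube[e] - state$lbe[e]
    tmax <- min(t_bound, ratio)
    if (!is.finite(tmax)) return("unbounded")       # impossible with finite bounds
    degen_run <- if (tmax < tol) degen_run + 1L else 0L

    if (t_bound <= tmax + tol && t_bound <= min(ratio)) {
      # bound flip: entering variable crosses to its other bound
      state$at_ub[e] <- !state$at_ub[e]
    } else {
      tie <- which(ratio <= tmax + tol)
      leave <- tie[which.min(state$basis[tie])]     # deterministic (Bland-like)
      lv <- state$basis[leave]
      state$basis[leave] <- e
      state$at_ub[lv] <- hits_ub[leave]
      state$at_ub[e] <- FALSE
    }
  }
  "iteration limit"
}
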