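#' Solve a bounded-variable linear program
#'
#' Dense two-phase revised simplex with explicit variable bounds, written for
#' the moderately sized, highly degenerate LPs that growth-coupled
#' metabolism-and-expression models produce (tens to a few hundred rows).
#' Inequalities are converted to equalities with signed slacks; phase 1
#' minimises the sum of artificial variables, phase 2 the user objective.
#' Pivoting is Dantzig with an automatic switch to Bland's rule to guarantee
#' termination on degenerate bases.
#'
#' @param obj numeric objective coefficients (length n).
#' @param mat constraint matrix (m x n), dense numeric.
#' @param dir character vector of row senses: "<=", ">=", "==".
#' @param rhs numeric right-hand sides (length m).
#' @param lb,ub variable bounds (length n); -Inf/Inf allowed.
#' @param maximize logical; maximize instead of minimize.
#' @param feasibility_only logical; stop after phase 1 and report whether the
#'   polytope is non-empty (objective ignored).
#' @param tol pivot/dual tolerance.
#' @param feas_tol phase-1 feasibility tolerance on the artificial sum.
#' @return list with elements \code{status} ("optimal", "infeasible",
#'   "unbounded"), \code{x} (primal solution, length n), \code{objval}.
#' @export
solve_lp <- function(obj, mat, dir, rhs, lb, ub,
                     maximize = FALSE, feasibility_only = FALSE,
                     tol = 1e-9, feas_tol = 1e-7) {
  mat <- as.matrix(mat)
  m <- nrow(mat); n <- ncol(mat)
  stopifnot(length(obj) == n, length(dir) == m, length(rhs) == m,
            length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) stop("lower bound exceeds upper bound")

  ## geometric-mean equilibration: ME matrices mix coefficients spanning
  ## many orders of magnitude (mu/keff terms vs per-protein residue counts)
  rsc <- rep(1, m); csc <- rep(1, n)
  Asc <- mat
  for (pass in 1:2) {
    la <- suppressWarnings(log2(abs(Asc)))
    la[!is.finite(la)] <- NA
    r <- 2^(-rowMeans(la, na.rm = TRUE)); r[!is.finite(r)] <- 1
    Asc <- Asc * r; rsc <- rsc * r
    la <- suppressWarnings(log2(abs(Asc)))
    la[!is.finite(la)] <- NA
    cl <- 2^(-colMeans(la, na.rm = TRUE)); cl[!is.finite(cl)] <- 1
    Asc <- sweep(Asc, 2, cl, "*"); csc <- csc * cl
  }
  mat <- Asc
  rhs <- rhs * rsc
  lb <- lb / csc; ub <- ub / csc
  obj_orig <- obj
  obj <- obj * csc

  ## slacks: <= gets +s (s >= 0), >= gets -s (s >= 0), == none
  ineq <- which(dir != "==")
  k <- length(ineq)
  Afull <- cbind(mat, matrix(0, m, k))
  if (k > 0) {
    sgn <- ifelse(dir[ineq] == "<=", 1, -1)
    Afull[cbind(ineq, n + seq_len(k))] <- sgn
  }
  lbf <- c(lb, rep(0, k))
  ubf <- c(ub, rep(Inf, k))
  cf <- c(if (maximize) -obj else obj, rep(0, k))
  nf <- n + k

  ## artificials, one per row, basic at |residual| of the starting point
  x0 <- ifelse(is.finite(lbf), lbf, ifelse(is.finite(ubf), ubf, 0))
  r <- rhs - as.vector(Afull %*% x0)
  Aart <- diag(ifelse(r >= 0, 1, -1), m, m)
  A <- cbind(Afull, Aart)
  lbA <- c(lbf, rep(0, m))
  ubA <- c(ubf, rep(Inf, m))
  ntot <- nf + m

  art <- nf + seq_len(m)
  run <- function(bland) {
    state <- list(
      A = A, b = rhs, lb = lbA, ub = ubA,
      basis = nf + seq_len(m),
      ## nonbasic bound status: TRUE = at lower, FALSE = at upper
      at_lb = ifelse(is.finite(lbf), TRUE,
                     ifelse(is.finite(ubf), FALSE, TRUE)),
      x = c(x0, abs(r))
    )
    ## phase 1
    c1 <- c(rep(0, nf), rep(1, m))
    state <- simplex_core(state, c1, tol, bland)
    if (state$status == "iterlimit") stop("simplex iteration limit in phase 1")
    p1 <- sum(state$x[art])
    if (p1 > feas_tol) return(list(status = "infeasible"))
    if (feasibility_only) return(list(status = "optimal", state = state))
    ## phase 2 keeps the artificials under a big-M cost instead of pinning
    ## them: a borderline-feasible LP (phase-1 residual just under feas_tol)
    ## then parks its residual there instead of pushing structural variables
    ## out of bounds
    bigM <- 1e6 * (1 + max(abs(cf)))
    c2 <- c(cf, rep(bigM, m))
    state <- simplex_core(state, c2, tol, bland)
    if (state$status == "iterlimit") stop("simplex iteration limit in phase 2")
    if (state$status == "unbounded") return(list(status = "unbounded"))
    list(status = "optimal", state = state)
  }
  ## a mid-solve basis repair can leave a basic variable outside its bounds;
  ## verify the point and fall back to Bland pivoting (different path, no
  ## cycling) if that happened
  primal_ok <- function(st) {
    z <- st$x[seq_len(nf)]
    ok_bounds <- max(c(lbA[seq_len(nf)] - z, z - ubA[seq_len(nf)]),
                     na.rm = TRUE) < 1e-6
    ok_bounds && sum(st$x[art]) < 10 * feas_tol
  }
  out <- run(FALSE)
  if (out$status == "optimal" && !primal_ok(out$state)) out <- run(TRUE)
  if (out$status == "infeasible") {
    return(list(status = "infeasible", x = rep(NA_real_, n),
                objval = NA_real_))
  }
  if (out$status == "unbounded") {
    return(list(status = "unbounded", x = rep(NA_real_, n),
                objval = NA_real_))
  }
  if (!primal_ok(out$state)) stop("simplex returned a primal-infeasible point")
  xs <- out$state$x[seq_len(n)] * csc
  list(status = "optimal", x = xs, objval = sum(obj_orig * xs))
}

## Core bounded-variable simplex loop over a prepared state.
## state: A, b, lb, ub, basis (indices), at_lb (length ncol(A) logical, only
## meaningful for nonbasic columns), x (current point).
simplex_core <- function(state, cost, tol, bland = FALSE) {
  A <- state$A; b <- state$b; lb <- state$lb; ub <- state$ub
  m <- nrow(A); ntot <- ncol(A)
  basis <- state$basis
  at_lb <- state$at_lb
  if (length(at_lb) < ntot) at_lb <- c(at_lb, rep(TRUE, ntot - length(at_lb)))
  x <- state$x

  ## refactorization with self-repair: long degenerate runs can leave the
  ## basis numerically singular; dependent columns are then swapped for the
  ## artificial (identity) columns that restore full rank
  art_first <- ntot - m + 1L
  refactor <- function() {
    B <- A[, basis, drop = FALSE]
    qd <- qr(B)
    if (qd$rank < m) {
      keep <- basis[sort(qd$pivot[seq_len(qd$rank)])]
      dropped <- setdiff(basis, keep)
      at_lb[dropped] <<- is.finite(lb[dropped]) | !is.finite(ub[dropped])
      for (i in seq_len(m)) {
        if (length(keep) == m) break
        cand <- art_first + i - 1L
        if (cand %in% keep) next
        if (qr(A[, c(keep, cand), drop = FALSE])$rank > length(keep))
          keep <- c(keep, cand)
      }
      basis <<- keep
    }
    solve(A[, basis, drop = FALSE])
  }
  Binv <- refactor()
  maxit <- 200L * (ntot + m) + 2000L
  bland_after <- if (bland) 0L else 6L * (ntot + m)
  refactor_every <- 40L
  it <- 0L

  repeat {
    it <- it + 1L
    if (it > maxit) {
      state$status <- "iterlimit"; state$x <- x; state$basis <- basis
      state$at_lb <- at_lb
      return(state)
    }
    if (it %% refactor_every == 0L) {
      Binv <- tryCatch(solve(A[, basis, drop = FALSE]),
                       error = function(e) refactor())
    }

    nonbasic <- setdiff(seq_len(ntot), basis)
    ## recompute basic values from nonbasic point (limits drift)
    xN <- ifelse(at_lb[nonbasic], lb[nonbasic], ub[nonbasic])
    xN[!is.finite(xN)] <- 0
    x[nonbasic] <- xN
    xB <- as.vector(Binv %*% (b - A[, nonbasic, drop = FALSE] %*% xN))
    x[basis] <- xB

    y <- as.vector(crossprod(Binv, cost[basis]))
    d <- cost[nonbasic] - as.vector(crossprod(A[, nonbasic, drop = FALSE], y))

    ## eligibility: increase from lower bound if d<0, decrease from upper if
    ## d>0; free variables (no finite bound) may move either way
    free_n <- !is.finite(lb[nonbasic]) & !is.finite(ub[nonbasic])
    can_inc <- (at_lb[nonbasic] | free_n) & d < -tol
    can_dec <- (!at_lb[nonbasic] | free_n) & d > tol
    elig <- can_inc | can_dec
    if (!any(elig)) {
      state$status <- "optimal"; state$x <- x; state$basis <- basis
      state$at_lb <- at_lb
      return(state)
    }
    cand <- which(elig)
    if (it <= bland_after) {
      q_loc <- cand[which.max(abs(d[cand]))]
    } else {
      q_loc <- cand[which.min(nonbasic[cand])]  # Bland: smallest index
    }
    q <- nonbasic[q_loc]
    dirn <- if (can_inc[q_loc]) 1 else -1

    w <- as.vector(Binv %*% A[, q])
    ## step limits
    step_own <- ub[q] - lb[q]              # bound flip distance
    ## Harris-style two-pass ratio test: pass 1 finds the step allowed when
    ## bounds are relaxed by a small slack, pass 2 picks the largest pivot
    ## among rows blocking within that step. Small-pivot rows can then be
    ## bypassed only at a bounded (~slack) bound violation, which keeps the
    ## basis well conditioned without drifting.
    delta <- -dirn * w
    t_strict <- t_rel <- rep(Inf, m)
    ## every row with nonzero movement participates in the ratio test; the
    ## relaxed ratio brel/|delta| discounts tiny pivots, bounding any bypass
    ## violation by ~brel. Noise-level movements get a looser relaxation so
    ## degenerate micro-blocks cannot stall progress.
    brel <- ifelse(abs(delta) > 1e-9, 1e-10, 1e-7)
    dec <- delta < 0      # basic decreasing -> hits its lower bound
    inc <- delta > 0      # basic increasing -> hits its upper bound
    t_strict[dec] <- (lb[basis[dec]] - xB[dec]) / delta[dec]
    t_strict[inc] <- (ub[basis[inc]] - xB[inc]) / delta[inc]
    t_rel[dec] <- t_strict[dec] - brel[dec] / delta[dec]
    t_rel[inc] <- t_strict[inc] + brel[inc] / delta[inc]
    t_strict[t_strict < 0] <- 0   # degeneracy guard
    t_rel[t_rel < 0] <- 0
    rmin <- if (m > 0) min(t_rel) else Inf
    tstar <- min(step_own, rmin)
    if (!is.finite(tstar)) {
      state$status <- "unbounded"; state$x <- x; state$basis <- basis
      state$at_lb <- at_lb
      return(state)
    }

    if (step_own <= rmin) {
      ## bound flip, basis unchanged
      at_lb[q] <- !at_lb[q]
      next
    }

    ## pass 2: largest pivot among rows blocking within the relaxed step
    leave_i <- which(t_strict <= rmin)
    if (length(leave_i) > 1) {
      if (it > bland_after) {
        leave_i <- leave_i[which.min(basis[leave_i])]
      } else {
        leave_i <- leave_i[which.max(abs(w[leave_i]))]
      }
    }
    p <- basis[leave_i]
    ## leaving variable goes to the bound it hit
    at_lb[p] <- delta[leave_i] < 0

    ## pivot update of Binv; a forced small pivot triggers an immediate
    ## refactorization so conditioning cannot silently degrade
    piv <- w[leave_i]
    Brow <- Binv[leave_i, ] / piv
    wa <- w; wa[leave_i] <- 0
    Binv <- Binv - outer(wa, Brow)
    Binv[leave_i, ] <- Brow
    basis[leave_i] <- q
    if (abs(piv) < 1e-7)
      Binv <- tryCatch(solve(A[, basis, drop = FALSE]),
                       error = function(e) refactor())
  }
}
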