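# Dense two-phase simplex and the FBA / pFBA front ends.
#
# The environment this package targets carries no LP solver package, and the
# networks are small (< 200 reactions), so a compact tableau simplex with
# Bland's anti-cycling rule is used. It is cross-checked in the test suite
# against an independent scipy.optimize.linprog oracle.

#' Solve min c'x s.t. A x = b, x >= 0 by the two-phase simplex method
#'
#' @param A constraint matrix (m x n)
#' @param b right-hand side (length m)
#' @param cvec objective coefficients (length n)
#' @param maxit iteration cap
#' @param tol numerical tolerance
#' @return list with `x`, `value`, `status` ("optimal", "infeasible",
#'   "unbounded", "maxit"), and for unbounded problems `unbounded_col`.
#' @export
simplex_solve <- function(A, b, cvec, maxit = 20000L, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(cvec) == n)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]

  # tableau with artificial variables appended
  Tb <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  ncol_t <- n + m

  run_phase <- function(Tb, basis, obj, allowed) {
    # obj: objective row over allowed columns; returns updated tableau/basis
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > maxit) return(list(Tb = Tb, basis = basis, status = "maxit"))
      # reduced costs: z_j - c_j computed directly
      cb <- obj[basis]
      red <- obj[allowed] - as.numeric(crossprod(cb, Tb[, allowed, drop = FALSE]))
      ent_rel <- which(red < -tol)
      if (!length(ent_rel)) return(list(Tb = Tb, basis = basis, status = "optimal"))
      enter <- allowed[min(ent_rel)]   # Bland: smallest index
      col <- Tb[, enter]
      pos <- which(col > tol)
      if (!length(pos)) {
        return(list(Tb = Tb, basis = basis, status = "unbounded", unbounded_col = enter))
      }
      ratio <- Tb[pos, ncol_t + 1L] / col[pos]
      leave_candidates <- pos[ratio <= min(ratio) + tol]
      leave <- leave_candidates[which.min(basis[leave_candidates])]  # Bland
      piv <- Tb[leave, enter]
      Tb[leave, ] <- Tb[leave, ] / piv
      other <- setdiff(seq_len(m), leave)
      Tb[other, ] <- Tb[other, ] - outer(Tb[other, enter], Tb[leave, ])
      basis[leave] <- enter
    }
  }

  # Phase 1: minimize sum of artificials
  obj1 <- c(rep(0, n), rep(1, m))
  ph1 <- run_phase(Tb, basis, obj1, seq_len(ncol_t))
  if (ph1$status != "optimal") {
    return(list(x = NULL, value = NA_real_, status = ph1$status,
                unbounded_col = ph1$unbounded_col))
  }
  Tb <- ph1$Tb; basis <- ph1$basis
  p1val <- sum(obj1[basis] * Tb[, ncol_t + 1L])
  if (p1val > 1e-7) {
    return(list(x = NULL, value = NA_real_, status = "infeasible"))
  }
  # pivot remaining artificials out of the basis where possible
  for (i in which(basis > n)) {
    row <- Tb[i, seq_len(n)]
    j <- which(abs(row) > tol)
    if (length(j)) {
      enter <- j[1]
      piv <- Tb[i, enter]
      Tb[i, ] <- Tb[i, ] / piv
      other <- setdiff(seq_len(m), i)
      Tb[other, ] <- Tb[other, ] - outer(Tb[other, enter], Tb[i, ])
      basis[i] <- enter
    }
  }
  allowed <- seq_len(n)
  obj2 <- c(cvec, rep(0, m))
  ph2 <- run_phase(Tb, basis, obj2, allowed)
  if (ph2$status != "optimal") {
    return(list(x = NULL, value = NA_real_, status = ph2$status,
                unbounded_col = ph2$unbounded_col))
  }
  Tb <- ph2$Tb; basis <- ph2$basis
  x <- numeric(n)
  keep <- basis <= n
  x[basis[keep]] <- Tb[keep, ncol_t + 1L]
  list(x = x, value = sum(cvec * x), status = "optimal")
}

#' Solve a bounded flux LP: optimize c'v s.t. S v = 0, lb <= v <= ub
#'
#' Fluxes are split as v = p - n with p, n >= 0; finite bounds become slack
#' rows. `penalty` adds `penalty * sum(p + n)` to the (minimized) objective,
#' which linearizes a sum-of-absolute-values term.
#'
#' @param S balance matrix (rows = balanced metabolites)
#' @param lb,ub flux bounds
#' @param cmin coefficients of the minimized objective over fluxes
#' @param penalty coefficient on total absolute flux (default 0)
#' @param penalty_exclude flux indices excluded from the penalty
#' @return list with `v` (named like colnames(S)), `value`, `status`
#' @export
flux_lp <- function(S, lb, ub, cmin, penalty = 0, penalty_exclude = integer(0)) {
  nr <- ncol(S)
  if (any(lb > ub)) sphingo_abort("lp", "lb > ub for some reaction")
  Apos <- cbind(S, -S)      # balances over (p, n)
  b <- rep(0, nrow(S))
  rows <- list(Apos)
  rhs <- list(b)
  nvar <- 2L * nr
  extra <- 0L
  slack_rows <- list()
  # bound rows: p - n (+/- slack) = bound
  for (j in seq_len(nr)) {
    if (is.finite(ub[j])) {
      r <- numeric(nvar); r[j] <- 1; r[nr + j] <- -1
      slack_rows[[length(slack_rows) + 1L]] <- list(r = r, rhs = ub[j], slack = +1)
    }
    if (is.finite(lb[j])) {
      r <- numeric(nvar); r[j] <- 1; r[nr + j] <- -1
      slack_rows[[length(slack_rows) + 1L]] <- list(r = r, rhs = lb[j], slack = -1)
    }
  }
  ns <- length(slack_rows)
  A <- matrix(0, nrow = nrow(S) + ns, ncol = nvar + ns)
  A[seq_len(nrow(S)), seq_len(nvar)] <- Apos
  bfull <- c(b, numeric(ns))
  for (k in seq_len(ns)) {
    A[nrow(S) + k, seq_len(nvar)] <- slack_rows[[k]]$r
    A[nrow(S) + k, nvar + k] <- slack_rows[[k]]$slack
    bfull[nrow(S) + k] <- slack_rows[[k]]$rhs
  }
  pen <- rep(penalty, nr)
  pen[penalty_exclude] <- 0
  cfull <- c(cmin + pen, -cmin + pen, numeric(ns))
  sol <- simplex_solve(A, bfull, cfull)
  if (sol$status != "optimal") {
    return(list(v = NULL, value = NA_real_, status = sol$status,
                unbounded_col = sol$unbounded_col))
  }
  v <- sol$x[seq_len(nr)] - sol$x[nr + seq_len(nr)]
  names(v) <- colnames(S)
  list(v = v, value = sum(cmin * v), status = "optimal")
}

#' Plain flux balance analysis (maximize biomass)
#'
#' @param net `sphingo_network` including a biomass reaction
#' @return list with `v`, `v_biomass`, `status`
#' @export
solve_fba <- function(net) {
  S <- build_stoichiometric_matrix(net, trim = TRUE)
  bio <- which(net$reactions$type == "biomass")
  if (!length(bio)) sphingo_abort("lp", "network has no biomass reaction")
  cmin <- numeric(ncol(S)); cmin[bio] <- -1
  sol <- flux_lp(S, net$reactions$lb, net$reactions$ub, cmin)
  if (sol$status != "optimal") {
    sphingo_abort("lp", "FBA ", sol$status,
                  if (!is.null(sol$unbounded_col)) paste0(" (column ", sol$unbounded_col, ")") else "")
  }
  list(v = sol$v, v_biomass = unname(sol$v[bio]), status = sol$status)
}

#' Parsimonious FBA with a tilted objective
#'
#' Maximizes `v_biomass - 0.0001 * sum_j |v_j|` (sum over non-biomass
#' reactions), subject to the steady-state balances and flux bounds. The tilt
#' keeps the growth optimum (to within 1e-4 of total flux) while selecting
#' the minimum-total-flux distribution, so futile cycles carry zero flux.
#'
#' @param net `sphingo_network`; must contain a biomass reaction (attach one
#'   with [attach_biomass()]).
#' @param biomass optional biomass reaction table to attach first.
#' @param rate optional growth rate overriding the biomass reaction bounds.
#' @param tilt penalty on total absolute flux (default 1e-4).
#' @return a `sphingo_reference` object (see [new_reference_state()]).
#' @export
solve_pfba <- function(net, biomass = NULL, rate = NULL, tilt = 1e-4) {
  if (!is.null(biomass)) net <- attach_biomass(net, biomass)
  bio <- which(net$reactions$type == "biomass")
  if (!length(bio)) sphingo_abort("lp", "network has no biomass reaction")
  if (!is.null(rate)) {
    net$reactions$lb[bio] <- rate
    net$reactions$ub[bio] <- rate
  }
  S <- build_stoichiometric_matrix(net, trim = TRUE)
  cmin <- numeric(ncol(S)); cmin[bio] <- -1
  sol <- flux_lp(S, net$reactions$lb, net$reactions$ub, cmin,
                 penalty = tilt, penalty_exclude = bio)
  if (sol$status == "infeasible") {
    sphingo_abort("lp", "pFBA infeasible: steady-state balances cannot be met ",
                  "with the given bounds and biomass composition")
  }
  if (sol$status != "optimal") {
    sphingo_abort("lp", "pFBA ", sol$status,
                  if (!is.null(sol$unbounded_col)) paste0(" (column ", sol$unbounded_col, ")") else "")
  }
  resid <- max(abs(S %*% sol$v))
  if (resid > 1e-7) sphingo_abort("lp", "pFBA balance residual too large: ", resid)
  new_reference_state(net, sol$v)
}
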