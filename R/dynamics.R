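# Normalized mass-action dynamics: RHS assembly, perturbations, and
# steady-state detection by pseudo-transient continuation (adaptive implicit
# Euler with an analytic Jacobian). The systems are small (< 100 states) but
# stiff: near-equilibrium chains carry exchange fluxes orders of magnitude
# above net fluxes, so explicit integration is not an option.

#' Compile a kinetic model into an evaluatable ODE system
#'
#' @param model `sphingo_model`
#' @param elem `sphingo_elementary`
#' @return a `sphingo_system`: list of closures `rates(x)`, `rhs(x)` (full
#'   species vector, buffered entries zeroed), `jac(x)` and index metadata.
#' @export
assemble_rhs <- function(model, elem) {
  steps <- elem$steps
  n_sp <- nrow(elem$species)
  n_st <- nrow(steps)
  if (length(model$K) != n_st) {
    sphingo_abort("assembly", "model has ", length(model$K), " rate constants for ",
                  n_st, " elementary steps; model and network are out of step")
  }
  K <- model$K
  r1 <- steps$r1
  r2 <- ifelse(is.na(steps$r2), 0L, steps$r2)
  has_pool <- !is.na(steps$pool)
  pool_members <- lapply(steps$pool[has_pool], function(p) elem$pools[[p]])
  pool_w <- lapply(pool_members, function(mem) {
    w <- elem$abundance[mem] %||% rep(1, length(mem))
    if (sum(w) <= 0) w <- rep(1, length(mem))
    w / sum(w)
  })
  pool_rows <- which(has_pool)

  # stoichiometry of elementary steps over species
  N <- matrix(0, n_sp, n_st)
  for (j in seq_len(n_st)) {
    s <- steps[j, ]
    N[s$r1, j] <- N[s$r1, j] - 1
    if (!is.na(s$r2)) N[s$r2, j] <- N[s$r2, j] - 1
    if (!is.na(s$p1)) N[s$p1, j] <- N[s$p1, j] + 1
    if (!is.na(s$p2)) N[s$p2, j] <- N[s$p2, j] + 1
  }
  buffered <- elem$species$buffered
  dyn <- which(!buffered)
  Ndyn <- N[dyn, , drop = FALSE]

  rates <- function(x) {
    a2 <- rep(1, n_st)
    nz <- r2 > 0L
    a2[nz] <- x[r2[nz]]
    if (length(pool_rows)) {
      for (k in seq_along(pool_rows)) {
        a2[pool_rows[k]] <- sum(x[pool_members[[k]]] * pool_w[[k]])
      }
    }
    K * x[r1] * a2
  }
  rhs <- function(x) {
    d <- numeric(n_sp)
    d[dyn] <- Ndyn %*% rates(x)
    d
  }
  jac <- function(x) {
    # D[j, i] = d v_j / d x_i, assembled sparsely then contracted with N
    a2 <- rep(1, n_st)
    nz <- r2 > 0L
    a2[nz] <- x[r2[nz]]
    if (length(pool_rows)) {
      for (k in seq_along(pool_rows)) {
        a2[pool_rows[k]] <- sum(x[pool_members[[k]]] * pool_w[[k]])
      }
    }
    D <- matrix(0, n_st, n_sp)
    D[cbind(seq_len(n_st), r1)] <- K * a2
    if (any(nz)) D[cbind(which(nz), r2[nz])] <- D[cbind(which(nz), r2[nz])] + K[nz] * x[r1[nz]]
    if (length(pool_rows)) {
      for (k in seq_along(pool_rows)) {
        j <- pool_rows[k]; mem <- pool_members[[k]]
        D[j, mem] <- D[j, mem] + K[j] * x[r1[j]] * pool_w[[k]]
      }
    }
    J <- matrix(0, n_sp, n_sp)
    J[dyn, ] <- Ndyn %*% D
    J
  }
  structure(list(rates = rates, rhs = rhs, jac = jac, N = N, dyn = dyn,
                 n_species = n_sp, n_steps = n_st, model = model, elem = elem),
            class = "sphingo_system")
}

#' Apply an enzyme- or regulator-level fold change to a state vector
#'
#' Fold-change-in-expression semantics: the states belonging exclusively to
#' the perturbed pool are scaled by `fold`. States shared with another
#' conserved pool (an enzyme-regulator complex belongs to both the enzyme's
#' and the regulator's conservation) are left untouched and re-equilibrate
#' dynamically -- over-expressing ORM must not inject extra SPT through the
#' SPT.ORM complex, and vice versa.
#'
#' @param elem `sphingo_elementary`
#' @param x state vector (typically the model's reference state)
#' @param target enzyme name or regulator species id
#' @param fold positive fold change (`1` is the identity)
#' @return perturbed state vector
#' @export
apply_perturbation <- function(elem, x, target, fold) {
  if (fold <= 0) sphingo_abort("domain", "perturbation fold change must be > 0")
  reg_members <- unique(unlist(elem$orm_pool %||% list()))
  if (target %in% names(elem$enzyme_states)) {
    members <- setdiff(elem$enzyme_states[[target]], reg_members)
  } else if (target %in% names(elem$orm_pool %||% list())) {
    enz_states <- which(elem$species$kind == "enzyme_state")
    members <- setdiff(elem$orm_pool[[target]], enz_states)
  } else {
    sphingo_abort("perturbation", "unknown perturbation target '", target, "'")
  }
  x[members] <- x[members] * fold
  x
}

#' Find a steady state by adaptive implicit Euler
#'
#' Integrates `dx/dt = f(x)` from `x0` with growing implicit-Euler steps
#' (pseudo-transient continuation) until `max|f| < tol_ss` or `t_max` is
#' exceeded. Buffered species are held fixed. Small negative excursions are
#' clipped to zero; larger ones trigger step rejection.
#'
#' @param sys `sphingo_system`
#' @param x0 initial state (default: the model's reference state)
#' @param tol_ss steady-state tolerance on the max derivative (default 1e-9)
#' @param t_max maximum normalized time (default 1e6)
#' @param h0 initial step
#' @param record if `TRUE`, store the (t, x) trajectory at accepted steps
#' @return `sphingo_steady`: list with `x`, `converged`, `residual`, `t`,
#'   `fluxes` (per-reaction net), `enzyme_flux`, and optionally `trajectory`
#' @export
simulate_to_steady_state <- function(sys, x0 = NULL, tol_ss = 1e-9, t_max = 1e6,
                                     h0 = 1e-3, record = FALSE) {
  x <- x0 %||% sys$model$x_ref
  dyn <- sys$dyn
  n_dyn <- length(dyn)
  t <- 0; h <- h0
  traj <- if (record) list(list(t = 0, x = x)) else NULL
  f <- sys$rhs(x)
  res <- max(abs(f))
  iter <- 0L
  while (res > tol_ss && t < t_max) {
    iter <- iter + 1L
    if (iter > 100000L) break
    y <- x
    ok <- FALSE
    for (newt in 1:12) {
      fy <- sys$rhs(y)
      G <- (y - x)[dyn] - h * fy[dyn]
      J <- diag(n_dyn) - h * sys$jac(y)[dyn, dyn, drop = FALSE]
      dy <- tryCatch(solve(J, -G), error = function(e) NULL)
      if (is.null(dy) || any(!is.finite(dy))) break
      y[dyn] <- y[dyn] + dy
      if (max(abs(dy)) < 1e-12 * max(1, max(abs(y[dyn])))) { ok <- TRUE; break }
      if (max(abs(dy)) < 1e-9 && max(abs((y - x)[dyn] - h * sys$rhs(y)[dyn])) < 1e-12) {
        ok <- TRUE; break
      }
    }
    if (ok && min(y[dyn]) < -1e-6) ok <- FALSE
    if (!ok) {
      h <- h / 4
      if (h < 1e-14) break
      next
    }
    y[dyn][y[dyn] < 0] <- 0
    x <- y
    t <- t + h
    h <- min(h * 2, 1e5)
    f <- sys$rhs(x)
    res <- max(abs(f))
    if (record) traj[[length(traj) + 1L]] <- list(t = t, x = x)
  }
  fl <- reaction_net_fluxes(sys, x)
  out <- list(x = x, converged = res <= tol_ss, residual = res, t = t,
              fluxes = fl$reaction, enzyme_flux = fl$enzyme)
  if (record) out$trajectory <- traj
  structure(out, class = "sphingo_steady")
}

#' Net reaction and enzyme fluxes at a state
#'
#' Per-reaction net flux is the net rate through the release step of each of
#' its catalytic chains (basal plus activated); per-enzyme flux sums the
#' enzyme's reactions.
#'
#' @param sys `sphingo_system`
#' @param x state vector
#' @return list with named vectors `reaction` and `enzyme`
#' @export
reaction_net_fluxes <- function(sys, x) {
  v <- sys$rates(x)
  elem <- sys$elem
  rxn <- stats::setNames(rep(0, 0), character(0))
  out <- list()
  for (ch in elem$chains) {
    net <- v[ch$rows[5]] - v[ch$rows[6]]
    out[[ch$rxn_id]] <- (out[[ch$rxn_id]] %||% 0) + net
  }
  reaction <- unlist(out) %||% numeric(0)
  enz_rxns <- elem$network$reactions
  enzyme <- tapply(reaction[names(reaction)],
                   enz_rxns$enzyme[match(names(reaction), enz_rxns$id)], sum)
  list(reaction = reaction, enzyme = c(enzyme))
}

#' Verify that a model reproduces the reference steady state
#'
#' @param model `sphingo_model`
#' @param elem `sphingo_elementary`
#' @param integrate also integrate for 1e3 normalized time units and require
#'   the state to stay within 1e-6 of the reference
#' @param tol residual tolerance (default 1e-9)
#' @return list with `ok`, `residual`, and `max_drift` when integrating
#' @export
verify_reference <- function(model, elem, integrate = FALSE, tol = 1e-9) {
  sys <- assemble_rhs(model, elem)
  res <- max(abs(sys$rhs(model$x_ref)))
  out <- list(ok = res < tol, residual = res)
  if (integrate && out$ok) {
    ss <- simulate_to_steady_state(sys, x0 = model$x_ref, t_max = 1e3)
    drift <- max(abs(ss$x - model$x_ref))
    out$max_drift <- drift
    out$ok <- out$ok && drift < 1e-6
  }
  out
}

#' Enzyme-state totals at a state vector
#'
#' @param elem `sphingo_elementary`
#' @param x state vector
#' @return named vector of per-enzyme totals (free + all complexes)
#' @export
enzyme_totals <- function(elem, x) {
  vapply(elem$enzyme_states, function(idx) sum(x[idx]), numeric(1))
}
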