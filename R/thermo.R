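# Thermodynamic feasibility bounds for reversibility sampling.

#' Convert a standard Gibbs energy to bounds on the summed log-reversibility
#'
#' For a reaction with net reference flux in the written direction, the
#' summed log-reversibilities of its elementary steps equal the actual
#' `dG/RT`, which ranges over `dG'0/RT + ln(q)` for substrate/product
#' concentration ratios `q` in `conc_ratio_range`. The bound on the directed
#' side is clipped so the directed reaction stays thermodynamically feasible
#' (strictly negative directed free energy; clip at `1e-3` for numerical
#' conditioning of the near-equilibrium limit).
#'
#' @param delta_g0 standard Gibbs energy, kJ/mol
#' @param conc_ratio_range admissible product/substrate concentration-ratio
#'   factor `[q_min, q_max]`, default `c(1e-3, 1e3)`
#' @param temperature Kelvin, default 298.15
#' @param sign_vnet sign of the reference net flux (+1 forward, -1 reverse)
#' @param clip feasibility margin on the directed free energy (dimensionless)
#' @return list with `lb`, `ub` (bounds on `sign(V) * sum(ln R)`), `dgrt`
#'   (`dG'0/RT`) and `feasible`
#' @export
gibbs_to_bounds <- function(delta_g0, conc_ratio_range = c(1e-3, 1e3),
                            temperature = 298.15, sign_vnet = 1, clip = 1e-3) {
  if (length(conc_ratio_range) != 2L || conc_ratio_range[1] <= 0) {
    sphingo_abort("domain", "conc_ratio_range must be positive with q_min <= q_max")
  }
  if (conc_ratio_range[1] > conc_ratio_range[2]) {
    sphingo_abort("domain", "conc_ratio_range must satisfy q_min <= q_max")
  }
  if (!is.finite(delta_g0)) sphingo_abort("domain", "delta_g0 must be finite")
  dgrt <- delta_g0 / (.R_GAS * temperature)
  lb <- dgrt + log(conc_ratio_range[1])
  ub <- dgrt + log(conc_ratio_range[2])
  if (sign_vnet >= 0) {
    ub <- min(ub, -clip)
  } else {
    lb <- max(lb, clip)
  }
  list(lb = lb, ub = ub, dgrt = dgrt, feasible = lb <= ub)
}

#' Sample elementary-step reversibilities under a thermodynamic bound
#'
#' Draws one reversibility per reversible step uniformly in (0, 1), then
#' rescales them jointly in log space so `sign(V) * sum(ln R)` lands at a
#' target drawn uniformly within `[lb, ub]`.
#'
#' @param n_steps number of reversible steps in the chain
#' @param bounds output of [gibbs_to_bounds()]
#' @param sign_vnet sign of the net reference flux
#' @param rxn_id reaction id used in error messages
#' @return numeric vector of reversibilities in (0, 1)
#' @export
sample_reversibilities <- function(n_steps, bounds, sign_vnet = 1, rxn_id = "?") {
  if (!bounds$feasible) {
    sphingo_abort("thermo", "thermodynamically infeasible bounds for reaction '",
                  rxn_id, "' (lb ", signif(bounds$lb, 4), " > ub ",
                  signif(bounds$ub, 4), ")")
  }
  if (n_steps < 1L) sphingo_abort("domain", "chain must have >= 1 reversible step")
  target <- stats::runif(1, bounds$lb, bounds$ub)
  lnR_total <- sign(sign_vnet + 0.5) * target   # sum of ln R, always <= 0
  if (lnR_total > 0) {
    sphingo_abort("thermo", "bounds for '", rxn_id,
                  "' imply sum(ln R) > 0, impossible for R in (0, 1]")
  }
  u <- stats::runif(n_steps)
  lnu <- log(u)
  lnR <- lnu * (lnR_total / sum(lnu))
  exp(lnR)
}

#' Forward/reverse elementary rates from net flux and reversibility
#'
#' Solves `v_fwd - v_rev = V_net` and `R = min(v_fwd, v_rev)/max(...)`:
#' for `V_net > 0`, `v_fwd = V/(1-R)`, `v_rev = R V/(1-R)`; mirrored for
#' `V_net < 0`.
#'
#' @param v_net net reference flux of the chain
#' @param R reversibility vector (one per reversible step)
#' @return list of vectors `v_fwd`, `v_rev`
#' @export
elementary_rates_from_R <- function(v_net, R) {
  if (any(R < 0 | R > 1)) sphingo_abort("domain", "reversibilities must lie in [0, 1]")
  if (v_net == 0) {
    return(list(v_fwd = rep(0, length(R)), v_rev = rep(0, length(R))))
  }
  if (any(R == 1)) {
    sphingo_abort("thermo", "R = 1 with nonzero net flux is thermodynamically inconsistent")
  }
  mag <- abs(v_net)
  hi <- mag / (1 - R)
  lo <- R * mag / (1 - R)
  if (v_net > 0) list(v_fwd = hi, v_rev = lo) else list(v_fwd = lo, v_rev = hi)
}

#' Sample reference enzyme-state fractions on the simplex
#'
#' Uniform on the `(n-1)`-simplex (symmetric Dirichlet with unit
#' concentration), floored at 1e-9 and renormalized so no state is exactly
#' empty (rate constants divide by the occupying fraction).
#'
#' @param n_states number of enzyme states (free + complexes), >= 2
#' @return numeric vector summing to 1
#' @export
sample_enzyme_fractions <- function(n_states) {
  if (n_states < 2L) sphingo_abort("domain", "an enzyme has at least 2 states")
  g <- stats::rexp(n_states)
  f <- g / sum(g)
  f <- pmax(f, 1e-9)
  f / sum(f)
}
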