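# Apparent kinetic parameters: King-Altman reduction of three-step chains to
# (kcat+, Ks), and distribution comparison between passing and failing models.

#' Lump a three-step chain's elementary constants into apparent parameters
#'
#' For the reversible chain `E + S <-> ES <-> EP <-> E + P` with elementary
#' constants `k1, k-1, k2, k-2, k3, k-3`, the steady-state initial-rate law
#' at vanishing product is Michaelis-Menten with
#' `kcat+ = k2 k3 / (k2 + k-2 + k3)` and
#' `Ks = (k-1 k3 + k-1 k-2 + k2 k3) / (k1 (k2 + k-2 + k3))`
#' (per unit total enzyme).
#'
#' @param k named or positional vector `(k1, km1, k2, km2, k3, km3)`
#' @return list with `kcat_plus` and `K_s`
#' @export
lump_chain_constants <- function(k) {
  if (length(k) != 6L || any(k < 0)) {
    sphingo_abort("mechanism", "need 6 nonnegative elementary constants (3 reversible steps)")
  }
  k1 <- k[1]; km1 <- k[2]; k2 <- k[3]; km2 <- k[4]; k3 <- k[5]; km3 <- k[6]
  den <- k2 + km2 + k3
  if (k1 <= 0 || den <= 0) {
    sphingo_abort("mechanism", "chain has no forward route (k1 or k2+k-2+k3 is zero)")
  }
  list(kcat_plus = k2 * k3 / den,
       K_s = (km1 * k3 + km1 * km2 + k2 * k3) / (k1 * den))
}

#' Apparent parameters for an enzyme (per catalytic branch)
#'
#' Pulls the elementary constants of each of the enzyme's chains out of a
#' kinetic model and lumps them. Basal and activated branches are lumped
#' separately; for promiscuous enzymes one entry per reaction is returned.
#'
#' @param model `sphingo_model`
#' @param elem `sphingo_elementary`
#' @param enzyme enzyme name
#' @return data frame with columns `enzyme`, `rxn_id`, `branch`, `kcat_plus`, `K_s`
#' @export
lump_apparent_params <- function(model, elem, enzyme) {
  sel <- vapply(elem$chains, function(ch) ch$enzyme == enzyme, logical(1))
  if (!any(sel)) sphingo_abort("mechanism", "enzyme '", enzyme, "' has no chains")
  out <- lapply(elem$chains[sel], function(ch) {
    kk <- model$K[ch$rows]
    if (all(kk == 0)) return(NULL)  # inactive branch (strict activation)
    lp <- lump_chain_constants(kk)
    data.frame(enzyme = enzyme, rxn_id = ch$rxn_id, branch = ch$branch,
               kcat_plus = lp$kcat_plus, K_s = lp$K_s, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Numerical oracle for apparent parameters of a three-step chain
#'
#' Solves the enzyme-internal steady state of the isolated chain at clamped
#' substrate concentration and vanishing product, returning the net rate; the
#' saturation limit gives kcat+ and the half-maximal substrate gives Ks. Kept
#' independent of [lump_chain_constants()] (linear solve + root bracketing).
#'
#' @param k elementary constants `(k1, km1, k2, km2, k3, km3)`
#' @param x_max saturating substrate level (default 1e9)
#' @return list with `kcat_plus`, `K_s`, and `rate(x)` closure
#' @export
chain_rate_oracle <- function(k, x_max = 1e9) {
  k1 <- k[1]; km1 <- k[2]; k2 <- k[3]; km2 <- k[4]; k3 <- k[5]; km3 <- k[6]
  rate <- function(x) {
    vapply(x, function(s) {
      # states (e, c1, c2), total 1, product clamped at 0
      A <- rbind(c(-k1 * s, km1 + 0, k3),
                 c(k1 * s, -(km1 + k2), km2),
                 c(1, 1, 1))
      b <- c(0, 0, 1)
      st <- solve(A, b)
      k3 * st[3] - 0 * st[1]
    }, numeric(1))
  }
  vmax <- rate(x_max)
  ks <- stats::uniroot(function(s) rate(s) - vmax / 2,
                       lower = 1e-12, upper = x_max, tol = 1e-12)$root
  list(kcat_plus = vmax, K_s = ks, rate = rate)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' @param values_pass,values_fail numeric samples (n >= 5 each)
#' @param parameter label carried through to the result
#' @return list with `parameter`, `D`, `p_value`, `n_pass`, `n_fail`
#' @export
ks_compare <- function(values_pass, values_fail, parameter = "parameter") {
  if (length(values_pass) < 5L || length(values_fail) < 5L) {
    sphingo_abort("insufficient_data", "KS comparison needs >= 5 values per group")
  }
  kt <- suppressWarnings(stats::ks.test(values_pass, values_fail))
  list(parameter = parameter, D = unname(kt$statistic), p_value = kt$p.value,
       n_pass = length(values_pass), n_fail = length(values_fail))
}

#' Compare apparent-parameter distributions between passing and failing models
#'
#' Lumps every enzyme chain of every model, splits by the screen outcome and
#' runs a two-sample KS test per lumped parameter. Raw p-values are reported
#' (matching the screening criterion `p < alpha`); a Bonferroni-adjusted
#' column is attached as a multiple-testing flag.
#'
#' @param ens `sphingo_ensemble`
#' @param screen `sphingo_screen` from the same ensemble
#' @param alpha significance threshold (default 0.001)
#' @return data frame with one row per (enzyme, reaction, branch, parameter)
#' @export
compare_pass_fail <- function(ens, screen, alpha = 0.001) {
  if (length(ens$models) != screen$n_models) {
    sphingo_abort("config", "screen result does not match the ensemble size")
  }
  if (!any(screen$model_pass)) {
    message("no passing models; nothing to compare")
    return(data.frame())
  }
  if (all(screen$model_pass)) {
    sphingo_abort("insufficient_data", "all models pass; no failing subset to compare")
  }
  enzymes <- names(ens$elem$enzyme_states)
  tabs <- lapply(seq_along(ens$models), function(i) {
    tb <- do.call(rbind, lapply(enzymes, function(e)
      lump_apparent_params(ens$models[[i]], ens$elem, e)))
    tb$model <- i
    tb$passed <- screen$model_pass[i]
    tb
  })
  tab <- do.call(rbind, tabs)
  keys <- unique(tab[, c("enzyme", "rxn_id", "branch")])
  out <- list()
  for (r in seq_len(nrow(keys))) {
    sel <- tab$enzyme == keys$enzyme[r] & tab$rxn_id == keys$rxn_id[r] &
      tab$branch == keys$branch[r]
    for (par in c("kcat_plus", "K_s")) {
      vp <- tab[[par]][sel & tab$passed]
      vf <- tab[[par]][sel & !tab$passed]
      if (length(vp) < 5L || length(vf) < 5L) next
      ks <- ks_compare(vp, vf, parameter = par)
      out[[length(out) + 1L]] <- data.frame(
        enzyme = keys$enzyme[r], rxn_id = keys$rxn_id[r], branch = keys$branch[r],
        parameter = par, D = ks$D, p_value = ks$p_value,
        p_bonferroni = NA_real_, significant = NA,
        n_pass = ks$n_pass, n_fail = ks$n_fail, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(data.frame())
  res$p_bonferroni <- pmin(1, res$p_value * nrow(res))
  res$significant <- res$p_value < alpha
  res[order(res$p_value), ]
}
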