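# Kinetic-model generation: anchor elementary mass-action rate constants to
# the reference steady state under sampled reversibilities and enzyme
# fractions (ensemble modeling core, with the activation extension).

#' Normalized rate constants for one chain from rates and occupancies
#'
#' `K = v_ref / (product of reference activities of the step's reactants)`;
#' metabolite activities are 1 at reference, enzyme-state activities are the
#' sampled fractions.
#'
#' @param v_steps named or positional vector of elementary rates (one per
#'   elementary reaction row)
#' @param rows step-row indices the rates belong to
#' @param elem `sphingo_elementary`
#' @param x_ref reference species vector
#' @return rate constants aligned with `rows`
#' @export
compute_rate_constants <- function(v_steps, rows, elem, x_ref) {
  stopifnot(length(v_steps) == length(rows))
  K <- numeric(length(rows))
  for (k in seq_along(rows)) {
    st <- elem$steps[rows[k], ]
    act <- x_ref[st$r1]
    if (!is.na(st$r2)) act <- act * x_ref[st$r2]
    # pooled regulator signal has reference activity 1
    if (act <= 0 && v_steps[k] != 0) {
      sphingo_abort("degenerate", "zero reactant activity with nonzero rate in step ", rows[k])
    }
    K[k] <- if (v_steps[k] == 0) 0 else v_steps[k] / act
  }
  K
}

#' Generate one kinetic model anchored to the reference state
#'
#' Samples enzyme fractions, activation splits, reversibilities and
#' regulatory binding scales, then back-computes all elementary rate
#' constants so that evaluating the system at the reference state reproduces
#' the reference fluxes exactly.
#'
#' @param elem `sphingo_elementary`
#' @param ref `sphingo_reference` (fluxes used on the SPT-normalized scale)
#' @param conc_ratio_range thermodynamic concentration-ratio range
#' @param alpha_min lower bound of the activated-branch flux share
#' @param strict_activation if `TRUE` the basal branch of an activated enzyme
#'   is catalytically inactive (activated share is 1)
#' @param zero_flux how to treat zero-reference-flux enzymatic reactions:
#'   `"error"` (default) or `"exclude"` (chain constants set to 0)
#' @return a `sphingo_model` (list with `K`, `x_ref`, `alpha`, `reversibilities`)
#' @export
generate_kinetic_model <- function(elem, ref, conc_ratio_range = c(1e-3, 1e3),
                                   alpha_min = 0.5, strict_activation = FALSE,
                                   zero_flux = c("error", "exclude")) {
  zero_flux <- match.arg(zero_flux)
  net <- ref$network
  n_sp <- nrow(elem$species)
  x_ref <- rep(1, n_sp)

  # enzyme-state fractions: unit-sum simplex per reaction pool
  for (rid in names(elem$instance_states)) {
    states <- elem$instance_states[[rid]]
    x_ref[states] <- sample_enzyme_fractions(length(states))
  }

  # regulator-state fractions: a regulator with sequestration complexes
  # (e.g. ceramide-bound ORM) has its reference occupancy sampled on the
  # simplex as well -- regulatory and metabolic parameters are sampled
  # simultaneously, and the free/sequestered ratio sets the feedback gain
  for (rg in names(elem$reg_pools %||% list())) {
    states <- elem$reg_pools[[rg]]
    x_ref[states] <- sample_enzyme_fractions(length(states))
  }

  # activation splits: one draw per activated enzyme, shared by its reactions
  alpha <- list()
  for (rid in names(elem$ea_state)) {
    e <- elem$ea_state[[rid]]$enzyme
    if (is.null(alpha[[e]])) {
      alpha[[e]] <- if (strict_activation) 1 else stats::runif(1, alpha_min, 1)
    }
  }

  v <- numeric(nrow(elem$steps))
  revs <- list()
  for (ch_name in names(elem$chains)) {
    ch <- elem$chains[[ch_name]]
    V_rxn <- ref$fluxes_spt[[ch$rxn_id]]
    if (V_rxn == 0) {
      if (zero_flux == "error") {
        sphingo_abort("config", "reaction '", ch$rxn_id, "' carries zero reference ",
                      "flux and cannot be normalized; drop it or use the ",
                      "epsilon-flux option of the reference state")
      }
      next
    }
    share <- if (is.null(elem$ea_state[[ch$rxn_id]])) 1
             else if (ch$branch == "activated") alpha[[ch$enzyme]]
             else 1 - alpha[[ch$enzyme]]
    V <- V_rxn * share
    if (V == 0) next  # strict activation: basal branch inactive
    dg <- net$reactions$delta_g0[net$reactions$id == ch$rxn_id]
    b <- gibbs_to_bounds(dg, conc_ratio_range, sign_vnet = sign(V))
    R <- sample_reversibilities(3L, b, sign_vnet = sign(V), rxn_id = ch$rxn_id)
    rates <- elementary_rates_from_R(V, R)
    v[ch$rows[c(1, 3, 5)]] <- rates$v_fwd
    v[ch$rows[c(2, 4, 6)]] <- rates$v_rev
    revs[[ch_name]] <- R
  }

  # regulatory binding steps: zero net flux at reference, sampled exchange scale
  for (rs_name in names(elem$reg_steps)) {
    rs <- elem$reg_steps[[rs_name]]
    w <- stats::runif(1)
    v[rs$f] <- w
    v[rs$r] <- w
  }

  # sinks anchored to the reference export of each species
  sink_flux <- reference_sink_fluxes(ref)
  for (spid in names(elem$sinks)) {
    v[elem$sinks[[spid]]$row] <- if (spid %in% names(sink_flux)) sink_flux[[spid]] else 0
  }

  K <- compute_rate_constants(v, seq_len(nrow(elem$steps)), elem, x_ref)
  structure(list(K = K, x_ref = x_ref, alpha = alpha, reversibilities = revs,
                 v_ref = v),
            class = "sphingo_model")
}

#' Generate an ensemble of kinetic models
#'
#' Repeats [generate_kinetic_model()] `n_models` times from a single seed.
#' Every model is verified to reproduce the reference steady state (residual
#' of the full ODE right-hand side below `1e-9`); failing draws are logged
#' and resampled.
#'
#' @param ref `sphingo_reference`
#' @param scheme `sphingo_scheme`
#' @param n_models ensemble size
#' @param seed integer seed (all pipeline randomness derives from it)
#' @param verify_integration also require a short integration to stay at the
#'   reference (slower; the residual check is always applied)
#' @param ... passed to [generate_kinetic_model()]
#' @return a `sphingo_ensemble`: list with `elem`, `ref`, `models`,
#'   `scheme_id`, `seed`, `n_rejected`
#' @export
generate_ensemble <- function(ref, scheme = new_scheme(NULL), n_models = 200L,
                              seed = 1L, verify_integration = FALSE, ...) {
  elem <- decompose_to_elementary(ref$network, scheme)
  models <- vector("list", n_models)
  n_rej <- 0L
  with_seed(derive_seed(seed, paste0("ensemble|", scheme$scheme_id)), {
    i <- 1L
    while (i <= n_models) {
      m <- generate_kinetic_model(elem, ref, ...)
      chk <- verify_reference(m, elem, integrate = verify_integration)
      if (chk$ok) {
        models[[i]] <- m
        i <- i + 1L
      } else {
        n_rej <- n_rej + 1L
        if (n_rej > max(10L, n_models)) {
          sphingo_abort("generation", "rejection rate above 50%; ",
                        "check thermodynamic bounds and reference fluxes")
        }
      }
    }
  })
  if (n_rej > 0.5 * max(n_models, 1L)) {
    sphingo_warn("generation", n_rej, " of ", n_models + n_rej,
                 " sampled models failed reference verification")
  }
  structure(list(elem = elem, ref = ref, models = models,
                 scheme_id = scheme$scheme_id, seed = seed, n_rejected = n_rej),
            class = "sphingo_ensemble")
}

#' @export
print.sphingo_ensemble <- function(x, ...) {
  cat("<sphingo_ensemble> ", length(x$models), " models, scheme ", x$scheme_id,
      ", seed ", x$seed, ", ", x$n_rejected, " rejected\n", sep = "")
  invisible(x)
}

#' Serialize an ensemble to a JSON-lines archive
#'
#' First line is a metadata header (scheme id, seed, network hash, species
#' ids); each following line is one model's parameter vector.
#'
#' @param ens `sphingo_ensemble`
#' @param path output file
#' @export
write_ensemble <- function(ens, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hash <- sum(utf8ToInt(paste(ens$ref$network$reactions$id, collapse = ","))) %% 1e9
  header <- list(scheme_id = ens$scheme_id, seed = ens$seed,
                 network_hash = hash, n_models = length(ens$models),
                 species = ens$elem$species$id)
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA), con)
  for (m in ens$models) {
    writeLines(jsonlite::toJSON(list(K = m$K, x_ref = m$x_ref), digits = NA), con)
  }
  invisible(path)
}
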