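# Perturbation screening: apply the perturbation/filter table to every model
# of an ensemble, and rank candidate regulatory schemes by how many of their
# models satisfy all observed responses.

#' Default perturbation set
#'
#' ORM over-expression and knockdown plus class I ceramide synthase
#' over-expression. The magnitudes are conventions (the observations are
#' qualitative): OE defaults to a 2x fold change, RNAi to 0.2x. The OE
#' default matters: at the reference branching, a CSI over-expression much
#' beyond 2x creates more demand for sphinganine than any regulatory relief
#' can free, so the observed sphinganine accumulation becomes structurally
#' unreachable (see the methods vignette). Robustness at other folds is
#' worth reporting alongside any screen.
#'
#' @param oe_fold fold change for over-expression (default 2)
#' @param rnai_fold fold change for knockdown (default 0.2)
#' @return data frame with columns `label`, `target`, `fold`
#' @export
default_perturbations <- function(oe_fold = 2, rnai_fold = 0.2) {
  data.frame(
    label = c("ORM_RNAi", "ORM_OE", "CSI_OE"),
    target = c("orm", "orm", "CSI"),
    fold = c(rnai_fold, oe_fold, oe_fold),
    stringsAsFactors = FALSE
  )
}

#' Default filter table (perturbations and associated filtration steps)
#'
#' Encodes the experimentally observed responses the models must reproduce:
#' differential ceramide-synthase activity under ORM perturbations, LCB and
#' ceramide concentration shifts under ORM OE, and LCB/ceramide-pool shifts
#' under CSI OE. "Activity" is steady-state net flux summed over the
#' enzyme's reactions; "C16-cer"/"C24-cer" are pooled free-ceramide
#' concentrations grouped by acyl length.
#'
#' @param epsilon relative change threshold for calling up/down (default 0.05)
#' @return data frame with columns `perturbation`, `observable`
#'   (`reaction_flux`, `species_concentration`, `pooled_concentration`),
#'   `target`, `direction`, `epsilon`
#' @export
default_filters <- function(epsilon = 0.05) {
  f <- function(p, obs, tgt, dir) data.frame(
    perturbation = p, observable = obs, target = tgt, direction = dir,
    epsilon = epsilon, stringsAsFactors = FALSE)
  rbind(
    f("ORM_RNAi", "reaction_flux", "CSI", "up"),
    f("ORM_RNAi", "reaction_flux", "CSII", "down"),
    f("ORM_OE", "reaction_flux", "CSI", "down"),
    f("ORM_OE", "reaction_flux", "CSII", "up"),
    f("ORM_OE", "species_concentration", "t18_0", "down"),
    f("ORM_OE", "species_concentration", "cer_d18_1_hc16", "down"),
    f("ORM_OE", "species_concentration", "cer_d18_1_hc24", "up"),
    f("CSI_OE", "species_concentration", "d18_0", "up"),
    f("CSI_OE", "pooled_concentration", "c16_cer", "up"),
    f("CSI_OE", "pooled_concentration", "c24_cer", "down")
  )
}

#' Resolve a filter target to species indices / observable accessor
#' @noRd
resolve_filter_target <- function(rule, elem) {
  net <- elem$network
  if (rule$observable == "reaction_flux") {
    if (!rule$target %in% net$reactions$enzyme) {
      sphingo_abort("rule", "filter targets unknown enzyme '", rule$target, "'")
    }
    return(list(kind = "flux", key = rule$target))
  }
  if (rule$observable == "species_concentration") {
    i <- match(rule$target, elem$species$id)
    if (is.na(i)) sphingo_abort("rule", "filter targets unknown species '", rule$target, "'")
    return(list(kind = "conc", idx = i))
  }
  if (rule$observable == "pooled_concentration") {
    mets <- net$metabolites
    free_cer <- mets$id[mets$species_class %in% c("ceramide", "hydroxyceramide")]
    members <- switch(rule$target,
      c16_cer = free_cer[mets$acyl_length[match(free_cer, mets$id)] == 16],
      c24_cer = free_cer[mets$acyl_length[match(free_cer, mets$id)] == 24],
      ceramide = free_cer,
      sphingo_abort("rule", "unknown pool '", rule$target, "'"))
    idx <- match(members, elem$species$id)
    if (!length(idx) || anyNA(idx)) {
      sphingo_abort("rule", "pool '", rule$target, "' resolves to no species")
    }
    return(list(kind = "pool", idx = idx))
  }
  sphingo_abort("rule", "unknown observable '", rule$observable, "'")
}

#' Evaluate filter rules on a reference / perturbed state pair
#'
#' An "up" rule passes iff the perturbed observable exceeds the reference
#' value by more than the relative tolerance; "down" mirrors it. No change
#' is neither an increase nor a decrease.
#'
#' @param ref_state `sphingo_steady` (or a list with `x` and `enzyme_flux`)
#' @param pert_state `sphingo_steady`
#' @param rules filter table rows (see [default_filters()])
#' @param elem `sphingo_elementary`
#' @return logical vector, one entry per rule
#' @export
evaluate_filters <- function(ref_state, pert_state, rules, elem) {
  vapply(seq_len(nrow(rules)), function(k) {
    rule <- rules[k, ]
    tg <- resolve_filter_target(rule, elem)
    obs <- function(state) {
      switch(tg$kind,
             flux = unname(state$enzyme_flux[tg$key]),
             conc = state$x[tg$idx],
             pool = sum(state$x[tg$idx]))
    }
    a <- obs(ref_state); b <- obs(pert_state)
    if (tg$kind == "pool") {
      w <- elem$abundance[tg$idx]
      if (sum(w) <= 0) w <- rep(1, length(tg$idx))
      a <- sum(ref_state$x[tg$idx] * w) / sum(w)
      b <- sum(pert_state$x[tg$idx] * w) / sum(w)
    }
    if (rule$direction == "up") b > a * (1 + rule$epsilon)
    else if (rule$direction == "down") b < a * (1 - rule$epsilon)
    else sphingo_abort("rule", "direction must be 'up' or 'down'")
  }, logical(1))
}

#' Screen an ensemble against a perturbation/filter table
#'
#' Every filter is evaluated for every model under every perturbation (no
#' early elimination), so the outcome is invariant to the order in which
#' perturbations are applied. Perturbed simulations that fail to converge
#' fail all their filters and are counted separately.
#'
#' @param ens `sphingo_ensemble`
#' @param perturbations data frame (`label`, `target`, `fold`), default
#'   [default_perturbations()]
#' @param filters filter table, default [default_filters()]
#' @param t_max integration horizon per perturbation
#' @return `sphingo_screen`: list with the pass matrix (`models x rules`),
#'   `model_pass`, `n_pass`, `pass_fraction`, `n_nonconverged`
#' @export
screen_ensemble <- function(ens, perturbations = default_perturbations(),
                            filters = default_filters(), t_max = 1e6) {
  if (!length(ens$models)) sphingo_abort("screen", "ensemble is empty")
  bad <- setdiff(filters$perturbation, perturbations$label)
  if (length(bad)) {
    sphingo_abort("config", "filters reference unknown perturbation(s): ",
                  paste(unique(bad), collapse = ", "))
  }
  for (p in perturbations$label) {
    if (!any(filters$perturbation == p)) {
      sphingo_abort("config", "perturbation '", p, "' has no filter rule")
    }
  }
  elem <- ens$elem
  n_m <- length(ens$models)
  rule_ids <- paste(filters$perturbation, filters$observable, filters$target,
                    filters$direction, sep = "|")
  pass <- matrix(FALSE, n_m, nrow(filters), dimnames = list(NULL, rule_ids))
  nonconv <- matrix(FALSE, n_m, nrow(perturbations),
                    dimnames = list(NULL, perturbations$label))
  for (i in seq_len(n_m)) {
    model <- ens$models[[i]]
    sys <- assemble_rhs(model, elem)
    ref_state <- list(x = model$x_ref,
                      enzyme_flux = reaction_net_fluxes(sys, model$x_ref)$enzyme)
    for (p in seq_len(nrow(perturbations))) {
      pert <- perturbations[p, ]
      x0 <- apply_perturbation(elem, model$x_ref, pert$target, pert$fold)
      ss <- simulate_to_steady_state(sys, x0 = x0, t_max = t_max)
      sel <- filters$perturbation == pert$label
      if (!ss$converged) {
        nonconv[i, p] <- TRUE
        pass[i, sel] <- FALSE
      } else {
        pass[i, sel] <- evaluate_filters(ref_state, ss, filters[sel, , drop = FALSE], elem)
      }
    }
  }
  model_pass <- apply(pass, 1, all)
  structure(list(
    pass = pass, model_pass = model_pass,
    n_models = n_m, n_pass = sum(model_pass),
    pass_fraction = mean(model_pass),
    n_nonconverged = colSums(nonconv),
    filters = filters, perturbations = perturbations,
    scheme_id = ens$scheme_id
  ), class = "sphingo_screen")
}

#' @export
print.sphingo_screen <- function(x, ...) {
  cat("<sphingo_screen> scheme ", x$scheme_id, ": ", x$n_pass, "/", x$n_models,
      " models pass all filters\n", sep = "")
  per <- colMeans(x$pass)
  for (nm in names(per)) cat(sprintf("  %-55s %5.1f%%\n", nm, 100 * per[nm]))
  invisible(x)
}

#' Generate, screen and rank an ensemble per regulatory scheme
#'
#' Each scheme gets its own ensemble (common base seed offset by scheme id,
#' so schemes are comparable but kinetic and regulatory parameters are
#' sampled jointly per scheme). A scheme passes when at least `min_pass`
#' models satisfy every filter.
#'
#' @param ref `sphingo_reference`
#' @param schemes list of `sphingo_scheme`
#' @param n_models models per scheme
#' @param seed base seed
#' @param min_pass models required for a scheme to pass (default 1)
#' @param perturbations,filters as in [screen_ensemble()]
#' @param ... passed to [generate_ensemble()]
#' @return `sphingo_scheme_screen`: report data frame (sorted by pass
#'   fraction) plus the per-scheme screen objects
#' @export
screen_schemes <- function(ref, schemes, n_models = 200L, seed = 1L, min_pass = 1L,
                           perturbations = default_perturbations(),
                           filters = default_filters(), ...) {
  if (!length(schemes)) sphingo_abort("screen", "no schemes supplied")
  rows <- list(); screens <- list()
  for (s in schemes) {
    res <- tryCatch({
      ens <- generate_ensemble(ref, s, n_models = n_models, seed = seed, ...)
      screen_ensemble(ens, perturbations, filters)
    }, sphingoem_thermo = function(e) e, sphingoem_generation = function(e) e)
    if (inherits(res, "condition")) {
      rows[[s$scheme_id]] <- data.frame(
        scheme_id = s$scheme_id, n_models = 0L, n_pass = 0L, pass_fraction = NA_real_,
        passes = FALSE, infeasible = TRUE,
        has_cer_orm = any(s$edges$regulator == "ceramide" & s$edges$target == "orm"),
        has_csii_activation = any(s$edges$target == "CSII" & s$edges$mode == "activation"),
        edges = paste(s$edges$regulator,
                      ifelse(s$edges$mode == "activation", "->", "-|"),
                      s$edges$target, collapse = "; "),
        stringsAsFactors = FALSE)
      next
    }
    screens[[s$scheme_id]] <- res
    rows[[s$scheme_id]] <- data.frame(
      scheme_id = s$scheme_id, n_models = res$n_models, n_pass = res$n_pass,
      pass_fraction = res$pass_fraction, passes = res$n_pass >= min_pass,
      infeasible = FALSE,
      has_cer_orm = any(s$edges$regulator == "ceramide" & s$edges$target == "orm"),
      has_csii_activation = any(s$edges$target == "CSII" & s$edges$mode == "activation"),
      edges = paste(s$edges$regulator,
                    ifelse(s$edges$mode == "activation", "->", "-|"),
                    s$edges$target, collapse = "; "),
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  report <- report[order(-replace(report$pass_fraction, is.na(report$pass_fraction), -1)), ]
  rownames(report) <- NULL
  structure(list(report = report, screens = screens, seed = seed,
                 n_models = n_models),
            class = "sphingo_scheme_screen")
}

#' @export
print.sphingo_scheme_screen <- function(x, ...) {
  cat("<sphingo_scheme_screen> ", sum(x$report$passes), " of ", nrow(x$report),
      " schemes pass (", x$n_models, " models each)\n", sep = "")
  print(x$report[, c("scheme_id", "n_pass", "pass_fraction", "passes", "edges")])
  invisible(x)
}
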