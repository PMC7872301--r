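# Biomass reaction from sphingolipid composition.

#' Build the biomass reaction from a composition profile
#'
#' The biomass pseudo-reaction consumes each measured sphingolipid species
#' with a stoichiometric coefficient proportional to its mole fraction of
#' total sphingolipid; its flux is fixed to the measured growth rate. With
#' fractions summing to 1, one unit of biomass flux consumes one unit of
#' total sphingolipid, so the pathway entry flux equals the growth rate
#' before SPT-normalization (the absolute scale is arbitrary downstream).
#'
#' @param comp data frame with columns `species_id`, `mole_fraction`.
#' @param rate growth rate (1/day); becomes both bounds of the reaction.
#' @param net `sphingo_network` the composition must map onto.
#' @return a one-row reaction table (same dialect as [build_network()] input)
#'   with the stoichiometry attached as attribute `stoich`.
#' @export
build_biomass_reaction <- function(comp, rate, net) {
  if (!all(c("species_id", "mole_fraction") %in% names(comp))) {
    sphingo_abort("format", "composition needs columns species_id, mole_fraction")
  }
  comp <- comp[comp$mole_fraction != 0, , drop = FALSE]
  if (any(comp$mole_fraction < 0)) {
    sphingo_abort("domain", "mole fractions must be >= 0")
  }
  tot <- sum(comp$mole_fraction)
  if (abs(tot - 1) > 1e-6) {
    comp$mole_fraction <- comp$mole_fraction / tot
  }
  missing <- setdiff(comp$species_id, net$metabolites$id)
  if (length(missing)) {
    sphingo_abort("mapping", "composition species absent from network: ",
                  paste(missing, collapse = ", "))
  }
  st <- stats::setNames(-comp$mole_fraction, comp$species_id)
  eq <- paste(paste(format(comp$mole_fraction, trim = TRUE, scientific = FALSE),
                    comp$species_id), collapse = " + ")
  out <- data.frame(rxn_id = "biomass", enzyme = "biomass", genes = "",
                    equation = paste(eq, "->"), delta_g0_kJ_mol = NA_real_,
                    lb = rate, ub = rate, stringsAsFactors = FALSE)
  attr(out, "stoich") <- st
  out
}

#' Attach a biomass reaction to a network
#'
#' @param net `sphingo_network`
#' @param biomass one-row reaction table from [build_biomass_reaction()].
#' @return new `sphingo_network` including the biomass reaction.
#' @export
attach_biomass <- function(net, biomass) {
  if (any(net$reactions$type == "biomass")) {
    keep <- net$reactions$type != "biomass"
    net$reactions <- net$reactions[keep, ]
    net$stoich <- net$stoich[net$reactions$id]
  }
  net$reactions <- rbind(net$reactions, data.frame(
    id = biomass$rxn_id, enzyme = "biomass", genes = biomass$genes,
    delta_g0 = NA_real_, lb = biomass$lb, ub = biomass$ub, type = "biomass",
    stringsAsFactors = FALSE))
  net$stoich[[biomass$rxn_id]] <- attr(biomass, "stoich")
  validate_network(net)
  net
}
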