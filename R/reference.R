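# Reference steady state: SPT-normalized net fluxes plus normalization
# conventions (all concentrations and enzyme totals are 1 at reference).

#' Construct a reference state from a flux vector
#'
#' Fluxes are stored both on the input scale and normalized so the summed
#' SPT flux equals 1 (the convention used for every figure-level branching
#' fraction). Enzymatic reactions with exactly zero flux are recorded as
#' excluded from kinetic parameterization, since the elementary-rate
#' construction divides by the net flux.
#'
#' @param net `sphingo_network` (with biomass attached if used)
#' @param v named flux vector over `net$reactions$id`
#' @return `sphingo_reference`
#' @export
new_reference_state <- function(net, v) {
  stopifnot(all(net$reactions$id %in% names(v)))
  v <- v[net$reactions$id]
  spt <- sum(v[net$reactions$enzyme == "SPT"])
  if (!is.finite(spt) || spt <= 0) {
    sphingo_abort("validation", "reference SPT flux must be positive; got ", spt)
  }
  enz <- net$reactions$type == "enzymatic"
  excluded <- net$reactions$id[enz & v == 0]
  bio <- which(net$reactions$type == "biomass")
  structure(list(
    network = net,
    fluxes = v,
    fluxes_spt = v / spt,
    spt_flux = spt,
    v_biomass = if (length(bio)) unname(v[bio]) else NA_real_,
    excluded = excluded
  ), class = "sphingo_reference")
}

#' @export
print.sphingo_reference <- function(x, ...) {
  cat("<sphingo_reference> SPT flux ", signif(x$spt_flux, 4),
      ", biomass ", signif(x$v_biomass, 4), "; ",
      length(x$excluded), " zero-flux enzymatic reaction(s)\n", sep = "")
  invisible(x)
}

#' Per-species reference export (sink) flux
#'
#' Sum over biomass and exchange reactions of the species' consumption at the
#' reference flux, on the SPT-normalized scale. Used to anchor the
#' first-order sink steps of the kinetic model.
#' @noRd
reference_sink_fluxes <- function(ref) {
  net <- ref$network
  out <- numeric(0)
  for (rid in net$reactions$id[net$reactions$type %in% c("biomass", "exchange")]) {
    st <- net$stoich[[rid]]
    cons <- st[st < 0]
    for (spid in names(cons)) {
      out[spid] <- (if (spid %in% names(out)) out[[spid]] else 0) -
        cons[[spid]] * ref$fluxes_spt[[rid]]
    }
  }
  out
}

#' Default branching fractions of the reference flux distribution
#'
#' `csii_share`: fraction of SPT flux through class II ceramide synthase;
#' `gcs_c16_share`: fraction of GCS flux on C16 substrates; `gcs_gipcs_split`:
#' GCS share of the combined GCS+GIPCS flux; `phospho_share`: flux fraction to
#' phosphorylated LCBs (0 in the core fixture, which carries no kinase);
#' `glyco_share`: fraction of SPT flux reaching glycosylated end products.
#' @return named list of defaults
#' @export
default_branching <- function() {
  list(csii_share = 0.73, gcs_c16_share = 0.30, gcs_gipcs_split = 0.50,
       phospho_share = 0, glyco_share = 0.80)
}

#' Per-species accumulation fractions implied by branching fractions
#'
#' Works backwards from the target flux branching on the core network: end
#' products (GlcCer, GIPC) receive the glycosylated share, and each chain's
#' residual is spread evenly over its free-ceramide intermediates so all
#' implied reaction fluxes are positive. The result is the composition
#' (mole-fraction) vector that makes pFBA reproduce the branching exactly.
#'
#' @param fractions list like [default_branching()]
#' @return named numeric vector of mole fractions (sums to 1)
#' @export
branching_to_composition <- function(fractions = default_branching()) {
  f <- utils::modifyList(default_branching(), fractions)
  for (nm in c("csii_share", "gcs_c16_share", "gcs_gipcs_split",
               "phospho_share", "glyco_share")) {
    if (f[[nm]] < 0 || f[[nm]] > 1) {
      sphingo_abort("validation", nm, " must lie in [0, 1]; got ", f[[nm]])
    }
  }
  if (f$phospho_share != 0) {
    sphingo_abort("validation", "phospho_share must be 0 on the core network ",
                  "(no kinase reaction); configure an extended network instead")
  }
  s <- f$csii_share
  g <- f$glyco_share * f$gcs_gipcs_split          # total GCS flux
  p <- f$glyco_share * (1 - f$gcs_gipcs_split)    # total GIPCS flux
  gcs_c16 <- f$gcs_c16_share * g
  gcs_c24 <- (1 - f$gcs_c16_share) * g
  csi <- 1 - s
  # C16 chain: CSI -> SLD -> FAH -> GCS; residual spread over 3 intermediates
  res16 <- csi - gcs_c16
  if (res16 < 0) {
    sphingo_abort("generation", "CSI flux (", csi, ") below the GCS C16 demand (",
                  gcs_c16, "); branching fractions inconsistent with topology")
  }
  # C24 side: CSII splits into the t18:0 route (-> GIPCS) and the d18:0 route
  # (-> GCS C24); the slack is spread over the 2 + 3 intermediates.
  res24 <- s - p - gcs_c24
  if (res24 < 0) {
    sphingo_abort("generation", "CSII flux (", s, ") below the C24 end-product ",
                  "demand (", p + gcs_c24, "); branching fractions inconsistent")
  }
  res_t <- res24 * 2 / 5
  res_d <- res24 * 3 / 5
  comp <- c(
    cer_d18_0_c16   = res16 / 3,
    cer_d18_1_c16   = res16 / 3,
    cer_d18_1_hc16  = res16 / 3,
    glccer_hc16     = gcs_c16,
    cer_t18_0_c24   = res_t / 2,
    cer_t18_0_hc24  = res_t / 2,
    gipc_hc24       = p,
    cer_d18_0_c24   = res_d / 3,
    cer_d18_1_c24   = res_d / 3,
    cer_d18_1_hc24  = res_d / 3,
    glccer_hc24     = gcs_c24
  )
  comp <- comp[comp > 0]
  comp / sum(comp)
}

#' Reaction fluxes implied by per-species accumulation on a tree network
#'
#' On the core network every tracked species has a single producing reaction,
#' so fluxes follow by summing accumulation over everything downstream
#' (reverse topological order). Exchange fluxes of buffered inputs are left
#' at zero (they carry no balance rows).
#' @noRd
implied_fluxes <- function(net, acc) {
  enz <- net$reactions[net$reactions$type == "enzymatic", ]
  producers <- list(); consumers <- list()
  for (rid in enz$id) {
    st <- net$stoich[[rid]]
    for (spid in names(st)) {
      if (st[[spid]] > 0) producers[[spid]] <- c(producers[[spid]], rid)
      if (st[[spid]] < 0) consumers[[spid]] <- c(consumers[[spid]], rid)
    }
  }
  v <- stats::setNames(rep(NA_real_, nrow(enz)), enz$id)
  get_flux <- function(rid) {
    if (!is.na(v[[rid]])) return(v[[rid]])
    st <- net$stoich[[rid]]
    prod_sp <- names(st)[st > 0]
    prod_sp <- prod_sp[prod_sp %in% names(acc) | vapply(prod_sp, function(s)
      length(consumers[[s]]) > 0, logical(1))]
    total <- 0
    for (spid in prod_sp) {
      a <- if (spid %in% names(acc)) acc[[spid]] else 0
      down <- sum(vapply(consumers[[spid]] %||% character(0), get_flux, numeric(1)))
      total <- total + a + down
    }
    v[[rid]] <<- total
    total
  }
  for (rid in enz$id) get_flux(rid)
  v
}

#' Build a reference state directly from branching fractions
#'
#' Bypasses the LP: converts branching fractions to a composition profile,
#' derives the implied balanced flux vector on the core network, and returns
#' it SPT-normalized. Used for fixtures and fast tests; `solve_pfba` on the
#' same composition reproduces these fluxes.
#'
#' @param fractions list like [default_branching()]
#' @param net the core network (default [fixture_network()])
#' @param rate growth rate attached to the biomass reaction (default 0.2/day)
#' @return `sphingo_reference`
#' @export
reference_from_fractions <- function(fractions = default_branching(),
                                     net = fixture_network(), rate = 0.2) {
  comp <- branching_to_composition(fractions)
  bio <- build_biomass_reaction(
    data.frame(species_id = names(comp), mole_fraction = unname(comp)),
    rate = rate, net = net)
  net2 <- attach_biomass(net, bio)
  acc <- comp * rate
  venz <- implied_fluxes(net2, acc)
  v <- stats::setNames(rep(0, nrow(net2$reactions)), net2$reactions$id)
  v[names(venz)] <- venz
  v[["biomass"]] <- rate
  S <- build_stoichiometric_matrix(net2, trim = TRUE)
  resid <- max(abs(S %*% v[colnames(S)]))
  if (resid > 1e-9) {
    sphingo_abort("validation", "implied fluxes violate mass balance (residual ",
                  signif(resid, 3), ")")
  }
  new_reference_state(net2, v)
}
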