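# Synthetic data: fixture networks, growth series and composition profiles
# emulating the study inputs so the full pipeline runs without downloads.

#' Generator configuration with study-calibrated defaults
#'
#' Defaults state the emulated world: exponential growth at 0.2/day sampled
#' at days 5/10/15/20 with three replicates of ten seedlings, lognormal
#' weight noise (sigma 0.05), and composition calibrated so the reference
#' fluxes reproduce the printed branching (73% of SPT flux through class II
#' ceramide synthase, 30% of GCS flux on C16 species, similar GCS and GIPCS
#' activity, no phosphorylated species).
#'
#' @param ... overrides for any default field
#' @return list of generator settings
#' @export
generator_config <- function(...) {
  cfg <- list(
    growth_rate = 0.2, initial_weight = 2, days = c(5, 10, 15, 20),
    n_replicates = 3, weight_noise_sigma = 0.05,
    branching = default_branching(), composition_noise_sigma = 0.05,
    seed = 1L
  )
  over <- list(...)
  cfg[names(over)] <- over
  if (!is.null(over$branching)) {
    cfg$branching <- utils::modifyList(default_branching(), over$branching)
  }
  if (cfg$weight_noise_sigma < 0 || cfg$composition_noise_sigma < 0) {
    sphingo_abort("domain", "noise sigma must be >= 0")
  }
  if (is.unsorted(cfg$days, strictly = TRUE)) {
    sphingo_abort("domain", "days must be strictly increasing")
  }
  cfg
}

#' Generate a synthetic dry-weight growth series
#'
#' `w = w0 * exp(mu * t) * exp(N(0, sigma^2))`; exactly exponential when
#' `sigma = 0`. All randomness flows from `config$seed`.
#'
#' @param config from [generator_config()]
#' @return data frame with columns `day`, `replicate`, `dry_weight`
#' @export
generate_growth_series <- function(config = generator_config()) {
  with_seed(derive_seed(config$seed, "growth"), {
    grid <- expand.grid(replicate = seq_len(config$n_replicates), day = config$days)
    noise <- if (config$weight_noise_sigma > 0) {
      stats::rnorm(nrow(grid), 0, config$weight_noise_sigma)
    } else rep(0, nrow(grid))
    data.frame(
      day = grid$day, replicate = grid$replicate,
      dry_weight = config$initial_weight * exp(config$growth_rate * grid$day + noise)
    )
  })
}

#' Generate a synthetic sphingolipid composition profile
#'
#' Composition is generated backwards from the target branching fractions
#' (fluxes -> end-product accumulation -> mole fractions) so the branching is
#' recoverable through pFBA as an end-to-end check; multiplicative lognormal
#' noise is applied per species and the profile renormalized.
#'
#' @param config from [generator_config()]
#' @return data frame with columns `species_id`, `mole_fraction`
#' @export
generate_composition <- function(config = generator_config()) {
  comp <- branching_to_composition(config$branching)
  with_seed(derive_seed(config$seed, "composition"), {
    if (config$composition_noise_sigma > 0) {
      comp <- comp * exp(stats::rnorm(length(comp), 0, config$composition_noise_sigma))
    }
    comp <- comp / sum(comp)
    data.frame(species_id = names(comp), mole_fraction = unname(comp))
  })
}

.FIXTURE_METS <- function() {
  data.frame(
    id = c("serine", "c16_coa", "c24_coa", "nadph", "udp_glucose", "inositol_p",
           "ketosphinganine", "d18_0", "t18_0",
           "cer_d18_0_c16", "cer_d18_1_c16", "cer_d18_1_hc16",
           "cer_d18_0_c24", "cer_d18_1_c24", "cer_d18_1_hc24",
           "cer_t18_0_c24", "cer_t18_0_hc24",
           "glccer_hc16", "glccer_hc24", "gipc_hc24", "orm"),
    name = c("L-serine", "palmitoyl-CoA", "C24 acyl-CoA pool", "NADPH",
             "UDP-glucose", "inositol phosphate donor",
             "3-ketosphinganine", "sphinganine d18:0", "trihydroxy LCB t18:0",
             "ceramide d18:0-C16", "ceramide d18:1-C16", "ceramide d18:1-hC16",
             "ceramide d18:0-C24", "ceramide d18:1-C24", "ceramide d18:1-hC24",
             "ceramide t18:0-C24", "ceramide t18:0-hC24",
             "GlcCer hC16", "GlcCer hC24", "GIPC hC24", "ORM protein"),
    species_class = c("cofactor", "acyl-CoA", "acyl-CoA", "cofactor", "cofactor",
                      "cofactor", "LCB", "LCB", "LCB",
                      "ceramide", "ceramide", "hydroxyceramide",
                      "ceramide", "ceramide", "hydroxyceramide",
                      "ceramide", "hydroxyceramide",
                      "GlcCer", "GlcCer", "GIPC", "regulator"),
    acyl_length = c(NA, 16, 24, NA, NA, NA, NA, NA, NA,
                    16, 16, 16, 24, 24, 24, 24, 24, 16, 24, 24, NA),
    hydroxylation = c(NA, NA, NA, NA, NA, NA, NA, "di", "tri",
                      "di", "di", "di", "di", "di", "di", "tri", "tri",
                      NA, NA, NA, NA),
    is_buffered = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                    rep(FALSE, 14), FALSE),
    stringsAsFactors = FALSE
  )
}

#' Core sphingolipid pathway fixture network
#'
#' The nine-enzyme pathway (SPT, KSR, SBH, CSI, CSII, SLD, FAH, GCS, GIPCS)
#' expanded over the C16/C24 acyl pools and di/tri-hydroxy LCB routes: 14
#' enzymatic reactions, with standard Gibbs energies attached per enzyme and
#' the LCB delta-8 desaturase set to a far-from-equilibrium default of
#' `sld_delta_g0` (no measured value is available for SLD).
#'
#' @param sld_delta_g0 standard Gibbs energy (kJ/mol) assigned to SLD
#'   reactions; default -50, flagged as a convention.
#' @return `sphingo_network`
#' @export
fixture_network <- function(sld_delta_g0 = -50) {
  rx <- function(id, enzyme, genes, eq, dg) {
    data.frame(rxn_id = id, enzyme = enzyme, genes = genes, equation = eq,
               delta_g0_kJ_mol = dg, lb = 0, ub = Inf, stringsAsFactors = FALSE)
  }
  tab <- rbind(
    rx("SPT",     "SPT",   "LCB1,LCB2", "1 serine + 1 c16_coa -> 1 ketosphinganine", 8.9),
    rx("KSR",     "KSR",   "TSC10",     "1 ketosphinganine + 1 nadph -> 1 d18_0",    -17.1),
    rx("SBH",     "SBH",   "SBH1,SBH2", "1 d18_0 -> 1 t18_0",                        -397.4),
    rx("CSI",     "CSI",   "LOH2",      "1 d18_0 + 1 c16_coa -> 1 cer_d18_0_c16",    -25.5),
    rx("CSII_t",  "CSII",  "LOH1,LOH3", "1 t18_0 + 1 c24_coa -> 1 cer_t18_0_c24",    -27.6),
    rx("CSII_d",  "CSII",  "LOH1,LOH3", "1 d18_0 + 1 c24_coa -> 1 cer_d18_0_c24",    -27.6),
    rx("SLD_c16", "SLD",   "SLD1,SLD2", "1 cer_d18_0_c16 -> 1 cer_d18_1_c16",        sld_delta_g0),
    rx("SLD_c24", "SLD",   "SLD1,SLD2", "1 cer_d18_0_c24 -> 1 cer_d18_1_c24",        sld_delta_g0),
    rx("FAH_c16", "FAH",   "FAH1,FAH2", "1 cer_d18_1_c16 -> 1 cer_d18_1_hc16",       -93.0),
    rx("FAH_c24", "FAH",   "FAH1,FAH2", "1 cer_d18_1_c24 -> 1 cer_d18_1_hc24",       -93.0),
    rx("FAH_t24", "FAH",   "FAH1,FAH2", "1 cer_t18_0_c24 -> 1 cer_t18_0_hc24",       -93.0),
    rx("GCS_c16", "GCS",   "GCS",       "1 cer_d18_1_hc16 + 1 udp_glucose -> 1 glccer_hc16", -4.5),
    rx("GCS_c24", "GCS",   "GCS",       "1 cer_d18_1_hc24 + 1 udp_glucose -> 1 glccer_hc24", -4.5),
    rx("GIPCS",   "GIPCS", "IPCS1",     "1 cer_t18_0_hc24 + 1 inositol_p -> 1 gipc_hc24",    -5.1),
    rx("EX_serine",   "exchange", "", "-> 1 serine",      NA),
    rx("EX_c16_coa",  "exchange", "", "-> 1 c16_coa",     NA),
    rx("EX_c24_coa",  "exchange", "", "-> 1 c24_coa",     NA),
    rx("EX_nadph",    "exchange", "", "-> 1 nadph",       NA),
    rx("EX_udpg",     "exchange", "", "-> 1 udp_glucose", NA),
    rx("EX_inositol", "exchange", "", "-> 1 inositol_p",  NA)
  )
  build_network(tab, .FIXTURE_METS())
}

#' Synthetic stand-in for the full supplementary reaction network
#'
#' A deterministic 77-reaction / 24-gene network emulating the scale and
#' promiscuity structure of the full pathway knowledgebase (LCB
#' modifications, two ceramide synthase classes over C16/C24 pools,
#' desaturation, hydroxylation, glycosylation, phosphorylation/ceramidase
#' turnover). It is a synthetic reconstruction for parser- and scale-level
#' tests, not a curated model.
#'
#' @return `sphingo_network` with 77 enzymatic reactions and 24 genes
#' @export
synthetic_s1_network <- function() {
  rows <- list()
  add <- function(id, enzyme, genes, eq, dg) {
    rows[[length(rows) + 1L]] <<- data.frame(
      rxn_id = id, enzyme = enzyme, genes = genes, equation = eq,
      delta_g0_kJ_mol = dg, lb = 0, ub = Inf, stringsAsFactors = FALSE)
  }
  lcb <- c("d18_0", "d18_1", "t18_0", "t18_1")
  acyl <- c("c16", "c24")
  add("SPT", "SPT", "LCB1,LCB2,SSSPT", "1 serine + 1 c16_coa -> 1 ketosphinganine", 8.9)
  add("KSR", "KSR", "TSC10A,TSC10B", "1 ketosphinganine + 1 nadph -> 1 d18_0", -17.1)
  add("SBH_free_0", "SBH", "SBH1,SBH2", "1 d18_0 -> 1 t18_0", -397.4)
  add("SBH_free_1", "SBH", "SBH1,SBH2", "1 d18_1 -> 1 t18_1", -397.4)
  add("SLD_free_d", "SLD", "SLD1,SLD2", "1 d18_0 -> 1 d18_1", -50)
  add("SLD_free_t", "SLD", "SLD1,SLD2", "1 t18_0 -> 1 t18_1", -50)
  for (l in c("d18_0", "d18_1")) {
    add(paste0("CSI_", l), "CSI", "LOH2",
        paste0("1 ", l, " + 1 c16_coa -> 1 cer_", l, "_c16"), -25.5)
  }
  for (l in lcb) {
    add(paste0("CSII_", l), "CSII", "LOH1,LOH3",
        paste0("1 ", l, " + 1 c24_coa -> 1 cer_", l, "_c24"), -27.6)
  }
  for (b in c("d", "t")) for (a in acyl) for (h in c("", "h")) {
    add(paste0("SLD_cer_", b, "_", h, a), "SLD", "SLD1,SLD2",
        paste0("1 cer_", b, "18_0_", h, a, " -> 1 cer_", b, "18_1_", h, a), -50)
  }
  for (u in c("0", "1")) for (a in acyl) for (h in c("", "h")) {
    add(paste0("SBH_cer_", u, "_", h, a), "SBH", "SBH1,SBH2",
        paste0("1 cer_d18_", u, "_", h, a, " -> 1 cer_t18_", u, "_", h, a), -397.4)
  }
  for (l in lcb) for (a in acyl) {
    add(paste0("FAH_", l, "_", a), "FAH", "FAH1,FAH2",
        paste0("1 cer_", l, "_", a, " -> 1 cer_", l, "_h", a), -93.0)
  }
  for (l in lcb) for (a in acyl) {
    add(paste0("GCS_", l, "_", a), "GCS", "GCS",
        paste0("1 cer_", l, "_h", a, " + 1 udp_glucose -> 1 glccer_", l, "_h", a), -4.5)
    add(paste0("GIPCS_", l, "_", a), "GIPCS", "IPCS1,IPCS2,IPCS3,GMT1",
        paste0("1 cer_", l, "_h", a, " + 1 inositol_p -> 1 gipc_", l, "_h", a), -5.1)
  }
  add("GMT_series", "GIPCS", "GINT1", "1 gipc_t18_1_hc24 + 1 udp_glucose -> 1 gipc_series_a", -5.0)
  for (l in lcb) {
    add(paste0("LCBK_", l), "LCBK", "LCBK1,LCBK2",
        paste0("1 ", l, " + 1 atp -> 1 ", l, "_p"), -20)
    add(paste0("SPP_", l), "SPP", "SPP1",
        paste0("1 ", l, "_p -> 1 ", l), -10)
  }
  for (l in lcb) for (a in acyl) for (h in c("", "h")) {
    add(paste0("ACD_", l, "_", h, a), "ACD", "ACD5",
        paste0("1 cer_", l, "_", h, a, " -> 1 ", l, " + 1 fa_", h, a), -15)
  }
  tab <- do.call(rbind, rows)
  mets <- data.frame(
    id = c("serine", "c16_coa", "c24_coa", "nadph", "udp_glucose", "inositol_p",
           "atp", "fa_c16", "fa_c24", "fa_hc16", "fa_hc24", "orm"),
    name = NA_character_,
    species_class = c("cofactor", "acyl-CoA", "acyl-CoA", "cofactor", "cofactor",
                      "cofactor", "cofactor", "boundary", "boundary", "boundary",
                      "boundary", "regulator"),
    acyl_length = NA_integer_, hydroxylation = NA_character_,
    is_buffered = c(rep(TRUE, 7), rep(TRUE, 4), FALSE),
    stringsAsFactors = FALSE
  )
  build_network(tab, mets)
}

#' Synthetic reconstruction of the 23 candidate regulatory schemes
#'
#' The curated scheme list is not printed in the main text; this
#' reconstruction enumerates the stated candidate space: every combination of
#' ORM->CSI (activation/inhibition), ORM->CSII (activation/inhibition) and
#' ceramide inhibition of SPT (18 schemes, including the baseline ORM -| SPT
#' alone), two schemes with direct ceramide inhibition of a ceramide synthase
#' class, and three schemes adding ceramide repression of ORMs on top of the
#' ORM-mediated CSII activation hypothesis. Every scheme carries the baseline
#' ORM -| SPT edge.
#'
#' @return list of 23 `sphingo_scheme`
#' @export
synthetic_s3_schemes <- function() {
  core <- enumerate_schemes(data.frame(
    regulator = c("orm", "orm", "orm", "orm", "ceramide"),
    target = c("CSI", "CSI", "CSII", "CSII", "SPT"),
    mode = c("activation", "inhibition", "activation", "inhibition", "inhibition"),
    stringsAsFactors = FALSE
  ))
  stopifnot(length(core) == 18L)
  extra <- list(
    new_scheme(data.frame(regulator = "ceramide", target = "CSI", mode = "inhibition"),
               scheme_id = "scheme19"),
    new_scheme(data.frame(regulator = "ceramide", target = "CSII", mode = "inhibition"),
               scheme_id = "scheme20"),
    new_scheme(data.frame(regulator = c("ceramide", "orm"),
                          target = c("orm", "CSII"),
                          mode = c("inhibition", "activation")),
               scheme_id = "scheme21"),
    new_scheme(data.frame(regulator = c("ceramide", "orm", "orm"),
                          target = c("orm", "CSII", "CSI"),
                          mode = c("inhibition", "activation", "inhibition")),
               scheme_id = "scheme22"),
    new_scheme(data.frame(regulator = c("ceramide", "orm", "ceramide"),
                          target = c("orm", "CSII", "SPT"),
                          mode = c("inhibition", "activation", "inhibition")),
               scheme_id = "scheme23")
  )
  c(core, extra)
}

#' Write scheme list to the scheme TSV dialect
#'
#' @param schemes list of `sphingo_scheme`
#' @param path output path
#' @export
write_schemes_tsv <- function(schemes, path) {
  tab <- do.call(rbind, lapply(schemes, function(s) {
    cbind(scheme_id = s$scheme_id, s$edges)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Emit a full set of synthetic study inputs
#'
#' Writes the growth CSV, composition CSV, network TSV (+ metabolite TSV),
#' perturbation/filter TSV and scheme TSV into a directory.
#'
#' @param dir output directory (created if missing)
#' @param config generator configuration
#' @return invisibly, the vector of written paths
#' @export
simulate_study_data <- function(dir, config = generator_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    growth = file.path(dir, "growth.csv"),
    composition = file.path(dir, "composition.csv"),
    network = file.path(dir, "network.tsv"),
    metabolites = file.path(dir, "metabolites.tsv"),
    filters = file.path(dir, "filters.tsv"),
    schemes = file.path(dir, "schemes.tsv")
  )
  utils::write.csv(generate_growth_series(config), paths["growth"], row.names = FALSE)
  utils::write.csv(generate_composition(config), paths["composition"], row.names = FALSE)
  net <- fixture_network()
  write_network_tsv(net, paths["network"], paths["metabolites"])
  utils::write.table(default_filters(), paths["filters"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_schemes_tsv(synthetic_s3_schemes(), paths["schemes"])
  invisible(paths)
}
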