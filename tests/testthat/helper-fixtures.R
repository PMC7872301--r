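# Shared fixtures, built in code. Heavier objects are cached per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

fix_net <- function() cached("net", fixture_network())
fix_ref <- function() cached("ref", reference_from_fractions())

fix_elem_baseline <- function() {
  cached("elem_baseline",
         decompose_to_elementary(fix_ref()$network, new_scheme(NULL)))
}

# small baseline ensemble shared across tests (seeded, deterministic)
fix_ensemble <- function(n = 20L) {
  cached(paste0("ens", n),
         generate_ensemble(fix_ref(), new_scheme(NULL), n_models = n, seed = 101L))
}

# a minimal linear-chain network: a -> b -> biomass, used for LP sanity tests
chain_network <- function() {
  tab <- data.frame(
    rxn_id = c("SPT", "R2", "EX_a", "biomass"),
    enzyme = c("SPT", "E2", "exchange", "biomass"),
    genes = "",
    equation = c("1 met_a -> 1 met_b", "1 met_b -> 1 met_c",
                 "-> 1 met_a", "1 met_c ->"),
    delta_g0_kJ_mol = c(-10, -10, NA, NA),
    lb = c(0, 0, 0, 1), ub = c(Inf, Inf, Inf, 1),
    stringsAsFactors = FALSE
  )
  mets <- data.frame(id = c("met_a", "met_b", "met_c"), name = NA,
                     species_class = "other", acyl_length = NA_integer_,
                     hydroxylation = NA, is_buffered = FALSE,
                     stringsAsFactors = FALSE)
  build_network(tab, mets)
}

# an isolated uni-uni enzyme whose substrate/product are buffered, for
# Michaelis-Menten closed-form comparisons; x[sub] is set per experiment
single_enzyme_elem <- function() {
  cached("single_elem", {
    tab <- data.frame(
      rxn_id = "SPT", enzyme = "SPT", genes = "",
      equation = "1 met_s -> 1 met_p", delta_g0_kJ_mol = -20,
      lb = 0, ub = Inf, stringsAsFactors = FALSE)
    mets <- data.frame(id = c("met_s", "met_p"), name = NA,
                       species_class = "other", acyl_length = NA_integer_,
                       hydroxylation = NA, is_buffered = FALSE,
                       stringsAsFactors = FALSE)
    net <- build_network(tab, mets)
    elem <- decompose_to_elementary(net, new_scheme(NULL, add_baseline = FALSE))
    # clamp substrate and product so steady-state rates can be scanned vs a
    # fixed substrate level (explicit in the chain, fixed in the dynamics)
    elem$species$buffered[match(c("met_s", "met_p"), elem$species$id)] <- TRUE
    elem
  })
}

# build a sphingo_model for the single-enzyme system from 6 elementary
# constants (k1, km1, k2, km2, k3, km3) with enzyme fractions e
single_enzyme_model <- function(k, e = c(1, 1, 1) / 3) {
  elem <- single_enzyme_elem()
  x_ref <- rep(1, nrow(elem$species))
  x_ref[elem$enzyme_states$SPT] <- e
  K <- numeric(nrow(elem$steps))
  rows <- elem$chains[["SPT|basal"]]$rows
  K[rows] <- k
  structure(list(K = K, x_ref = x_ref, alpha = list(), v_ref = NULL),
            class = "sphingo_model")
}

expect_sphingo_error <- function(expr, class) {
  expect_error(expr, class = paste0("sphingoem_", class))
}
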