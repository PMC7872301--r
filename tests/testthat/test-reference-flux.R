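# reference_flux: growth regression, biomass construction, FBA/pFBA.

test_that("growth rate fits are exact on noise-free exponentials", {
  d <- expand.grid(day = c(5, 10, 15, 20), replicate = 1:3)
  d$dry_weight <- 2 * exp(0.2 * d$day)
  fit <- fit_growth_rate(d)
  expect_equal(fit$rate, 0.2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # constant weights -> zero rate
  d$dry_weight <- 3
  expect_equal(fit_growth_rate(d)$rate, 0)
  # rescaling weights leaves the slope unchanged
  d$dry_weight <- 2 * exp(0.2 * d$day)
  f2 <- fit_growth_rate(transform(d, dry_weight = dry_weight * 37.5))
  expect_equal(f2$rate, 0.2, tolerance = 1e-12)
})

test_that("growth fit error paths", {
  expect_sphingo_error(
    fit_growth_rate(data.frame(day = c(1, 2), dry_weight = c(1, -1))), "domain")
  expect_sphingo_error(
    fit_growth_rate(data.frame(day = c(5, 5), dry_weight = c(1, 2))),
    "insufficient_data")
})

test_that("biomass reaction mirrors composition proportions", {
  net <- fix_net()
  bio <- build_biomass_reaction(
    data.frame(species_id = c("glccer_hc16", "gipc_hc24"), mole_fraction = c(0.5, 0.5)),
    rate = 0.1, net = net)
  st <- attr(bio, "stoich")
  expect_equal(unname(st[c("glccer_hc16", "gipc_hc24")]), c(-0.5, -0.5))
  expect_equal(bio$lb, 0.1)
  # single-species composition
  bio1 <- build_biomass_reaction(
    data.frame(species_id = "gipc_hc24", mole_fraction = 1), 0.1, net)
  expect_equal(names(attr(bio1, "stoich")), "gipc_hc24")
  # unknown species list the offending ids
  err <- tryCatch(build_biomass_reaction(
    data.frame(species_id = c("gipc_hc24", "nope1"), mole_fraction = c(0.5, 0.5)),
    0.1, net), condition = function(e) conditionMessage(e))
  expect_match(err, "nope1")
})

test_that("pFBA on a linear chain pushes the growth flux through every step", {
  ref <- solve_pfba(chain_network())
  expect_equal(unname(ref$fluxes[c("SPT", "R2", "EX_a", "biomass")]),
               c(1, 1, 1, 1), tolerance = 1e-9)
  S <- build_stoichiometric_matrix(ref$network)
  expect_lt(max(abs(S %*% ref$fluxes)), 1e-9)
})

test_that("objective tilt zeroes futile cycles without sacrificing growth", {
  # chain plus a reversible futile pair b <-> d
  tab <- data.frame(
    rxn_id = c("SPT", "R2", "CYC1", "CYC2", "EX_a", "biomass"),
    enzyme = c("SPT", "E2", "E3", "E4", "exchange", "biomass"),
    genes = "",
    equation = c("1 a -> 1 b", "1 b -> 1 c", "1 b -> 1 d", "1 d -> 1 b",
                 "-> 1 a", "1 c ->"),
    delta_g0_kJ_mol = c(-1, -1, -1, -1, NA, NA),
    lb = c(0, 0, 0, 0, 0, 1), ub = c(1000, 1000, 1000, 1000, 1000, 1))
  mets <- data.frame(id = c("a", "b", "c", "d"), name = NA, species_class = "other",
                     acyl_length = NA_integer_, hydroxylation = NA, is_buffered = FALSE)
  net <- build_network(tab, mets)
  plain <- solve_fba(net)
  tilted <- solve_pfba(net)
  expect_equal(tilted$v_biomass, plain$v_biomass, tolerance = 1e-6)
  expect_equal(unname(tilted$fluxes[c("CYC1", "CYC2")]), c(0, 0), tolerance = 1e-9)
  # total absolute flux of the tilted optimum is minimal among alternate
  # optima reachable by randomized tilts of the same LP
  S <- build_stoichiometric_matrix(net)
  base <- sum(abs(tilted$fluxes))
  set.seed(42)
  for (i in 1:5) {
    cmin <- stats::rnorm(ncol(S), sd = 1e-6)
    cmin[net$reactions$id == "biomass"] <- -1
    alt <- flux_lp(S, net$reactions$lb, net$reactions$ub, cmin)
    expect_gte(sum(abs(alt$v)) + 1e-9, base)
  }
})

test_that("simplex agrees with an independent LP oracle", {
  # random bounded feasible LPs, checked against scipy.optimize.linprog when
  # available (same conda env ships both interpreters)
  set.seed(7)
  m <- 4; n <- 7
  A <- matrix(round(stats::rnorm(m * n), 2), m)
  x0 <- round(stats::runif(n), 2)           # feasible point
  b <- as.numeric(A %*% x0)
  cvec <- round(stats::rnorm(n), 2)
  sol <- simplex_solve(A, b, cvec)
  expect_equal(sol$status, "optimal")
  expect_lt(max(abs(A %*% sol$x - b)), 1e-8)
  py <- Sys.which("python")
  expect_true(nzchar(py))  # ships in the same environment as R
  script <- sprintf(
    "import json,sys;from scipy.optimize import linprog;import numpy as np\nA=np.array(json.loads(sys.argv[1]));b=np.array(json.loads(sys.argv[2]));c=np.array(json.loads(sys.argv[3]))\nr=linprog(c,A_eq=A,b_eq=b,bounds=[(0,None)]*len(c),method='highs')\nprint(json.dumps({'fun':r.fun,'status':int(r.status)}))")
  out <- system2(py, c("-c", shQuote(script),
                       shQuote(jsonlite::toJSON(A, digits = NA)),
                       shQuote(jsonlite::toJSON(b, digits = NA)),
                       shQuote(jsonlite::toJSON(cvec, digits = NA))),
                 stdout = TRUE)
  orc <- jsonlite::fromJSON(out[length(out)])
  expect_equal(orc$status, 0L)
  expect_equal(sol$value, orc$fun, tolerance = 1e-7)
})

test_that("branching fractions round-trip through composition and pFBA", {
  ref <- fix_ref()
  v <- ref$fluxes_spt
  expect_equal(unname(v[["CSII_t"]] + v[["CSII_d"]]), 0.73, tolerance = 1e-12)
  expect_equal(unname(v[["CSI"]]), 0.27, tolerance = 1e-12)
  expect_equal(unname(v[["GCS_c16"]] / (v[["GCS_c16"]] + v[["GCS_c24"]])), 0.30,
               tolerance = 1e-12)
  S <- build_stoichiometric_matrix(ref$network)
  expect_lt(max(abs(S %*% ref$fluxes)), 1e-9)
  # pFBA reproduces the fraction-implied fluxes on the same composition
  net <- fix_net()
  comp <- generate_composition(generator_config(composition_noise_sigma = 0))
  bio <- build_biomass_reaction(comp, 0.2, net)
  ref2 <- solve_pfba(net, biomass = bio)
  expect_equal(ref2$fluxes_spt[names(v)], v, tolerance = 1e-8)
})

test_that("reference_from_fractions validates share ranges and edge cases", {
  expect_sphingo_error(reference_from_fractions(list(csii_share = 1.2)), "validation")
  # all flux through CSII: CSI = 0 (needs compatible downstream shares)
  ref <- reference_from_fractions(list(csii_share = 1, gcs_c16_share = 0))
  expect_equal(unname(ref$fluxes_spt[["CSI"]]), 0)
  expect_true("CSI" %in% ref$excluded)
  # infeasible demand: CSI cannot supply the C16 glycosylation demand
  expect_sphingo_error(
    reference_from_fractions(list(csii_share = 0.95, gcs_c16_share = 0.5)),
    "generation")
})
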