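# ensemble_generation: thermodynamic bounds, reversibility sampling,
# elementary rates, enzyme fractions, rate-constant anchoring.

test_that("Gibbs energies convert to dimensionless bounds", {
  b <- gibbs_to_bounds(8.9, c(1, 1))
  expect_equal(b$dgrt, 3.590, tolerance = 1e-3)
  # dG'0 = 0 with unit ratio pins both bounds at 0 before the feasibility clip
  b0 <- gibbs_to_bounds(0, c(1, 1), clip = 0)
  expect_equal(c(b0$lb, b0$ub), c(0, 0))
  bk <- gibbs_to_bounds(-17.1, c(1, 1))
  expect_equal(bk$dgrt, -6.898, tolerance = 1e-3)
  expect_true(bk$feasible)        # forward-feasible at q = 1
  expect_lt(bk$ub, 0)
  # domain errors
  expect_sphingo_error(gibbs_to_bounds(1, c(-1, 1)), "domain")
  expect_sphingo_error(gibbs_to_bounds(1, c(2, 1)), "domain")
  # strongly positive dG'0 with a tight ratio range is infeasible forward
  expect_false(gibbs_to_bounds(30, c(1, 1))$feasible)
})

test_that("reversibility sampling respects point and interval constraints", {
  b_point <- list(lb = -5, ub = -5, feasible = TRUE)
  set.seed(1)
  R <- sample_reversibilities(1L, b_point)
  expect_equal(log(R), -5, tolerance = 1e-12)
  # interval: 10k draws of 3-step chains land uniformly in the interval
  b <- list(lb = -10, ub = -1, feasible = TRUE)
  set.seed(2)
  sums <- replicate(10000, sum(log(sample_reversibilities(3L, b))))
  expect_true(all(sums >= -10 - 1e-9 & sums <= -1 + 1e-9))
  ks <- suppressWarnings(stats::ks.test(sums, "punif", -10, -1))
  expect_gt(ks$p.value, 0.01)
  # infeasible bounds error names the reaction
  expect_sphingo_error(
    sample_reversibilities(3L, list(lb = 1, ub = -1, feasible = FALSE), rxn_id = "SPT"),
    "thermo")
})

test_that("elementary rates solve the net-flux/reversibility relations", {
  r <- elementary_rates_from_R(1, 0.5)
  expect_equal(c(r$v_fwd, r$v_rev), c(2, 1))
  r2 <- elementary_rates_from_R(2, 0.9)
  expect_equal(c(r2$v_fwd, r2$v_rev), c(20, 18), tolerance = 1e-12)
  r0 <- elementary_rates_from_R(1, 0)
  expect_equal(c(r0$v_fwd, r0$v_rev), c(1, 0))
  # mirrored for reverse net flux
  rn <- elementary_rates_from_R(-1, 0.5)
  expect_equal(c(rn$v_fwd, rn$v_rev), c(1, 2))
  expect_sphingo_error(elementary_rates_from_R(1, 1), "thermo")
  # R = 1 is admissible only for zero net flux
  rz <- elementary_rates_from_R(0, c(1, 1))
  expect_equal(rz$v_fwd, c(0, 0))
})

test_that("enzyme fractions are a floored uniform simplex sample", {
  expect_sphingo_error(sample_enzyme_fractions(1L), "domain")
  set.seed(3)
  f <- sample_enzyme_fractions(2L)
  expect_equal(sum(f), 1)
  expect_true(all(f > 0))
  draws <- replicate(10000, sample_enzyme_fractions(3L))
  expect_true(all(draws >= 1e-9))
  expect_equal(unname(rowMeans(draws)), rep(1 / 3, 3), tolerance = 0.01)
})

test_that("rate constants anchor the chain to its reference rates", {
  # K = v / (occupancy * activities): direct division example
  elem <- single_enzyme_elem()
  m <- single_enzyme_model(k = rep(1, 6), e = c(0.5, 0.25, 0.25))
  rows <- elem$chains[["SPT|basal"]]$rows
  v <- c(2, 1, 1, 0.5, 1, 0.5)
  K <- compute_rate_constants(v, rows, elem, m$x_ref)
  expect_equal(K[1], 2 / 0.5)   # binding consumes the free enzyme state
  expect_equal(K[2], 1 / 0.25)
  # round-trip: a freshly sampled fixture model reproduces its reference
  # elementary rates exactly when evaluated at the reference state
  ens <- fix_ensemble()
  m2 <- ens$models[[2]]
  sys <- assemble_rhs(m2, ens$elem)
  v_eval <- sys$rates(m2$x_ref)
  expect_equal(v_eval, m2$v_ref, tolerance = 1e-12)
})

test_that("ensemble generation is anchored, thermodynamically consistent, deterministic", {
  ref <- fix_ref()
  ens <- generate_ensemble(ref, new_scheme(NULL), n_models = 10, seed = 99)
  expect_length(ens$models, 10L)
  for (m in ens$models) {
    expect_lt(verify_reference(m, ens$elem)$residual, 1e-9)
    # thermodynamic consistency: per reaction, sum(ln R) within bounds
    for (ch_name in names(ens$elem$chains)) {
      ch <- ens$elem$chains[[ch_name]]
      R <- m$reversibilities[[ch_name]]
      if (is.null(R)) next
      dg <- ref$network$reactions$delta_g0[ref$network$reactions$id == ch$rxn_id]
      b <- gibbs_to_bounds(dg)
      expect_true(sum(log(R)) >= b$lb - 1e-9 && sum(log(R)) <= b$ub + 1e-9)
    }
  }
  # Haldane-type consistency: product of K ratios equals exp(sum ln R)
  m <- ens$models[[1]]
  for (ch_name in names(ens$elem$chains)) {
    ch <- ens$elem$chains[[ch_name]]
    K <- m$K[ch$rows]
    lnKeq <- sum(log(K[c(1, 3, 5)])) - sum(log(K[c(2, 4, 6)]))
    expect_equal(lnKeq, -sum(log(m$reversibilities[[ch_name]])), tolerance = 1e-9)
  }
  # seed determinism: bitwise-identical parameter sets
  ens2 <- generate_ensemble(ref, new_scheme(NULL), n_models = 10, seed = 99)
  expect_identical(lapply(ens$models, `[[`, "K"), lapply(ens2$models, `[[`, "K"))
  # empty ensemble is not an error
  expect_length(generate_ensemble(ref, new_scheme(NULL), n_models = 0)$models, 0L)
})

test_that("zero-flux reactions are rejected unless excluded", {
  ref <- reference_from_fractions(list(csii_share = 1, gcs_c16_share = 0))
  sch <- new_scheme(NULL)
  expect_sphingo_error(generate_ensemble(ref, sch, n_models = 1, seed = 1), "config")
  ens <- generate_ensemble(ref, sch, n_models = 2, seed = 1, zero_flux = "exclude")
  expect_length(ens$models, 2L)
  expect_lt(verify_reference(ens$models[[1]], ens$elem)$residual, 1e-9)
})

test_that("activation splits the reference flux across both branches", {
  ref <- fix_ref()
  sch <- new_scheme(data.frame(regulator = "orm", target = "CSII", mode = "activation"), "act")
  ens <- generate_ensemble(ref, sch, n_models = 3, seed = 5)
  for (m in ens$models) {
    a <- m$alpha$CSII
    expect_true(a >= 0.5 && a <= 1)
    # basal + activated release nets sum to the reaction reference flux
    for (rid in c("CSII_t", "CSII_d")) {
      vb <- m$v_ref[ens$elem$chains[[paste0(rid, "|basal")]]$rows]
      va <- m$v_ref[ens$elem$chains[[paste0(rid, "|activated")]]$rows]
      expect_equal((vb[5] - vb[6]) + (va[5] - va[6]),
                   unname(ref$fluxes_spt[[rid]]), tolerance = 1e-12)
    }
    expect_lt(verify_reference(m, ens$elem)$residual, 1e-9)
  }
})
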