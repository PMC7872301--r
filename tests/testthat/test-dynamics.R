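# dynamics: RHS assembly, Jacobian, steady-state detection, perturbations.

test_that("RHS vanishes at the reference state and scales with mass action", {
  ens <- fix_ensemble()
  m <- ens$models[[1]]
  sys <- assemble_rhs(m, ens$elem)
  expect_lt(max(abs(sys$rhs(m$x_ref))), 1e-9)
  # doubling the free enzyme of an isolated binding step doubles its rate
  elem <- single_enzyme_elem()
  ms <- single_enzyme_model(k = c(2, 1, 3, 1, 4, 0.5))
  sys1 <- assemble_rhs(ms, elem)
  rows <- elem$chains[["SPT|basal"]]$rows
  x <- ms$x_ref
  v1 <- sys1$rates(x)[rows[1]]
  x2 <- x; x2[elem$enzyme_states$SPT[1]] <- 2 * x2[elem$enzyme_states$SPT[1]]
  expect_equal(sys1$rates(x2)[rows[1]], 2 * v1)
})

test_that("analytic Jacobian matches finite differences", {
  ens <- fix_ensemble()
  m <- ens$models[[3]]
  sys <- assemble_rhs(m, ens$elem)
  set.seed(4)
  x <- m$x_ref * exp(stats::rnorm(length(m$x_ref), 0, 0.1))
  J <- sys$jac(x)
  h <- 1e-7
  for (j in sample(seq_along(x), 12)) {
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    fd <- (sys$rhs(xp) - sys$rhs(xm)) / (2 * h)
    expect_equal(J[, j], fd, tolerance = 1e-5)
  }
})

test_that("steady-state simulation is anchored and identity-stable", {
  ens <- fix_ensemble()
  m <- ens$models[[4]]
  sys <- assemble_rhs(m, ens$elem)
  # no perturbation: stays at reference
  ss <- simulate_to_steady_state(sys)
  expect_true(ss$converged)
  expect_lt(max(abs(ss$x - m$x_ref)), 1e-6)
  expect_equal(ss$fluxes[names(ens$ref$fluxes_spt)[1:14]],
               ens$ref$fluxes_spt[1:14], tolerance = 1e-6)
  # fold = 1 perturbation is the identity
  x0 <- apply_perturbation(ens$elem, m$x_ref, "CSI", 1)
  expect_identical(x0, m$x_ref)
  # steady-state flux consistency: S v = 0 on balance rows at convergence
  ss2 <- simulate_to_steady_state(sys, x0 = apply_perturbation(ens$elem, m$x_ref, "orm", 2))
  expect_true(ss2$converged)
  S <- build_stoichiometric_matrix(ens$ref$network)
  enz <- intersect(colnames(S), names(ss2$fluxes))
  sink_flux <- vapply(rownames(S), function(sp) {
    i <- match(sp, ens$elem$species$id)
    s <- ens$elem$sinks[[ens$elem$species$id[i]]]
    if (is.null(s)) 0 else m$K[s$row] * ss2$x[i]
  }, numeric(1))
  resid <- S[, enz] %*% ss2$fluxes[enz] - sink_flux
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("verify_reference flags broken anchoring", {
  ens <- fix_ensemble()
  m <- ens$models[[5]]
  expect_true(verify_reference(m, ens$elem, integrate = TRUE)$ok)
  m_bad <- m
  m_bad$K[which(m_bad$K > 0)[1]] <- 2 * m_bad$K[which(m_bad$K > 0)[1]]
  expect_false(verify_reference(m_bad, ens$elem)$ok)
})

test_that("uni-uni steady-state rates follow the Michaelis-Menten closed form", {
  elem <- single_enzyme_elem()
  set.seed(8)
  for (rep in 1:5) {
    k <- stats::runif(6, 0.2, 5)
    k[6] <- 0  # vanishing product rebinding: exact MM regime
    m <- single_enzyme_model(k)
    sys <- assemble_rhs(m, elem)
    lp <- lump_chain_constants(k)
    i_s <- match("met_s", elem$species$id)
    i_p <- match("met_p", elem$species$id)
    for (X in c(0.01, 0.1, 1, 10, 100)) {
      x0 <- m$x_ref
      x0[i_s] <- X
      x0[i_p] <- 0
      ss <- simulate_to_steady_state(sys, x0 = x0, tol_ss = 1e-12)
      vmm <- lp$kcat_plus * X / (lp$K_s + X)
      v <- unname(ss$fluxes["SPT"])
      expect_equal(v, vmm, tolerance = 1e-6)
    }
  }
})

test_that("pure-sequestration inhibition is monotone in inhibitor total", {
  ref <- fix_ref()
  ens <- generate_ensemble(ref, new_scheme(NULL), n_models = 3, seed = 31)
  for (m in ens$models) {
    sys <- assemble_rhs(m, ens$elem)
    folds <- c(0.2, 0.5, 1, 2, 5)
    spt_flux <- vapply(folds, function(f) {
      ss <- simulate_to_steady_state(sys, x0 = apply_perturbation(ens$elem, m$x_ref, "orm", f))
      expect_true(ss$converged)
      unname(ss$enzyme_flux["SPT"])
    }, numeric(1))
    expect_true(all(diff(spt_flux) <= 1e-6))
  }
})

test_that("states remain nonnegative along perturbed trajectories", {
  ens <- fix_ensemble()
  m <- ens$models[[2]]
  sys <- assemble_rhs(m, ens$elem)
  ss <- simulate_to_steady_state(sys, x0 = apply_perturbation(ens$elem, m$x_ref, "orm", 0.2),
                                 record = TRUE)
  expect_true(ss$converged)
  mins <- vapply(ss$trajectory, function(p) min(p$x), numeric(1))
  expect_gte(min(mins), -1e-9)
})
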