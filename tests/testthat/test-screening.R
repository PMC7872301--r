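# screening: filter evaluation, order invariance, scheme ranking mechanics.

mock_state <- function(x, enzyme_flux = c(CSI = 1, CSII = 1)) {
  list(x = x, enzyme_flux = enzyme_flux)
}

test_that("filter logic: strict relative increase/decrease", {
  elem <- fix_elem_baseline()
  n <- nrow(elem$species)
  xref <- rep(1, n)
  rules <- data.frame(perturbation = "p", observable = "reaction_flux",
                      target = "CSI", direction = "up", epsilon = 0.01)
  ref_state <- mock_state(xref, c(CSI = 1.0, CSII = 1))
  expect_true(evaluate_filters(ref_state, mock_state(xref, c(CSI = 1.5, CSII = 1)),
                               rules, elem))
  # no change is not an increase
  expect_false(evaluate_filters(ref_state, mock_state(xref, c(CSI = 1.0, CSII = 1)),
                                rules, elem))
  # sub-threshold change fails
  expect_false(evaluate_filters(ref_state, mock_state(xref, c(CSI = 1.005, CSII = 1)),
                                rules, elem))
  rules$direction <- "down"
  expect_true(evaluate_filters(ref_state, mock_state(xref, c(CSI = 0.5, CSII = 1)),
                               rules, elem))
  # unresolvable targets raise rule errors
  bad <- rules; bad$target <- "NOPE"
  expect_sphingo_error(evaluate_filters(ref_state, ref_state, bad, elem), "rule")
  badp <- data.frame(perturbation = "p", observable = "pooled_concentration",
                     target = "unknown_pool", direction = "up", epsilon = 0.01)
  expect_sphingo_error(evaluate_filters(ref_state, ref_state, badp, elem), "rule")
})

test_that("pooled observables aggregate free ceramides by acyl length", {
  elem <- fix_elem_baseline()
  n <- nrow(elem$species)
  xref <- rep(1, n)
  xpert <- xref
  c16 <- match(c("cer_d18_0_c16", "cer_d18_1_c16", "cer_d18_1_hc16"), elem$species$id)
  xpert[c16] <- 2
  rules <- data.frame(perturbation = "p", observable = "pooled_concentration",
                      target = c("c16_cer", "c24_cer"), direction = "up",
                      epsilon = 0.05)
  got <- evaluate_filters(mock_state(xref), mock_state(xpert), rules, elem)
  expect_equal(got, c(TRUE, FALSE))
})

test_that("screening is order-invariant and counts non-convergence as failure", {
  ens <- fix_ensemble(10L)
  pert <- default_perturbations(oe_fold = 2)
  scr1 <- screen_ensemble(ens, pert)
  scr2 <- screen_ensemble(ens, pert[c(3, 1, 2), ])
  expect_equal(scr1$pass[, sort(colnames(scr1$pass))],
               scr2$pass[, sort(colnames(scr2$pass))])
  expect_equal(scr1$n_pass, scr2$n_pass)
  # configuration errors
  expect_sphingo_error(
    screen_ensemble(ens, pert, default_filters()[0, ]), "config")
  p_extra <- rbind(pert, data.frame(label = "GCS_OE", target = "GCS", fold = 2))
  expect_sphingo_error(screen_ensemble(ens, p_extra, default_filters()), "config")
})

test_that("direct enzyme scaling raises the scaled enzyme's flux in every model", {
  ens <- fix_ensemble(10L)
  elem <- ens$elem
  for (m in ens$models) {
    sys <- assemble_rhs(m, elem)
    ss <- simulate_to_steady_state(sys, x0 = apply_perturbation(elem, m$x_ref, "CSI", 2))
    expect_true(ss$converged)
    expect_gt(unname(ss$enzyme_flux["CSI"]),
              unname(ens$ref$fluxes_spt[["CSI"]]) * (1 + 1e-3))
  }
})

test_that("scheme screening report is deterministic and carries structure flags", {
  ref <- fix_ref()
  schemes <- synthetic_s3_schemes()[c(1, 21)]
  r1 <- screen_schemes(ref, schemes, n_models = 5, seed = 7)
  r2 <- screen_schemes(ref, schemes, n_models = 5, seed = 7)
  expect_identical(r1$report, r2$report)
  expect_equal(sort(r1$report$scheme_id), c("scheme01", "scheme21"))
  expect_equal(r1$report$has_cer_orm[r1$report$scheme_id == "scheme21"], TRUE)
  expect_equal(r1$report$has_cer_orm[r1$report$scheme_id == "scheme01"], FALSE)
  expect_true(all(r1$report$n_models == 5))
})
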