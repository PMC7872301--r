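# network_model: parsing, validation, stoichiometry, elementarization,
# scheme enumeration.

test_that("fixture network parses with Table-level Gibbs energies attached", {
  net <- fix_net()
  rx <- net$reactions
  expect_equal(rx$delta_g0[rx$id == "SPT"], 8.9)
  expect_equal(rx$delta_g0[rx$id == "KSR"], -17.1)
  expect_equal(rx$delta_g0[rx$id == "SBH"], -397.4)
  expect_equal(rx$delta_g0[rx$id == "GCS_c16"], -4.5)
  expect_equal(rx$delta_g0[rx$id == "GIPCS"], -5.1)
  s <- network_summary(net)
  expect_equal(s$n_enzymatic, 14L)
  # buffered flags: cofactors and the acyl-CoA pools
  mets <- net$metabolites
  expect_true(all(mets$is_buffered[mets$id %in% c("serine", "c16_coa", "c24_coa", "nadph")]))
  expect_false(any(mets$is_buffered[mets$species_class %in% c("LCB", "ceramide")]))
})

test_that("degenerate and malformed inputs raise classed errors", {
  expect_sphingo_error(build_network(fix_net()$reactions[0, ]), "validation")
  tab <- data.frame(rxn_id = "r1", enzyme = "SPT", genes = "", equation = "1 a -> -> 1 b",
                    delta_g0_kJ_mol = 1, lb = 0, ub = 1)
  expect_sphingo_error(build_network(tab), "format")
  tab2 <- data.frame(rxn_id = c("r1", "r1"), enzyme = "SPT", genes = "",
                     equation = "1 a -> 1 b", delta_g0_kJ_mol = 1, lb = 0, ub = 1)
  expect_sphingo_error(build_network(tab2), "validation")
  # enzymatic reaction without a Gibbs energy
  tab3 <- data.frame(rxn_id = "r1", enzyme = "SPT", genes = "",
                     equation = "1 a -> 1 b", delta_g0_kJ_mol = NA, lb = 0, ub = 1)
  expect_sphingo_error(build_network(tab3), "validation")
})

test_that("acyl pooling maps chain lengths below/above 20 carbons to C16/C24", {
  expect_equal(pool_acyl_id(c("cer_d18_1_c18", "cer_d18_1_c22", "fa_hc26", "c14_coa")),
               c("cer_d18_1_c16", "cer_d18_1_c24", "fa_hc24", "c16_coa"))
  # pooling merges duplicate species inside an equation
  tab <- data.frame(rxn_id = "r1", enzyme = "SPT", genes = "",
                    equation = "1 cer_x_c18 + 1 cer_x_c19 -> 1 cer_y_c24",
                    delta_g0_kJ_mol = 1, lb = 0, ub = 1)
  net <- build_network(tab)
  expect_equal(net$stoich$r1[["cer_x_c16"]], -2)
})

test_that("stoichiometric matrix reproduces reactions and trims buffered rows", {
  tab <- data.frame(rxn_id = c("r1", "r2"), enzyme = c("SPT", "E2"), genes = "",
                    equation = c("1 a -> 1 b", "1 b -> 1 c"),
                    delta_g0_kJ_mol = -1, lb = 0, ub = 1)
  mets <- data.frame(id = c("a", "b", "c"), name = NA, species_class = "other",
                     acyl_length = NA_integer_, hydroxylation = NA, is_buffered = FALSE)
  net <- build_network(tab, mets)
  S <- build_stoichiometric_matrix(net, trim = FALSE)
  expect_equal(unname(S[c("a", "b", "c"), ]),
               matrix(c(-1, 1, 0, 0, -1, 1), nrow = 3))
  # per-column audit on the fixture: every enzymatic column reproduces its
  # stoichiometry exactly, including buffered species in the untrimmed matrix
  net <- fix_net()
  S_full <- build_stoichiometric_matrix(net, trim = FALSE)
  for (rid in net$reactions$id) {
    st <- net$stoich[[rid]]
    expect_equal(unname(S_full[names(st), rid]), unname(st))
    expect_equal(sum(S_full[, rid] != 0), length(st))
  }
  # trimmed matrix drops buffered/boundary/regulator rows
  S_trim <- build_stoichiometric_matrix(net, trim = TRUE)
  expect_false(any(rownames(S_trim) %in% c("serine", "c16_coa", "orm")))
  # exchange column has a single nonzero entry (untrimmed)
  expect_equal(sum(S_full[, "EX_serine"] != 0), 1)
})

test_that("TSV round-trip preserves the network", {
  net <- fix_net()
  tmp <- tempfile(fileext = ".tsv"); tmpm <- tempfile(fileext = ".tsv")
  write_network_tsv(net, tmp, tmpm)
  net2 <- load_network(tmp, tmpm)
  expect_equal(net2$reactions, net$reactions)
  expect_equal(net2$stoich, net$stoich)
  expect_equal(net2$metabolites$is_buffered, net$metabolites$is_buffered)
})

test_that("synthetic full-scale network has the expected scale", {
  net <- synthetic_s1_network()
  s <- network_summary(net)
  expect_equal(s$n_enzymatic, 77L)
  expect_equal(s$n_genes, 24L)
})

test_that("uni-uni decomposition yields 3 reversible steps per reaction", {
  elem <- single_enzyme_elem()
  expect_equal(elem$n_metabolic, 6L)
  expect_equal(elem$n_regulatory, 0L)
  # fixture: 14 reactions x 6 elementary reactions, regulatory steps separate
  eb <- fix_elem_baseline()
  expect_equal(eb$n_metabolic, 84L)
  expect_equal(eb$n_regulatory, 2L)  # ORM -| SPT binding, both directions
})

test_that("regulatory steps never alter the metabolic count; decomposition is deterministic", {
  ref <- fix_ref()
  sch <- new_scheme(data.frame(regulator = c("ceramide", "orm"),
                               target = c("orm", "CSII"),
                               mode = c("inhibition", "activation")), "s")
  e1 <- decompose_to_elementary(ref$network, sch)
  expect_equal(e1$n_metabolic, fix_elem_baseline()$n_metabolic)
  # inhibition edge: +2 regulatory rows; activation: +2 binding rows and a
  # full 6-row chain per catalyzed reaction (CSII has 2), + cer-orm binding
  expect_equal(e1$n_regulatory, 2L + 2L + 2L + 12L + 2L)
  e2 <- decompose_to_elementary(ref$network, sch)
  expect_identical(e1$steps, e2$steps)
  expect_identical(e1$species, e2$species)
})

test_that("elementary chains conserve enzyme along trajectories", {
  ens <- fix_ensemble()
  m <- ens$models[[1]]
  sys <- assemble_rhs(m, ens$elem)
  x0 <- apply_perturbation(ens$elem, m$x_ref, "CSI", 3)
  ss <- simulate_to_steady_state(sys, x0 = x0)
  tot0 <- enzyme_totals(ens$elem, x0)
  tot1 <- enzyme_totals(ens$elem, ss$x)
  expect_lt(max(abs(tot1 - tot0)), 1e-9)
})

test_that("scheme enumeration covers the candidate space and dedups", {
  expect_length(enumerate_schemes(NULL), 1L)
  two <- data.frame(regulator = c("orm", "ceramide"), target = c("CSII", "orm"),
                    mode = c("activation", "inhibition"))
  expect_length(enumerate_schemes(two), 4L)
  expect_length(synthetic_s3_schemes(), 23L)
  # contradictory duplicate edge
  expect_sphingo_error(
    new_scheme(data.frame(regulator = c("orm", "orm"), target = c("CSI", "CSI"),
                          mode = c("activation", "inhibition"))),
    "scheme")
  # edge targeting a nonexistent enzyme
  expect_sphingo_error(
    validate_scheme(new_scheme(data.frame(regulator = "orm", target = "NOPE",
                                          mode = "inhibition")), fix_net()),
    "scheme")
})

test_that("scheme TSV round-trips and overrides enumeration", {
  tmp <- tempfile(fileext = ".tsv")
  write_schemes_tsv(synthetic_s3_schemes(), tmp)
  schemes <- enumerate_schemes(candidates = NULL, override = tmp)
  expect_length(schemes, 23L)
  expect_true(all(vapply(schemes, function(s)
    any(s$edges$regulator == "orm" & s$edges$target == "SPT"), logical(1))))
})

test_that("count diagnostic reports discrepancies instead of failing", {
  elem <- decompose_to_elementary(synthetic_s1_network(), new_scheme(NULL))
  d <- elementary_count_diagnostic(elem, 374L)
  expect_equal(d$observed, 77L * 6L)
  expect_equal(d$difference, d$observed - 374L)
  expect_match(d$message, "convention")
})
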