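test_that("proofreading scheme matches the branched mechanism", {
  p <- proofreading_params(k2 = 18.3, k3 = 2.9, K3 = 0.061,
                           k4 = 5.42, k_minus4 = 0.33)
  sch <- build_proofreading_scheme(p, conc_E = 1, conc_D = 0.25)
  expect_length(sch$species, 6)
  expect_length(sch$reactions, 9)
  labels <- vapply(sch$reactions, `[[`, "", "label")
  k <- vapply(sch$reactions, `[[`, 0, "rate_constant")
  # reverse transfer is always derived as k3 / K3
  expect_equal(k[labels == "k-3"], 2.9 / 0.061)
  expect_equal(unname(sch$init[c("E", "D")]), c(1, 0.25))
  expect_equal(sum(sch$init[c("ED_p", "ED_x", "ED_I", "P")]), 0)

  # symmetric transfer identity case
  p2 <- proofreading_params(k2 = 1, k3 = 10, K3 = 1)
  sch2 <- build_proofreading_scheme(p2, 1, 0.25)
  k2v <- vapply(sch2$reactions, `[[`, 0, "rate_constant")
  l2 <- vapply(sch2$reactions, `[[`, "", "label")
  expect_equal(k2v[l2 == "k-3"], 10)
})

test_that("inhibited-state branch is absent, not zero, when not modelled", {
  p <- fixture("excision_20C", "4")
  expect_false(p$ed_i_present)
  expect_null(p$k4)
  sch <- build_proofreading_scheme(p, 1, 0.25)
  expect_false("ED_I" %in% sch$species)
  expect_length(sch$reactions, 7)
})

test_that("parameter validation catches bad inputs", {
  expect_error(proofreading_params(k2 = 1, k3 = 2, K3 = 0), "K3")
  expect_error(proofreading_params(k2 = 1, k3 = 2, K3 = NA), "K3")
  expect_error(proofreading_params(k2 = -1, k3 = 0, K3 = 1), "invalid")
  expect_error(proofreading_params(k2 = 1, k3 = 1, K3 = 1, k_minus4 = 2),
               "k_minus4")
  p <- proofreading_params(k2 = 1, k3 = 1, K3 = 1)
  expect_error(build_proofreading_scheme(p, -1, 0.25), "> 0")
  expect_error(build_proofreading_scheme(p, 1, 0), "> 0")
  expect_error(kin_reaction("A", "B", -3, "k"), ">= 0")
})

test_that("extension scheme encodes the fraction primed", {
  p <- extension_params(k1_prime = 0.82, k_minus1_prime = 1.46, k_pol = 13.2)
  expect_equal(p$fraction_primed, 0.82 / 2.28)
  expect_equal(round(p$fraction_primed, 2), 0.36)
  sch <- build_extension_scheme(p)
  expect_identical(sch$preequilibrate, "k_pol")
  expect_equal(unname(sch$init["ED"]), 0.075)

  p10 <- extension_params(k1_prime = 1.5, k_minus1_prime = 0.04, k_pol = 400)
  expect_equal(p10$fraction_primed, 1.5 / 1.54, tolerance = 1e-12)
  expect_gt(p10$fraction_primed, 0.97)

  # k_pol = 0: no product at any time
  sch0 <- build_extension_scheme(extension_params(1, 1, 0))
  tr <- integrate_scheme(sch0, times = c(1, 100))
  expect_equal(max(tr$conc["P_ext", ]), 0)
})

test_that("stoichiometry audit rejects pool-imbalanced reactions", {
  sp <- list(kin_species("E", "free-enzyme"), kin_species("D", "free-DNA"),
             kin_species("ED", "complex"))
  # DNA appears from nothing
  expect_error(kinetic_scheme(sp, list(kin_reaction("E", "ED", 1, "bad")),
                              c(E = 1)), "conserve")
  # undeclared species
  expect_error(kinetic_scheme(sp, list(kin_reaction(c("E", "D"), "EDX", 1, "k")),
                              c(E = 1)), "undeclared")
  # valid scheme passes
  expect_true(audit_stoichiometry(scheme_n0()))
})

test_that("scheme building is deterministic and JSON round trip is lossless", {
  a <- scheme_n0()
  b <- scheme_n0()
  expect_identical(a, b)
  js <- scheme_to_json(a)
  c1 <- scheme_from_json(js)
  expect_identical(a$species, c1$species)
  expect_identical(a$roles, c1$roles)
  expect_identical(a$init, c1$init)
  # numeric payloads survive to within one ulp of decimal serialization
  expect_equal(lapply(a$reactions, unclass), lapply(c1$reactions, unclass),
               tolerance = 1e-15)
  # via file too
  f <- tempfile(fileext = ".json")
  scheme_to_json(a, f)
  expect_identical(scheme_from_json(f)$init, a$init)
})

test_that("fate scheme resolves extension rates and absorbing states", {
  ext0 <- mismatch_extension_kinetics(kcat = 0.025, Km = 87)
  ext1 <- mismatch_extension_kinetics(kcat_over_Km_limit = 0.1)
  sch <- build_fate_scheme(fixture("excision_buried", "n-0"),
                           fixture("excision_buried", "n-1"), ext0, ext1)
  k <- vapply(sch$reactions, `[[`, 0, "rate_constant")
  l <- vapply(sch$reactions, `[[`, "", "label")
  expect_equal(k[l == "k_ext_n0"], 0.025)         # saturating -> kcat
  expect_equal(k[l == "k_ext_n1"], 0.1 * 1000 * 1e-6)  # limit * [dNTP]
  expect_setequal(names(sch$roles)[sch$roles == "absorbing-product"],
                  c("excised_n0", "excised_n1", "buried"))
  # saturating rate undefined for a limit
  expect_error(extension_rate(ext1, "saturating"), "limit")
  # Michaelis-Menten resolution at finite dNTP
  expect_equal(as.numeric(extension_rate(ext0, 87)), 0.0125)
})

test_that("mismatch extension kinetics demands exactly one form", {
  expect_error(mismatch_extension_kinetics(), "exactly one")
  expect_error(mismatch_extension_kinetics(kcat = 1, Km = 2,
                                           kcat_over_Km_limit = 3),
               "exactly one")
  expect_error(mismatch_extension_kinetics(kcat = 1), "Km")
})
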