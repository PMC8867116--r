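test_that("pol-site occupancy follows 100/(1+K3)", {
  expect_equal(round(pol_site_occupancy(0.061)), 94)
  expect_equal(pol_site_occupancy(1), 50)
  expect_equal(round(pol_site_occupancy(0.033)), 97)
  # complement identity holds exactly
  for (K in c(0.0087, 0.061, 0.5, 1.4))
    expect_equal(pol_site_occupancy(K) + 100 * K / (1 + K), 100)
  expect_error(pol_site_occupancy(0))
})

test_that("reverse transfer rate is k3/K3", {
  expect_equal(round(reverse_transfer_rate(2.9, 0.061)), 48)
  expect_equal(reverse_transfer_rate(1, 1), 1)
  expect_equal(reverse_transfer_rate(0.28, 0.033), 8.48, tolerance = 1e-2)
})

test_that("fold change of the transfer equilibrium constant", {
  expect_equal(fold_change(0.061, 0.0087), 7.0, tolerance = 0.01)
  expect_equal(fold_change(0.3, 0.3), 1)
  expect_equal(fold_change(1.003, 0.0087), 115, tolerance = 0.01)
})

test_that("van't Hoff analysis reproduces the known free energy", {
  th <- vant_hoff(0.033, celsius_to_kelvin(4), 0.061, celsius_to_kelvin(20))
  expect_equal(th$delta_G_kJ, -8.314 * 293.15 * log(0.061) / 1000)
  expect_equal(th$delta_G_kJ, 6.8, tolerance = 0.01)
  # dH from the rounded printed constants (25.9 kJ/mol by the closed form)
  expect_equal(th$delta_H_kJ, 25.9, tolerance = 0.01)
  # equal K at both temperatures -> dH = 0
  expect_equal(vant_hoff(0.5, 277.15, 0.5, 293.15)$delta_H_kJ, 0)
  # swapping the pairs leaves dH unchanged (antisymmetric relation)
  th2 <- vant_hoff(0.061, celsius_to_kelvin(20), 0.033, celsius_to_kelvin(4))
  expect_equal(th2$delta_H_kJ, th$delta_H_kJ)
  expect_error(vant_hoff(0.1, 293.15, 0.2, 293.15))
})

test_that("mismatch fate agrees between ODE and jump-chain routes", {
  ext0 <- mismatch_extension_kinetics(kcat = 0.025, Km = 87)
  ext1 <- mismatch_extension_kinetics(kcat_over_Km_limit = 0.1)
  sch <- build_fate_scheme(fixture("excision_buried", "n-0"),
                           fixture("excision_buried", "n-1"), ext0, ext1)
  rep <- mismatch_fate(sch)
  expect_equal(rep$fraction_excised + rep$fraction_extended_once +
                 rep$fraction_buried, 100, tolerance = 1e-6)
  expect_lt(max(abs(rep$routes$ode - rep$routes$jump_chain)), 1e-4)
  # closed-form oracle for the first-stage extension probability
  p0 <- fix_n0()
  p_ext <- stage_extend_prob(p0$k3, p0$k3 / p0$K3, 1000, 0.025)
  expect_equal(rep$fraction_extended_once + rep$fraction_buried,
               100 * p_ext, tolerance = 1e-4)
  expect_equal(round(rep$fraction_excised, 1), 99.1)
  expect_true(rep$buried_is_upper_limit)
})

test_that("zero extension rates give 100% excision", {
  ext0 <- mismatch_extension_kinetics(kcat = 0, Km = 87)
  sch <- build_fate_scheme(fix_n0(), fixture("excision_buried", "n-1"),
                           ext0, ext0, dntp_n0 = 500, dntp_n1 = 500)
  rep <- mismatch_fate(sch)
  expect_equal(rep$fraction_excised, 100, tolerance = 1e-8)
  expect_equal(rep$fraction_buried, 0)
  expect_identical(as.numeric(rep$contribution_factor), Inf)
})

test_that("contribution factor is the reciprocal buried fraction", {
  fake <- structure(list(fraction_buried = 0.005,
                         buried_is_upper_limit = TRUE),
                    class = "fate_report")
  cf <- contribution_factor(fake)
  expect_equal(as.numeric(cf), 2e4)
  expect_identical(attr(cf, "bound"), ">=")
  fake$fraction_buried <- 100
  expect_equal(as.numeric(contribution_factor(fake)), 1)
})

test_that("contribution factor is monotone in the branch rates", {
  ext1 <- mismatch_extension_kinetics(kcat_over_Km_limit = 0.1)
  base_p <- fix_n0()
  cf_for <- function(kcat, k3_n0) {
    p <- proofreading_params(k2 = base_p$k2, k3 = k3_n0, K3 = base_p$K3,
                             k4 = base_p$k4, k_minus4 = base_p$k_minus4)
    sch <- build_fate_scheme(p, fixture("excision_buried", "n-1"),
                             mismatch_extension_kinetics(kcat = kcat, Km = 87),
                             ext1)
    as.numeric(mismatch_fate(sch)$contribution_factor)
  }
  # faster extension -> more burial -> smaller factor
  expect_gt(cf_for(0.025, 2.9), cf_for(0.05, 2.9))
  # faster excision transfer -> larger factor
  expect_gt(cf_for(0.025, 5.8), cf_for(0.025, 2.9))
})
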