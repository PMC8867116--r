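test_that("upper-limit arithmetic matches the closed form", {
  expect_equal(upper_limit_kcat_km(0.05, 60, 5e-4), -log(0.95) / 0.03)
  expect_equal(upper_limit_kcat_km(0.05, 60, 5e-4), 1.71, tolerance = 1e-3)
  # detection fraction -> 0 drives the limit to 0
  expect_lt(upper_limit_kcat_km(1e-9, 180, 1e-3), 1e-8)
  expect_error(upper_limit_kcat_km(1, 180, 1e-3), "\\(0, 1\\)")
  expect_error(upper_limit_kcat_km(1.2, 180, 1e-3), "\\(0, 1\\)")
})

test_that("noiseless excision self-fit recovers the generating truth", {
  gen <- generate_excision(experiment_design("excision_20C", "1",
                                             noise = noiseless(), seed = 1))
  # start well away from the truth
  init <- proofreading_params(k2 = 5, k3 = 1, K3 = 0.2, k4 = 1, k_minus4 = 1)
  fit <- fit_excision(gen, init = init, seed = 1, n_starts = 2)
  expect_true(fit$converged)
  expect_lt(fit$rss, 1e-12)
  truth <- c(k2 = 18.3, k3 = 2.9, K3 = 0.061, k4 = 5.42, k_minus4 = 0.33)
  expect_equal(fit$estimates[names(truth)], truth, tolerance = 1e-3)
  # locked parameters are bit-identical to their inputs
  expect_identical(fit$estimates[["k1"]], 300)
  expect_identical(fit$estimates[["k_exo"]], 1000)
  expect_identical(fit$estimates[["k_minus1"]], 0.2)
})

test_that("noiseless extension self-fit recovers k_pol to 0.1%", {
  gen <- generate_extension(experiment_design("extension", "n-3",
                                              noise = noiseless(), seed = 1))
  fit <- fit_extension(gen, init = extension_params(0.3, 0.5, 5),
                       seed = 1, n_starts = 2)
  expect_true(fit$converged)
  truth <- c(k1_prime = 0.82, k_minus1_prime = 1.46, k_pol = 13.2)
  expect_equal(fit$estimates[names(truth)], truth, tolerance = 1e-3)
})

test_that("k_pol can be locked, mirroring the fast-substrate convention", {
  gen <- generate_extension(experiment_design("extension", "n-10",
                                              noise = noiseless(), seed = 1,
                                              times = 10^seq(-3, 1, length.out = 15)))
  init <- extension_params(k1_prime = 0.5, k_minus1_prime = 0.1, k_pol = 400)
  fit <- fit_extension(gen, init = init, lock_k_pol = TRUE, seed = 1,
                       n_starts = 2)
  expect_identical(fit$estimates[["k_pol"]], 400)
  fp <- fit$estimates[["k1_prime"]] /
    (fit$estimates[["k1_prime"]] + fit$estimates[["k_minus1_prime"]])
  expect_equal(fp, 1.5 / 1.54, tolerance = 0.01)
})

test_that("all-zero product data drives k_pol to its bound, flagged", {
  tc <- time_course("null", 20, 1L, c(0.1, 1, 10, 60, 180),
                    "extended-product", rep(0, 5))
  attr(tc, "conc_D") <- 0.075
  fit <- fit_extension(list(tc), init = extension_params(1, 1, 0.1),
                       seed = 1, n_starts = 2)
  expect_lt(fit$estimates[["k_pol"]] *
              fit$estimates[["k1_prime"]] /
              (fit$estimates[["k1_prime"]] + fit$estimates[["k_minus1_prime"]]),
            1e-3)
  expect_true(length(fit$at_bound) > 0)
})

test_that("joint float of binding constants reports ill-conditioning", {
  gen <- generate_excision(experiment_design("excision_20C", "1", seed = 5))
  fit <- fit_excision(gen, init = fixture("excision_20C", "1"), seed = 5,
                      n_starts = 1,
                      float = c("k1", "k2", "k_minus1", "k_minus2",
                                "k3", "K3", "k4", "k_minus4"))
  # the binding rates are not individually constrained: the engine must
  # surface this (huge condition number / ND flags / SEs swamping the
  # estimates), not report spuriously tight errors
  rel_se <- fit$se[c("k1", "k2")] / fit$estimates[c("k1", "k2")]
  ill <- fit$condition_number > 1e6 ||
    any(c("k1", "k2") %in% fit$not_determined) ||
    any(!is.finite(rel_se)) || any(rel_se > 1, na.rm = TRUE)
  expect_true(ill)
})

test_that("fit errors and degenerate specs are caught", {
  expect_error(fit_spec(list(), function(p, d) 0, c(a = 1)), "datasets")
  expect_error(fit_spec(list(data.frame()), function(p, d) 0, c(a = 1),
                        locked = "a"), "floated")
  js <- jsonlite::fromJSON(fit_to_json(structure(list(
    estimates = c(k = 1), se = c(k = 0.1), rss = 0.5, converged = TRUE,
    condition_number = 10, not_determined = character(),
    spec = list(locked = "x"), n_obs = 5, seed = 1), class = "fit_result")))
  expect_equal(js$estimates$k, 1)
  expect_true(js$converged)
})
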