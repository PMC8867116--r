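test_that("all-zero rates leave concentrations at initial conditions", {
  sp <- list(kin_species("D", "free-DNA"), kin_species("P", "absorbing-product"))
  sch <- kinetic_scheme(sp, list(kin_reaction("D", "P", 0, "k")), c(D = 0.7))
  tr <- integrate_scheme(sch, times = c(0.1, 1, 100))
  expect_equal(unname(tr$conc["D", ]), rep(0.7, 3))
  expect_equal(unname(tr$conc["P", ]), rep(0, 3))
})

test_that("irreversible binding matches the exact bimolecular solution", {
  sp <- list(kin_species("E", "free-enzyme"), kin_species("D", "free-DNA"),
             kin_species("ED", "complex"))
  sch <- kinetic_scheme(sp, list(kin_reaction(c("E", "D"), "ED", 300, "k1")),
                        c(E = 10, D = 0.01))
  tt <- c(2e-4, 5e-4, 1e-3, 2e-3)
  tr <- integrate_scheme(sch, times = tt)
  expect_equal(unname(tr$conc["D", ]),
               bimolecular_exact(tt, 300, 10, 0.01), tolerance = 1e-6)
  # pseudo-first-order approximation D0 exp(-k E0 t) holds to ~enzyme
  # depletion accuracy (0.2% here, E only 1000-fold over D)
  expect_equal(tr$conc[["D", 3]], 0.01 * exp(-3000 * 1e-3), tolerance = 5e-3)
})

test_that("DNA and enzyme pools are conserved to 1e-6 relative", {
  rows <- list(c("excision_20C", "1"), c("excision_20C", "4"),
               c("excision_4C", "2"), c("excision_buried", "n-3"))
  for (r in rows) {
    sch <- build_proofreading_scheme(fixture(r[1], r[2]), 1, 0.25)
    tr <- integrate_scheme(sch, times = default_time_grid("excision"))
    pools <- exokin:::species_pools(sch)
    dna <- colSums(tr$conc * pools$dna)
    enz <- colSums(tr$conc * pools$enzyme)
    expect_lt(max(abs(dna - 0.25)) / 0.25, 1e-6)
    expect_lt(max(abs(enz - 1)), 1e-6)
  }
})

test_that("halving tolerances changes observables by < 1e-4 relative", {
  sch <- scheme_n0()
  tt <- default_time_grid("excision")
  a <- observe(integrate_scheme(sch, tt, rtol = 1e-8, atol = 1e-12),
               "remaining-starting-primer")
  b <- observe(integrate_scheme(sch, tt, rtol = 5e-9, atol = 5e-13),
               "remaining-starting-primer")
  expect_lt(max(abs(a$concentration_uM - b$concentration_uM)) / 0.25, 1e-4)
})

test_that("biphasic decay shows the fast direct-binding phase", {
  sch <- scheme_n0()
  tr <- integrate_scheme(sch, times = c(0.015, 10))
  rem <- observe(tr, "remaining-starting-primer")$concentration_uM
  # just after the binding transient the fast phase has removed roughly
  # the direct-exo fraction k2/(k1+k2) ~ 6%, plus the beginning of the
  # slow transfer phase (k3 = 2.9 s^-1, ~4% by 15 ms)
  expect_gt(rem[1] / 0.25, 0.88)
  expect_lt(rem[1] / 0.25, 0.97)
  # but well short of completion on the 10 s experimental window
  expect_gt(rem[2], 0)
})

test_that("observe maps species to the experimental observables", {
  sch <- scheme_n0()
  tr <- integrate_scheme(sch, times = c(1e-9, 1))
  rem <- observe(tr, "remaining-starting-primer")
  expect_equal(rem$concentration_uM[1], 0.25, tolerance = 1e-6)
  expect_named(rem, c("substrate_id", "temperature_C", "replicate", "time_s",
                      "observable", "concentration_uM"))
  # without the inhibited state and with irreversible hydrolysis the
  # reaction goes to completion: remaining -> 0
  sch4 <- build_proofreading_scheme(fixture("excision_20C", "4"), 1, 0.25)
  tr4 <- integrate_scheme(sch4, times = 30)
  expect_lt(observe(tr4, "remaining-starting-primer")$concentration_uM, 1e-4)
  # extension runs to completion at long times (everything drains through
  # the primed state)
  sch3 <- build_extension_scheme(fixture("extension", "n-3"))
  tr3 <- integrate_scheme(sch3, times = 180)
  expect_equal(observe(tr3, "extended-product")$concentration_uM, 0.075,
               tolerance = 1e-5)
  expect_error(observe(tr3, "no-such-thing"))
})

test_that("pre-equilibration reaches the two-state equilibrium before t=0", {
  p <- fixture("extension", "n-3")
  sch <- build_extension_scheme(p)
  tr <- integrate_scheme(sch, times = 1e-9)
  primed <- tr$conc[["ED_p", 1]] / 0.075
  expect_equal(primed, p$fraction_primed, tolerance = 1e-6)
  expect_equal(tr$conc[["P_ext", 1]], 0, tolerance = 1e-9)
})

test_that("protocol validation and integration errors are informative", {
  sch <- scheme_n0()
  expect_error(integrate_scheme(sch, times = c(2, 1)), "strictly increasing")
  expect_error(kin_protocol(list(protocol_phase(1),
                                 protocol_phase("equilibrium"))),
               "must come first")
  expect_error(protocol_phase(-1))
  expect_error(integrate_scheme(sch, times = 1,
                                protocol = kin_protocol(list(
                                  protocol_phase(1, disable = "nope")))),
               "unknown reactions")
})

test_that("time-course serialization round trips through delimited text", {
  tc <- observe(integrate_scheme(scheme_n0(), c(0.01, 0.1, 1)),
                "remaining-starting-primer", substrate_id = "mm1",
                temperature = 20)
  f <- tempfile(fileext = ".tsv")
  write_time_course(tc, f, meta = c(seed = "1"))
  back <- read_time_course(f)
  expect_equal(back$concentration_uM, tc$concentration_uM)
  expect_equal(back$time_s, tc$time_s)
  expect_identical(back$substrate_id, tc$substrate_id)
  expect_match(readLines(f, n = 1), "^# seed: 1")
})

test_that("stochastic oracle obeys the exponential law and reproduces seeds", {
  sp <- list(kin_species("D", "free-DNA"), kin_species("P", "absorbing-product"))
  sch <- kinetic_scheme(sp, list(kin_reaction("D", "P", 2, "k")), c(D = 1))
  tt <- c(0.1, 0.35, 0.7, 1.5)
  g <- gillespie_oracle(sch, tt, n_molecules = 100, n_runs = 100, seed = 42)
  expected <- exp(-2 * tt)
  z <- abs(g$mean["D", ] - expected) / pmax(g$se["D", ], 1e-9)
  expect_lt(max(z), 3)
  g2 <- gillespie_oracle(sch, tt, n_molecules = 100, n_runs = 100, seed = 42)
  expect_identical(g, g2)
  # zero rates: no events ever
  sch0 <- kinetic_scheme(sp, list(kin_reaction("D", "P", 0, "k")), c(D = 1))
  g0 <- gillespie_oracle(sch0, tt, n_molecules = 50, n_runs = 5, seed = 1)
  expect_equal(unname(g0$mean["D", ]), rep(1, 4))
})

test_that("ODE mean agrees with the Gillespie mean within 3x Monte-Carlo SE", {
  for (r in list(c("excision_20C", "1"), c("excision_20C", "4"))) {
    sch <- build_proofreading_scheme(fixture(r[1], r[2]), 1, 0.25)
    tt <- c(0.005, 0.02, 0.1, 0.5, 2)
    g <- gillespie_oracle(sch, tt, n_molecules = 250, n_runs = 120, seed = 7)
    tr <- integrate_scheme(sch, times = tt)
    rem <- names(sch$roles)[sch$roles %in% c("free-DNA", "complex")]
    ode <- colSums(tr$conc[rem, , drop = FALSE])
    ssa <- colSums(g$mean[rem, , drop = FALSE])
    se <- sqrt(colSums(g$se[rem, , drop = FALSE]^2))
    expect_lt(max(abs(ssa - ode) / pmax(se, 1e-9)), 3)
  }
})
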