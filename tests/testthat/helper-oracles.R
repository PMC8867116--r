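# Independent closed-form oracles used across the test files.  These are
# derived from first principles and never call the integrator.

# Exact solution of the irreversible bimolecular reaction E + D -> ED:
# with dE = E0 - D0 conserved, D(t) = D0 dE exp(-k dE t) / (E0 - D0 exp(-k dE t)).
bimolecular_exact <- function(t, k, E0, D0) {
  dE <- E0 - D0
  D0 * dE * exp(-k * dE * t) / (E0 - D0 * exp(-k * dE * t))
}

# Absorption probabilities for one excision/extension stage of the fate
# chain: starting in the pol-site complex, competing extension (k_ext)
# against transfer (k3) with return (k_minus3) and hydrolysis (k_exo).
# P(extend) from the embedded jump chain.
stage_extend_prob <- function(k3, k_minus3, k_exo, k_ext) {
  k_ext * (k_exo + k_minus3) / (k3 * k_exo + k_ext * (k_exo + k_minus3))
}

# Standard fixtures used in many tests.
fix_n0 <- function() fixture("excision_20C", "1")
scheme_n0 <- function() build_proofreading_scheme(fix_n0(), 1, 0.25)

noiseless <- function() noise_model(0, 0)
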