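# Shared fixtures: the published figure-caption parameter sets and
# random-model generators used across the suite.

fig1a_model <- function(phi = 1e5) {
  pm_single(k = 100, c = 50, lam = 8, phi = phi, mu = 10)  # K = phi/10
}

mem_params <- function() list(k = 100, c = 50, lam = 8, phi = 1e5, mu = 10)

fig2_model <- function(lam1 = 5) {
  pm_two_pop(k1 = 125, c1 = 80, lam1 = lam1, mu1 = 10,
             k2 = 100, c2 = 20, lam2 = 4, mu2 = 5, phi = 5e3)
}

fig5_model <- function(phi1 = 1e6, phi2 = 1e5) {
  pm_two_compartment(k_m = 150, c_m = 80, lam_m1 = 10, lam_m2 = 5,
                     k_n = 100, c_n = 120, lam_n1 = 50, A = 10,
                     phi1 = phi1, mu1 = 10, phi2 = phi2, mu2 = 3)
}

# a random stable single-population parameter set (ck > lam*mu with margin)
random_stable_single <- function() {
  repeat {
    k <- runif(1, 10, 300); c <- runif(1, 10, 200)
    lam <- runif(1, 1, 20); mu <- runif(1, 1, 30)
    if (c * k > 1.5 * lam * mu) {
      return(pm_single(k, c, lam, phi = runif(1, 1e4, 1e6), mu = mu))
    }
  }
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_true(all(abs(actual - expected) <= rel_tol * pmax(abs(expected),
                                                           1e-12)),
              label = sprintf("max rel err %.3g vs tol %.3g",
                              max(abs(actual - expected) /
                                    pmax(abs(expected), 1e-12)), rel_tol))
}

# relative tolerance for large components, absolute floor for components
# expected to vanish (e.g. an excluded population)
expect_near <- function(actual, expected, rel_tol, abs_tol) {
  expect_true(all(abs(actual - expected) <=
                    pmax(rel_tol * abs(expected), abs_tol)),
              label = sprintf("max abs err %.3g (rel %.3g, abs floor %.3g)",
                              max(abs(actual - expected)), rel_tol,
                              abs_tol))
}
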