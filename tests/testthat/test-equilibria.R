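test_that("carrying capacities emerge as production/consumption ratios", {
  expect_equal(carrying_capacity(fig1a_model())$K, 1e4)
  cc <- carrying_capacity(fig5_model())
  expect_equal(cc$K_m, 1e5 / 3)
  expect_equal(cc$K_n, 1e5 - 1e5 / 3)
  expect_equal(cc$K_total, 1e5)
  expect_true(cc$feasible)
  # memory capacity above the total makes the naive compartment infeasible
  cc2 <- carrying_capacity(fig5_model(phi2 = 4e6))  # phi2/mu2 > phi1/mu1
  expect_lt(cc2$K_n, 0)
  expect_false(cc2$feasible)
  expect_error(carrying_capacity(pm_lotka_volterra(1, 1, 10, 10, 1, 1)),
               "parameters")
})

test_that("the single-model equilibrium follows phi/mu and k*phi/(lam*mu)", {
  eq <- single_equilibrium(fig1a_model())
  expect_equal(eq$values$sizes, 1e4)
  expect_equal(eq$values$interleukins, 1.25e5)
  expect_true(eq$feasible)
  eqb <- single_equilibrium(fig1a_model(phi = 8e4))
  expect_equal(eqb$values$sizes, 8e3)
  # x* and h* depend on k and lam only through k/lam
  m1 <- pm_single(100, 50, 8, 1e5, 10)
  m2 <- pm_single(300, 50, 24, 1e5, 10)
  expect_equal(single_equilibrium(m1)$values$interleukins,
               single_equilibrium(m2)$values$interleukins)
})

test_that("every feasible closed form annihilates its vector field", {
  set.seed(11)
  for (rep in 1:30) {
    m <- random_stable_single()
    eq <- single_equilibrium(m)
    y <- flatten_state(eq$values, m)
    scale <- max(abs(y), 1)
    expect_lt(max(abs(build_vector_field(m)(0, y))), 1e-9 * scale)
  }
  # two-population line: several points along the manifold
  m2 <- fig2_model()
  for (x2s in c(0, 200, 600, 999)) {
    eq2 <- two_pop_equilibria(m2, x2_star = x2s)
    y <- flatten_state(eq2$values, m2)
    expect_lt(max(abs(build_vector_field(m2)(0, y))), 1e-9 * max(abs(y)))
  }
  # naive pool and two-compartment points
  mn <- pm_naive_pool(100, 50, 8, 1e5, 10, A = c(3, 7, 15))
  yn <- flatten_state(naive_equilibrium(mn)$values, mn)
  expect_lt(max(abs(build_vector_field(mn)(0, yn))), 1e-9 * max(abs(yn)))
  mt <- fig5_model()
  yt <- flatten_state(two_compartment_equilibrium(mt)$values, mt)
  expect_lt(max(abs(build_vector_field(mt)(0, yt))), 1e-9 * max(abs(yt)))
})

test_that("the two-population system classifies its trichotomy from lam1*k2 - lam2*k1", {
  eq <- two_pop_equilibria(fig2_model())      # balanced: 5*100 = 4*125
  expect_equal(eq$kind, "line_of_equilibria")
  expect_equal(eq$free_parameter_range, c(0, 1000))  # x2* up to phi/mu2
  # reported point sits on the closed-form line
  x2s <- eq$values$sizes[2]
  expect_equal(eq$values$sizes[1], 500 - 0.5 * x2s)
  expect_equal(eq$values$interleukins,
               125 * 5e3 / (5 * 10) + 125 * 5 / 50 * x2s)
  eq_hi <- two_pop_equilibria(fig2_model(lam1 = 10))
  expect_equal(eq_hi$kind, "exclusion_x2")
  expect_equal(eq_hi$values$sizes, c(500, 0))
  eq_lo <- two_pop_equilibria(fig2_model(lam1 = 2.5))
  expect_equal(eq_lo$kind, "exclusion_x1")
  expect_equal(eq_lo$values$sizes, c(0, 1000))
})

test_that("equal consumption rates pin the equilibrium total at phi/mu", {
  m <- pm_two_pop(100, 50, 8, 10, 100, 50, 8, 10, phi = 5e4)
  for (x2s in c(0, 1000, 4999)) {
    eq <- two_pop_equilibria(m, x2_star = x2s)
    expect_equal(sum(eq$values$sizes), 5e3)
    expect_equal(eq$values$interleukins,
                 100 * 5e4 / (8 * 10))    # h* independent of the split
  }
})

test_that("naive equilibrium is affinity-proportional with capacity K", {
  m <- pm_naive_pool(100, 50, 8, 1e5, 10, A = c(10, 30))
  eq <- naive_equilibrium(m)
  expect_equal(eq$values$sizes, c(2500, 7500))
  expect_equal(eq$notes$h_star, (100 * 1e5 - 10 * 40) / (8 * 10))
  # symmetry: equal affinities split K evenly
  m2 <- pm_naive_pool(100, 50, 8, 1e5, 10, A = rep(4, 5))
  expect_equal(naive_equilibrium(m2)$values$sizes, rep(2e3, 5))
  # a clone with zero antigenic force has zero equilibrium size
  m3 <- pm_naive_pool(100, 50, 8, 1e5, 10, A = c(0, 10))
  expect_equal(naive_equilibrium(m3)$values$sizes[1], 0)
  # infeasible when consumption of force outweighs production: h* <= 0
  m4 <- pm_naive_pool(k = 1, c = 50, lam = 8, phi = 10, mu = 10,
                      A = c(5, 10))
  expect_false(naive_equilibrium(m4)$feasible)
})

test_that("two-compartment equilibrium responds to each interleukin as claimed", {
  eq <- two_compartment_equilibrium(fig5_model())
  expect_equal(eq$values$sizes, c(1e5 / 3, 1e5 - 1e5 / 3))
  expect_true(eq$feasible)
  # raising IL-7 production adds naive cells only
  eq7 <- two_compartment_equilibrium(fig5_model(phi1 = 1.5e6))
  expect_equal(eq7$values$sizes[1], eq$values$sizes[1])
  expect_gt(eq7$values$sizes[2], eq$values$sizes[2])
  # raising IL-15 production converts naive space into memory space
  eq15 <- two_compartment_equilibrium(fig5_model(phi2 = 2e5))
  expect_gt(eq15$values$sizes[1], eq$values$sizes[1])
  expect_lt(eq15$values$sizes[2], eq$values$sizes[2])
  # total is pinned by IL-7 alone
  expect_equal(sum(eq15$values$sizes), sum(eq$values$sizes))
  # scaling lam_m2 rescales h2* inversely, leaving the populations alone
  m_scaled <- fig5_model()
  m_scaled$tc$lam_m2 <- m_scaled$tc$lam_m2 * 4
  eq_s <- two_compartment_equilibrium(m_scaled)
  expect_equal(eq_s$values$sizes, eq$values$sizes)
  expect_equal(eq_s$notes$h2_star, eq$notes$h2_star / 4)
  # degenerate naive compartment is reported, not raised
  expect_equal(two_compartment_equilibrium(fig5_model(phi2 = 4e6))$kind,
               "degenerate")
})

test_that("the stability criterion ck > lam*mu matches the Jacobian spectrum", {
  m <- fig1a_model()     # ck = 5000 > lam*mu = 80
  rep1 <- stability(m)
  expect_true(rep1$condition_holds)
  expect_true(rep1$numerically_stable)
  expect_true(all(Re(rep1$eigenvalues) < 0))
  # analytic characteristic polynomial agrees with the numeric spectrum
  roots <- single_characteristic_roots(m)
  expect_equal(sort(Re(roots)), sort(Re(rep1$eigenvalues)),
               tolerance = 1e-6)
  # violating the criterion produces an unstable mode
  m_bad <- pm_single(k = 2, c = 2, lam = 8, phi = 1e5, mu = 10)  # ck=4<80
  rep2 <- stability(m_bad)
  expect_false(rep2$condition_holds)
  expect_false(rep2$numerically_stable)
  expect_true(any(Re(rep2$eigenvalues) > 0))
  # ...and the trajectory fails to settle
  tr <- integrate_pm(m_bad, system_state(sizes = 1e4 * 1.01,
                                         velocities = 0,
                                         interleukins = 2e4 / 8 * 1.01),
                     integrator_settings(t_max = 60))
  expect_false(tr$converged)
})

test_that("the coexistence line carries exactly one zero mode", {
  m <- fig2_model()
  eq <- two_pop_equilibria(m, x2_star = 400)
  rep <- stability(m, eq)
  expect_equal(rep$zero_modes, 1L)
  expect_true(rep$numerically_stable)
})

test_that("marginal ck = lam*mu is classified as not stable", {
  m <- pm_single(k = 4, c = 20, lam = 8, phi = 1e5, mu = 10)  # ck = 80 = lam*mu
  rep <- stability(m)
  expect_false(rep$condition_holds)
  expect_gte(rep$zero_modes, 1L)
})

test_that("the memory-pool equilibrium total is K for any clone count", {
  p <- mem_params()
  for (M in c(1, 5, 50)) {
    m <- do.call(pm_memory_pool, c(list(M = M), p))
    expect_equal(uninvadable_total(m), 1e4)
    expect_equal(sum(equilibrium(m)$values$sizes), 1e4)
  }
  # doubling production doubles the total
  m2 <- pm_memory_pool(5, p$k, p$c, p$lam, 2 * p$phi, p$mu)
  expect_equal(uninvadable_total(m2), 2e4)
  expect_error(uninvadable_total(do.call(pm_memory_pool,
                                         c(list(M = 3), p)), 4),
               "does not match")
})
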