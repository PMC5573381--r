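test_that("the single population relaxes to its equilibrium and stays non-negative", {
  m <- fig1a_model()
  tr <- integrate_pm(m, system_state(sizes = 100, interleukins = 0))
  expect_true(tr$converged)
  fs <- final_state(tr)
  expect_rel_equal(fs$sizes, 1e4, 1e-3)
  expect_rel_equal(fs$interleukins, 1.25e5, 1e-3)
  expect_true(all(tr$states[, c("x", "h")] >= 0))
  # times strictly increasing
  expect_true(all(diff(tr$times) > 0))
})

test_that("homeostatic proliferation restores the reduced-production equilibrium", {
  # equilibrate at phi = 8e4, drop the population, re-integrate: the pool
  # returns to the same (reduced-capacity) equilibrium
  m <- fig1a_model(phi = 8e4)
  eq <- find_steady_state(m, system_state(sizes = 100, interleukins = 0))
  expect_rel_equal(eq$sizes, 8e3, 1e-3)
  dropped <- perturb(eq, d_sizes = -0.6 * eq$sizes, zero_velocities = TRUE)
  expect_equal(dropped$sizes, 0.4 * eq$sizes)
  back <- find_steady_state(m, dropped)
  expect_rel_equal(back$sizes, eq$sizes, 1e-3)
  expect_rel_equal(back$interleukins, eq$interleukins, 1e-3)
})

test_that("competitive exclusion drives the disadvantaged population to zero", {
  m <- fig2_model(lam1 = 10)   # lam1*k2 = 1000 > lam2*k1 = 500
  tr <- integrate_pm(m, system_state(sizes = c(100, 200), interleukins = 0),
                     integrator_settings(t_max = 2000))
  expect_true(tr$converged)
  fs <- final_state(tr)
  expect_rel_equal(fs$sizes[1], 500, 1e-3)
  expect_lt(fs$sizes[2], 1e-6 * 500)
  expect_true(all(tr$states[, c("x1", "x2", "h")] >= 0))
})

test_that("equal-parameter clone trajectories superpose to the single-model trajectory", {
  p <- mem_params()
  mm <- do.call(pm_memory_pool, c(list(M = 3), p))
  ms <- fig1a_model()
  s3 <- system_state(sizes = c(500, 1200, 300), interleukins = 1e4)
  s1 <- system_state(sizes = 2000, interleukins = 1e4)
  set <- integrator_settings(t_max = 100, dt_out = 1)
  tr3 <- integrate_pm(mm, s3, set)
  tr1 <- integrate_pm(ms, s1, set)
  shared <- intersect(round(tr3$times, 9), round(tr1$times, 9))
  i3 <- match(shared, round(tr3$times, 9))
  i1 <- match(shared, round(tr1$times, 9))
  total3 <- rowSums(tr3$states[i3, c("m1", "m2", "m3"), drop = FALSE])
  expect_rel_equal(total3, tr1$states[i1, "x"], 1e-6)
})

test_that("on the coexistence manifold the final point depends on the start", {
  m <- fig2_model()   # lam1*k2 = lam2*k1 = 500
  finals <- lapply(list(c(100, 200), c(300, 50), c(50, 400)),
                   function(x0) {
                     find_steady_state(m, system_state(sizes = x0,
                                                       interleukins = 0),
                                       integrator_settings(t_max = 1000))
                   })
  sizes <- t(vapply(finals, `[[`, numeric(2), "sizes"))
  # all on the line mu1*x1 + mu2*x2 = phi, but pairwise distinct
  expect_rel_equal(10 * sizes[, 1] + 5 * sizes[, 2], rep(5e3, 3), 1e-3)
  expect_gt(min(dist(sizes)), 1)
})

test_that("an interleukin clamped at zero is released when production catches up", {
  # overloaded pool: consumption far exceeds production, h crashes to 0,
  # then the population decays and h is released
  m <- pm_single(k = 100, c = 50, lam = 8, phi = 1e3, mu = 10)  # K = 100
  tr <- integrate_pm(m, system_state(sizes = 5e3, interleukins = 50),
                     integrator_settings(t_max = 300))
  ev <- tr$constraint_events
  expect_true(any(ev$variable == "h" & ev$kind == "clamped_at_zero"))
  expect_true(any(ev$variable == "h" & ev$kind == "released"))
  expect_true(all(tr$states[, "h"] >= 0))
  expect_true(tr$converged)
  expect_rel_equal(final_state(tr)$sizes, 100, 1e-3)
})

test_that("find_steady_state raises a typed condition when it cannot converge", {
  m <- fig1a_model()
  err <- tryCatch(
    find_steady_state(m, system_state(sizes = 100, interleukins = 0),
                      integrator_settings(t_max = 1)),
    pm_nonconvergence = function(e) e)
  expect_s3_class(err, "pm_nonconvergence")
  expect_s3_class(err$last_state, "pm_state")
})

test_that("perturb shifts sizes, appends clones and can zero velocities", {
  s <- system_state(sizes = c(10, 20), velocities = c(1, -1),
                    interleukins = 5)
  expect_equal(perturb(s), s)                      # identity at zero deltas
  s2 <- perturb(s, d_sizes = c(5, 0))
  expect_equal(s2$sizes, c(15, 20))
  expect_equal(s2$velocities, c(1, -1))
  s3 <- perturb(s, new_clones = 7, zero_velocities = TRUE)
  expect_equal(s3$sizes, c(10, 20, 7))
  expect_equal(s3$velocities, c(0, 0, 0))
  expect_error(perturb(s, d_sizes = c(-11, 0)), "below 0")
})

test_that("trajectories export as tidy CSV with a stable column order", {
  m <- fig1a_model()
  tr <- integrate_pm(m, system_state(sizes = 100, interleukins = 0),
                     integrator_settings(t_max = 20))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  df <- read.csv(path)
  expect_named(df, c("t", "variable", "value"))
  expect_equal(unique(df$variable), c("x", "v_x", "h"))
  s <- trajectory_summary(tr)
  expect_false(s$converged)
  expect_type(s$final_state$sizes, "double")
})
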