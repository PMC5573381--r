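test_that("presets carry the published caption parameters", {
  s <- load_scenario("fig1a")
  p <- s$model$populations[[1]]
  expect_equal(c(p$k, p$c, p$lam, p$mu), c(100, 50, 8, 10))
  expect_equal(s$model$interleukins[[1]]$phi, 1e5)
  expect_equal(load_scenario("fig1b")$model$interleukins[[1]]$phi, 8e4)

  s2 <- load_scenario("fig2")
  p1 <- s2$model$populations[[1]]; p2 <- s2$model$populations[[2]]
  expect_equal(c(p1$k, p1$c, p1$lam, p1$mu), c(125, 80, 5, 10))
  expect_equal(c(p2$k, p2$c, p2$lam, p2$mu), c(100, 20, 4, 5))
  expect_equal(s2$model$interleukins[[1]]$phi, 5e3)
  expect_gte(length(s2$initial), 5)

  s5 <- load_scenario("fig5")
  expect_equal(s5$model$tc[c("k_m", "c_m", "lam_m1", "lam_m2", "k_n",
                             "c_n", "lam_n1", "A", "phi1", "mu1", "phi2",
                             "mu2")],
               list(k_m = 150, c_m = 80, lam_m1 = 10, lam_m2 = 5,
                    k_n = 100, c_n = 120, lam_n1 = 50, A = 10,
                    phi1 = 1e6, mu1 = 10, phi2 = 1e5, mu2 = 3))
  expect_error(load_scenario("fig99"), "unknown preset")
})

test_that("scenario configs round-trip through YAML and JSON", {
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    spec <- load_scenario("fig1a")
    write_scenario(spec, path)
    spec2 <- load_scenario(path)
    expect_equal(spec2$model, spec$model)
    expect_equal(spec2$name, spec$name)
    expect_equal(lapply(spec2$initial, unlist),
                 lapply(spec$initial, unlist))
    expect_equal(spec2$settings$t_max, spec$settings$t_max)
  }
  bad <- withr::local_tempfile(fileext = ".yaml",
                               lines = "name: broken\nmodel:\n  lv: {}")
  expect_error(load_scenario(bad), "model_id|initial")
})

test_that("the drop-recovery protocol returns to the reduced-phi equilibrium", {
  out <- withr::local_tempdir()
  res <- run_scenario("fig1c", out, quiet = TRUE)
  expect_true(file.exists(file.path(out, "trajectory.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  tr <- res$trajectory_1
  expect_true(tr$converged)
  fs <- final_state(tr)
  expect_rel_equal(fs$sizes, 8e3, 1e-3)   # phi/mu with phi = 8e4
  df <- read.csv(file.path(out, "trajectory.csv"))
  x <- df$value[df$variable == "x"]
  expect_lt(x[1], 0.5 * 8e3)              # starts from the applied drop
})

test_that("raising IL-7 production in the two-compartment scenario moves only the naive pool", {
  s <- load_scenario("fig5")
  eq <- two_compartment_equilibrium(s$model)
  s$model$tc$phi1 <- 1.5e6
  eq_up <- two_compartment_equilibrium(s$model)
  expect_equal(eq_up$values$sizes[1], eq$values$sizes[1])
  expect_gt(eq_up$values$sizes[2], eq$values$sizes[2])
})

test_that("scenario runs are deterministic", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_scenario("fig1a", d1, quiet = TRUE)
  run_scenario("fig1a", d2, quiet = TRUE)
  t1 <- readLines(file.path(d1, "trajectory.csv"))
  t2 <- readLines(file.path(d2, "trajectory.csv"))
  expect_identical(t1, t2)
})

test_that("event-protocol scenarios write a turnover ledger", {
  out <- withr::local_tempdir()
  res <- run_scenario("fig3a", out, quiet = TRUE)
  expect_true(file.exists(file.path(out, "ledger.csv")))
  lg <- res$ledger
  expect_rel_equal(sum(lg$clones), 1e4, 1e-3)   # pool back at K
  # the new clone settled near m0*K/(K + m0)
  expect_rel_equal(unname(lg$clones[length(lg$clones)]),
                   2e3 * 1e4 / (1e4 + 2e3), 0.01)
})

test_that("fixtures are reproducible and schema-stable", {
  f1 <- generate_fixture("event_sequence", 10, seed = 123)
  f2 <- generate_fixture("event_sequence", 10, seed = 123)
  expect_identical(f1, f2)
  expect_named(f1, c("order", "kind", "clone_id", "size"))
  expect_true(all(f1$size > 0))
  # reactivations only ever reference clones created earlier
  created <- 0
  for (i in seq_len(nrow(f1))) {
    if (f1$kind[i] == "naive_activation") {
      created <- created + 1
    } else {
      expect_true(as.integer(sub("clone", "", f1$clone_id[i])) <= created)
    }
  }
  f0 <- generate_fixture("affinity_profile", 0, seed = 1)
  expect_named(f0, c("clone_id", "affinity"))
  expect_equal(nrow(f0), 0)
})

test_that("larger event sizes drive more incumbent extinctions downstream", {
  run_frac_extinct <- function(scale_meanlog, seed) {
    fx <- generate_fixture("event_sequence", 12, seed = seed,
                           meanlog = scale_meanlog, sdlog = 0.3,
                           reactivation_prob = 0)
    evs <- lapply(fx$size, function(s)
      activation_event("naive_activation", m_new_0 = s))
    incumbents <- c(i1 = 400, i2 = 300, i3 = 200, i4 = 100)
    lg <- run_event_sequence(list(K = 1000), evs,
                             initial_clones = incumbents,
                             mode = "closed_form")
    mean(names(incumbents) %in% lg$extinct)
  }
  small <- vapply(1:5, function(s) run_frac_extinct(log(50), s), numeric(1))
  large <- vapply(1:5, function(s) run_frac_extinct(log(800), s), numeric(1))
  expect_gt(mean(large), mean(small))
})
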