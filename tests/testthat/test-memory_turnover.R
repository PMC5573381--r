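test_that("a naive activation rescales the whole pool by K/(K + m_new_0)", {
  lg <- memory_ledger(c(old = 500), K = 1000)
  lg <- apply_naive_activation(lg, 100, clone_id = "new")
  expect_equal(unname(lg$clones["new"]), 100 * 1000 / 1100)
  expect_equal(unname(lg$clones["old"]), 500 * 1000 / 1100)
  # a vanishing entry changes nothing in the limit
  lg2 <- apply_naive_activation(memory_ledger(c(a = 500), K = 1000), 1e-9)
  expect_equal(unname(lg2$clones["a"]), 500, tolerance = 1e-10)
  # the entry size is bounded above by K and increasing in m_new_0
  m1s <- vapply(c(10, 100, 1e3, 1e4, 1e6),
                function(m0) m0 * 1000 / (1000 + m0), numeric(1))
  expect_true(all(diff(m1s) > 0))
  expect_true(all(m1s < 1000))
})

test_that("reactivation boosts the activated clone and shrinks the rest", {
  lg <- memory_ledger(c(a = 50, b = 300), K = 1000)
  lg <- apply_memory_reactivation(lg, "a", 200)
  expect_equal(unname(lg$clones["a"]), 250 * 1000 / 1200)  # 208.333...
  expect_equal(unname(lg$clones["b"]), 250)
  expect_gt(lg$clones["a"], 50)    # boosted whenever m_{1,0} < K
  expect_lt(lg$clones["b"], 300)
  expect_error(apply_memory_reactivation(lg, "nope", 10), "unknown")
})

test_that("the sequential product equals iterated per-event updates exactly", {
  expect_equal(sequential_size(100, c(100, 100), 1000),
               100 * (10 / 11)^2)
  expect_equal(sequential_size(100, numeric(0), 1000), 100)
  set.seed(5)
  for (rep in 1:10) {
    K <- runif(1, 500, 5000)
    deltas <- runif(sample(2:6, 1), 1, K)
    m0 <- runif(1, 1, K)
    lg <- memory_ledger(c(watched = m0, other = K - m0), K,
                        removal_threshold = 0)   # keep tiny clones
    for (d in deltas) lg <- apply_naive_activation(lg, d)
    expect_equal(unname(lg$clones["watched"]),
                 sequential_size(m0, deltas, K))
    # the product is permutation-invariant
    expect_equal(sequential_size(m0, rev(deltas), K),
                 sequential_size(m0, deltas, K))
  }
})

test_that("extinction predicates: exact product vs logarithmic approximation", {
  # the approximation predicts extinction once sum(deltas) > K*log(m0)
  p <- extinction_predicate(20, rep(100, 30), 1000)  # sum = 3000 > 2995.7
  expect_true(p$log_approx)
  p2 <- extinction_predicate(20, rep(100, 29), 1000) # sum = 2900 < 2995.7
  expect_false(p2$log_approx)
  # an initially sub-threshold clone is extinct under both modes
  p3 <- extinction_predicate(0.5, numeric(0), 1000)
  expect_true(p3$exact && p3$log_approx && !p3$disagree)
  # small events: modes agree across random sequences
  set.seed(9)
  for (rep in 1:20) {
    K <- 1000
    deltas <- runif(sample(5:40, 1), 1, K / 20)
    m0 <- runif(1, 1.5, 100)
    p <- extinction_predicate(m0, deltas, K)
    expect_false(p$disagree)
  }
  # one event comparable to K: the coarse log rule overshoots
  p4 <- extinction_predicate(3, 1200, 1000)
  expect_false(p4$exact)        # 3 * 1000/2200 = 1.36 cells remain
  expect_true(p4$log_approx)    # log(3) = 1.10 < 1.2
  expect_true(p4$disagree)
})

test_that("clones dropping below one cell are removed and recorded", {
  lg <- memory_ledger(c(tiny = 2, big = 998), K = 1000)
  lg <- apply_naive_activation(lg, 1500)   # shrink factor 0.4
  expect_false("tiny" %in% names(lg$clones))
  expect_true("tiny" %in% lg$extinct)
  h <- lg$history
  expect_true(h$extinct_flag[h$clone_id == "tiny"])
  expect_false(any(h$extinct_flag[h$clone_id != "tiny"]))
})

test_that("closed-form and ODE turnover agree event by event", {
  p <- mem_params()
  evs <- list(activation_event("naive_activation", m_new_0 = 2000),
              activation_event("memory_reactivation", clone_id = "clone1",
                               delta_m = 1500),
              activation_event("naive_activation", m_new_0 = 800))
  init <- c(clone1 = 6e3, clone2 = 4e3)
  cf <- run_event_sequence(p, evs, init, mode = "closed_form")
  od <- run_event_sequence(p, evs, init, mode = "ode")
  expect_setequal(names(cf$clones), names(od$clones))
  expect_rel_equal(od$clones[names(cf$clones)], cf$clones, 0.01)
  # pool total back at K after the ODE relaxations
  expect_rel_equal(sum(od$clones), 1e4, 1e-3)
  # per-event records exist for both modes
  expect_equal(max(cf$history$event_index), 3L)
  expect_equal(max(od$history$event_index), 3L)
})

test_that("non-reactivated clones shrink monotonically toward extinction", {
  p <- list(K = 1000)
  evs <- lapply(rep(400, 25), function(d)
    activation_event("naive_activation", m_new_0 = d))
  lg <- run_event_sequence(p, evs, c(resident = 1000), mode = "closed_form")
  h <- lg$history
  res <- h[h$clone_id == "resident", ]
  expect_true(all(diff(res$post_size) < 0))
  expect_false("resident" %in% names(lg$clones))  # eventually extinct
  # clones entering with more cells persist longer
  evs2 <- lapply(rep(500, 5), function(d)
    activation_event("naive_activation", m_new_0 = d))
  lg_big <- run_event_sequence(p, list(
    activation_event("naive_activation", m_new_0 = 800)), numeric(0),
    mode = "closed_form")
  first_id <- names(lg_big$clones)[1]
  survived_big <- run_event_sequence(p, evs2, lg_big$clones,
                                     mode = "closed_form")
  lg_small <- run_event_sequence(p, list(
    activation_event("naive_activation", m_new_0 = 30)), numeric(0),
    mode = "closed_form")
  survived_small <- run_event_sequence(p, evs2, lg_small$clones,
                                       mode = "closed_form")
  n_events_survived <- function(lg, id) {
    h <- lg$history
    rows <- h[h$clone_id == id & !h$extinct_flag, ]
    nrow(rows)
  }
  expect_gte(n_events_survived(survived_big, first_id),
             n_events_survived(survived_small, names(lg_small$clones)[1]))
})

test_that("event CSV round-trips into activation events", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(order = c(2, 1), kind = c("memory_reactivation",
                                             "naive_activation"),
                   clone_id = c("clone1", ""), size = c(50, 200))
  write.csv(df, path, row.names = FALSE)
  evs <- read_events_csv(path)
  expect_length(evs, 2)
  expect_equal(evs[[1]]$kind, "naive_activation")  # reordered by `order`
  expect_equal(evs[[1]]$m_new_0, 200)
  expect_equal(evs[[2]]$clone_id, "clone1")
  expect_error(read_events_csv(withr::local_tempfile(fileext = ".csv",
                                                     lines = "a,b\n1,2")),
               "missing columns")
})
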