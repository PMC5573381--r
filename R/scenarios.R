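# Scenario presets (published figure-caption parameter sets), YAML/JSON scenario
# configs, scenario execution with manifest output, and synthetic fixture
# generation for event sequences and affinity profiles.

#' Scenario specification
#'
#' A validated bundle of model, initial condition(s), integrator settings
#' and optional protocol extras, as loaded from a preset or a config file.
#'
#' @param name Scenario name.
#' @param model A `pm_model`.
#' @param initial A list of initial-condition lists, each with `sizes` and
#'   optional `velocities` / `interleukins` (missing blocks default to 0).
#' @param settings [integrator_settings()].
#' @param protocol One of `"integrate"` (default), `"drop_recovery"`
#'   (equilibrate, multiply sizes by `drop_factor`, re-integrate),
#'   `"events"` (run an activation event sequence) or `"turnover_sweep"`
#'   (closed form vs ODE across a grid of event sizes).
#' @param drop_factor Size multiplier for `"drop_recovery"`.
#' @param events List of [activation_event()]s for `"events"`.
#' @param turnover_params Parameter list for event protocols (see
#'   [run_event_sequence()]).
#' @param seed Optional integer seed, recorded in all outputs.
#' @return An object of class `pm_scenario`.
#' @export
scenario_spec <- function(name, model, initial, settings =
                            integrator_settings(),
                          protocol = "integrate", drop_factor = NULL,
                          events = NULL, turnover_params = NULL,
                          seed = NULL) {
  stopifnot(inherits(model, "pm_model"),
            protocol %in% c("integrate", "drop_recovery", "events",
                            "turnover_sweep"))
  if (protocol == "drop_recovery" &&
      (is.null(drop_factor) || drop_factor <= 0 || drop_factor >= 1)) {
    stop("drop_recovery requires 0 < drop_factor < 1")
  }
  if (!length(initial) || !is.list(initial[[1]])) initial <- list(initial)
  initial <- lapply(initial, function(ic) {
    if (is.null(ic$sizes)) stop("initial condition is missing 'sizes'")
    ic
  })
  structure(list(name = name, model = model, initial = initial,
                 settings = settings, protocol = protocol,
                 drop_factor = drop_factor, events = events,
                 turnover_params = turnover_params, seed = seed),
            class = "pm_scenario")
}

initial_state <- function(ic, model) {
  lay <- model_layout(model)
  system_state(
    sizes = unlist(ic$sizes),
    velocities = if (!is.null(ic$velocities)) unlist(ic$velocities)
                 else if (lay$n_vel) rep(0, lay$n_vel) else numeric(0),
    interleukins = if (!is.null(ic$interleukins)) unlist(ic$interleukins)
                   else rep(0, lay$n_il))
}

# Figure-caption parameter sets. Units are the models' own dimensionless
# units throughout.
pm_presets <- function() {
  fig1 <- function(phi) pm_single(k = 100, c = 50, lam = 8, phi = phi,
                                  mu = 10)
  mem <- list(k = 100, c = 50, lam = 8, phi = 1e5, mu = 10)  # K = 1e4
  list(
    fig1a = function() scenario_spec(
      "fig1a", fig1(1e5), list(sizes = 100), integrator_settings()),
    fig1b = function() scenario_spec(
      "fig1b", fig1(8e4), list(sizes = 100), integrator_settings()),
    fig1c = function() scenario_spec(
      "fig1c", fig1(8e4), list(sizes = 100), integrator_settings(),
      protocol = "drop_recovery", drop_factor = 0.4),
    fig2 = function() scenario_spec(
      "fig2",
      pm_two_pop(k1 = 125, c1 = 80, lam1 = 5, mu1 = 10,
                 k2 = 100, c2 = 20, lam2 = 4, mu2 = 5, phi = 5e3),
      list(list(sizes = c(100, 200)), list(sizes = c(300, 50)),
           list(sizes = c(50, 400)), list(sizes = c(250, 250)),
           list(sizes = c(450, 20))),
      integrator_settings(t_max = 1000)),
    fig3a = function() scenario_spec(
      "fig3a", do.call(pm_memory_pool, c(list(M = 2), mem)),
      list(sizes = c(1e4, 2e3), interleukins = 1.25e5),
      integrator_settings(t_max = 1000),
      protocol = "events",
      events = list(activation_event("naive_activation", m_new_0 = 2e3)),
      turnover_params = mem),
    fig3b = function() scenario_spec(
      "fig3b", do.call(pm_memory_pool, c(list(M = 2), mem)),
      list(sizes = c(6e3, 4e3), interleukins = 1.25e5),
      integrator_settings(t_max = 1000),
      protocol = "events",
      events = list(activation_event("memory_reactivation",
                                     clone_id = "clone1", delta_m = 3e3)),
      turnover_params = mem),
    fig4 = function() scenario_spec(
      "fig4", do.call(pm_memory_pool, c(list(M = 2), mem)),
      list(sizes = c(6e3, 4e3), interleukins = 1.25e5),
      integrator_settings(t_max = 1000),
      protocol = "turnover_sweep", turnover_params = mem),
    fig5 = function() scenario_spec(
      "fig5",
      pm_two_compartment(k_m = 150, c_m = 80, lam_m1 = 10, lam_m2 = 5,
                         k_n = 100, c_n = 120, lam_n1 = 50, A = 10,
                         phi1 = 1e6, mu1 = 10, phi2 = 1e5, mu2 = 3),
      list(sizes = c(1e4, 1e4)),
      integrator_settings(t_max = 2000)))
}

#' Load a scenario preset or config file
#'
#' Presets `fig1a`, `fig1b`, `fig1c`, `fig2`, `fig3a`, `fig3b`, `fig4`
#' and `fig5` carry the published figure-caption parameter values (the
#' `fig1c` drop is applied at the reduced-production equilibrium, and the
#' last Fig. 5 constant is read as the IL-15 consumption rate `mu2 = 3`,
#' since `mu1 = 10` is listed separately). A path ending in `.yaml`/`.yml`
#' or `.json` is parsed as a config mapping with keys `name`, `model`
#' (see [model_from_config()]), `initial`, `settings`, `protocol`,
#' `drop_factor`, `seed`.
#'
#' @param x Preset name or config file path.
#' @return A `pm_scenario`.
#' @export
load_scenario <- function(x) {
  presets <- pm_presets()
  if (x %in% names(presets)) return(presets[[x]]())
  if (!file.exists(x)) {
    stop("unknown preset or missing file: '", x, "' (presets: ",
         paste(names(presets), collapse = ", "), ")")
  }
  cfg <- if (grepl("\\.ya?ml$", x, ignore.case = TRUE)) {
    yaml::read_yaml(x)
  } else if (grepl("\\.json$", x, ignore.case = TRUE)) {
    jsonlite::read_json(x, simplifyVector = FALSE)
  } else {
    stop("config file must end in .yaml, .yml or .json")
  }
  scenario_from_config(cfg)
}

scenario_from_config <- function(cfg) {
  if (is.null(cfg$name)) stop("scenario config is missing key 'name'")
  if (is.null(cfg$model)) stop("scenario config is missing key 'model'")
  if (is.null(cfg$initial)) stop("scenario config is missing key 'initial'")
  model <- model_from_config(cfg$model)
  st <- cfg$settings
  settings <- integrator_settings(
    rel_tol = st$rel_tol %||% 1e-9,
    abs_tol = st$abs_tol,
    t_max = st$t_max %||% 500,
    ss_tol = st$ss_tol,
    ss_window = st$ss_window %||% 10)
  scenario_spec(cfg$name, model, cfg$initial, settings,
                protocol = cfg$protocol %||% "integrate",
                drop_factor = cfg$drop_factor,
                seed = cfg$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a scenario to a config list / file
#'
#' @param spec A `pm_scenario`.
#' @param path Optional `.yaml`/`.json` output path.
#' @return The config list, invisibly when written.
#' @export
write_scenario <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "pm_scenario"))
  cfg <- list(
    name = spec$name,
    model = model_to_config(spec$model),
    initial = spec$initial,
    settings = list(rel_tol = spec$settings$rel_tol,
                    abs_tol = spec$settings$abs_tol,
                    t_max = spec$settings$t_max,
                    ss_tol = spec$settings$ss_tol,
                    ss_window = spec$settings$ss_window),
    protocol = spec$protocol)
  if (!is.null(spec$drop_factor)) cfg$drop_factor <- spec$drop_factor
  if (!is.null(spec$seed)) cfg$seed <- spec$seed
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  if (!is.null(path)) {
    if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      yaml::write_yaml(cfg, path)
    } else {
      jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }
    return(invisible(cfg))
  }
  cfg
}

#' Run a scenario and write its outputs
#'
#' Writes, as applicable: one tidy trajectory CSV per initial condition
#' (`trajectory.csv` or `trajectory_<i>.csv`), an equilibrium/stability
#' JSON (`equilibrium.json`), a turnover ledger CSV (`ledger.csv`), and
#' always a run manifest (`manifest.json`: scenario name, parameters,
#' seed, package version, convergence flags). Outputs are deterministic
#' given the spec and seed.
#'
#' @param spec A `pm_scenario` (or preset name / config path, passed to
#'   [load_scenario()]).
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the trajectories / ledger and the
#'   manifest.
#' @export
run_scenario <- function(spec, out_dir, quiet = FALSE) {
  if (is.character(spec)) spec <- load_scenario(spec)
  stopifnot(inherits(spec, "pm_scenario"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf("[%s] %s", spec$name,
                                                   paste0(...)))
  model <- spec$model
  results <- list()
  converged <- logical(0)

  if (spec$protocol == "events") {
    say("running event sequence (ode mode)")
    init <- initial_state(spec$initial[[1]], model)
    lg <- run_event_sequence(spec$turnover_params, spec$events,
                             initial_clones = init$sizes, mode = "ode",
                             settings = spec$settings)
    write_ledger_csv(lg, file.path(out_dir, "ledger.csv"))
    results$ledger <- lg
  } else if (spec$protocol == "turnover_sweep") {
    say("sweeping event size: closed form vs ODE relaxation")
    tp <- spec$turnover_params
    K <- tp$phi / tp$mu
    deltas <- K * c(0.05, 0.1, 0.2, 0.4, 0.8)
    init <- initial_state(spec$initial[[1]], model)
    rows <- lapply(deltas, function(d) {
      ev <- list(activation_event("naive_activation", m_new_0 = d))
      cf <- run_event_sequence(tp, ev, init$sizes, mode = "closed_form")
      od <- run_event_sequence(tp, ev, init$sizes, mode = "ode",
                               settings = spec$settings)
      shared <- intersect(names(cf$clones), names(od$clones))
      data.frame(delta = d,
                 max_rel_err = max(abs(cf$clones[shared] -
                                         od$clones[shared]) /
                                     od$clones[shared]))
    })
    sweep <- do.call(rbind, rows)
    utils::write.csv(sweep, file.path(out_dir, "turnover_sweep.csv"),
                     row.names = FALSE, quote = FALSE)
    results$sweep <- sweep
  } else {
    for (i in seq_along(spec$initial)) {
      st <- initial_state(spec$initial[[i]], model)
      if (spec$protocol == "drop_recovery") {
        say("equilibrating before the population drop")
        eq <- find_steady_state(model, st, spec$settings)
        st <- perturb(eq, d_sizes = -(1 - spec$drop_factor) * eq$sizes,
                      zero_velocities = TRUE)
      }
      tr <- tryCatch(integrate_pm(model, st, spec$settings),
                     pm_error = function(e) {
                       say("integration failed: ", conditionMessage(e))
                       stop(e)
                     })
      fname <- if (length(spec$initial) == 1L) "trajectory.csv"
               else sprintf("trajectory_%d.csv", i)
      write_trajectory_csv(tr, file.path(out_dir, fname))
      results[[paste0("trajectory_", i)]] <- tr
      converged <- c(converged, tr$converged)
      say(sprintf("initial condition %d: converged=%s", i, tr$converged))
    }
    if (model$model_id != "memory_pool" || length(model$populations)) {
      eq <- tryCatch(equilibrium(model), error = function(e) NULL)
      if (!is.null(eq)) {
        rep <- if (eq$feasible) tryCatch(stability(model, eq),
                                         error = function(e) NULL)
               else NULL
        equilibrium_json(eq, rep, file.path(out_dir, "equilibrium.json"))
      }
    }
  }

  manifest <- list(
    scenario = spec$name,
    protocol = spec$protocol,
    model = model_to_config(model),
    seed = spec$seed,
    package_version = as.character(utils::packageVersion("popmech")),
    converged = as.list(converged))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(results, list(manifest = manifest)))
}

#' Generate a synthetic fixture (event sequence or affinity profile)
#'
#' Stand-ins for infection histories and thymic output: event sizes and
#' affinities are drawn from a log-normal distribution (a fixture choice,
#' not an empirical claim) with reproducible seeding.
#'
#' @param kind `"event_sequence"` or `"affinity_profile"`.
#' @param n Number of events / clones (0 gives an empty, schema-valid
#'   table).
#' @param seed Integer seed.
#' @param meanlog,sdlog Log-normal parameters of the size/affinity draws.
#' @param reactivation_prob For event sequences: probability that an event
#'   is a reactivation of an existing clone rather than a new activation
#'   (reactivations before any clone exists are re-labelled activations).
#' @param path Optional CSV output path.
#' @return The fixture data frame (events: `order`, `kind`, `clone_id`,
#'   `size`; affinities: `clone_id`, `affinity`).
#' @export
generate_fixture <- function(kind = c("event_sequence", "affinity_profile"),
                             n, seed, meanlog = log(500), sdlog = 1,
                             reactivation_prob = 0.3, path = NULL) {
  kind <- match.arg(kind)
  stopifnot(n >= 0, sdlog >= 0, reactivation_prob >= 0,
            reactivation_prob <= 1)
  set.seed(seed)
  if (kind == "affinity_profile") {
    df <- data.frame(clone_id = if (n) paste0("clone", seq_len(n))
                                else character(0),
                     affinity = if (n) stats::rlnorm(n, meanlog, sdlog)
                                else numeric(0))
  } else {
    sizes <- if (n) stats::rlnorm(n, meanlog, sdlog) else numeric(0)
    is_react <- if (n) stats::runif(n) < reactivation_prob else logical(0)
    clone_id <- character(n)
    n_clones <- 0L
    for (i in seq_len(n)) {
      if (is_react[i] && n_clones > 0L) {
        clone_id[i] <- paste0("clone", sample.int(n_clones, 1))
      } else {
        is_react[i] <- FALSE
        n_clones <- n_clones + 1L
        clone_id[i] <- ""
      }
    }
    df <- data.frame(order = seq_len(n),
                     kind = ifelse(is_react, "memory_reactivation",
                                   "naive_activation"),
                     clone_id = clone_id, size = sizes)
  }
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  df
}
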