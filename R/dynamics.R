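# Constrained integration of the population-mechanics ODE systems.
# The smooth field is integrated piecewise with deSolve::lsodar; when a
# cell count or interleukin amount crosses zero the integration stops at
# the crossing, the variable is clamped at 0 (sizes also have their
# velocity zeroed) and, if no constant force pushes it back into the
# domain, frozen until its unconstrained derivative turns non-negative.

#' Integrator settings
#'
#' @param rel_tol Relative solver tolerance.
#' @param abs_tol Absolute solver tolerance; default `1e-9` times the
#'   model's capacity scale (resolved at integration time when `NULL`).
#' @param t_max Integration horizon.
#' @param ss_tol Steady-state threshold on the max-norm of the full
#'   derivative; default `1e-8` times the capacity scale.
#' @param ss_window Time window over which the derivative norm must stay
#'   below `ss_tol` for the trajectory to count as converged.
#' @param max_step Optional maximum solver step.
#' @param dt_out Output sampling interval; default `ss_window / 4`.
#' @return An object of class `pm_integrator_settings`.
#' @export
integrator_settings <- function(rel_tol = 1e-9, abs_tol = NULL, t_max = 500,
                                ss_tol = NULL, ss_window = 10,
                                max_step = NULL, dt_out = NULL) {
  stopifnot(rel_tol > 0, t_max > 0, ss_window > 0)
  if (!is.null(abs_tol)) stopifnot(abs_tol > 0)
  if (!is.null(ss_tol)) stopifnot(ss_tol > 0)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol, t_max = t_max,
                 ss_tol = ss_tol, ss_window = ss_window,
                 max_step = max_step, dt_out = dt_out),
            class = "pm_integrator_settings")
}

resolve_settings <- function(settings, model, initial) {
  scale <- pm_scale(model, initial)
  if (is.null(settings$abs_tol)) settings$abs_tol <- 1e-9 * scale
  if (is.null(settings$ss_tol)) settings$ss_tol <- 1e-8 * scale
  if (is.null(settings$dt_out)) {
    settings$dt_out <- max(settings$ss_window / 4, settings$t_max / 2000)
  }
  settings$scale <- scale
  settings
}

pm_condition <- function(class, message, ...) {
  structure(class = c(class, "pm_error", "error", "condition"),
            list(message = message, call = sys.call(-1), ...))
}

#' Integrate a model, enforcing non-negativity of cells and interleukins
#'
#' Solves the model's ODE system from `initial` up to `settings$t_max` or
#' until a steady state is detected (max-norm of the full derivative below
#' `ss_tol` over a window of length `ss_window`). Zero crossings of cell
#' counts or interleukin amounts are located by root finding; the crossing
#' variable is clamped at 0 (for a cell count, its velocity too) and held
#' there while its unconstrained derivative points out of the domain. Every
#' clamp and release is recorded in `constraint_events`.
#'
#' @param model A `pm_model`.
#' @param initial Initial [system_state()] (velocities default to 0).
#' @param settings An [integrator_settings()].
#' @return An object of class `pm_trajectory`: a list with `times`, a
#'   `states` matrix (one named column per flat-state variable),
#'   `converged`, `convergence_time`, `constraint_events` (data frame with
#'   columns `time`, `variable`, `kind`), the `model` and the resolved
#'   `settings`.
#' @export
integrate_pm <- function(model, initial, settings = integrator_settings()) {
  stopifnot(inherits(model, "pm_model"), inherits(initial, "pm_state"),
            inherits(settings, "pm_integrator_settings"))
  settings <- resolve_settings(settings, model, initial)
  lay <- model_layout(model)
  field <- build_vector_field(model)
  y <- flatten_state(initial, model)
  nvar <- length(y)
  # indices subject to the non-negativity constraint
  constrained <- c(lay$idx_sizes, lay$idx_il)
  vel_of <- integer(nvar)                      # size index -> velocity index
  if (lay$n_vel) vel_of[lay$idx_sizes] <- lay$idx_vel

  frozen <- rep(FALSE, nvar)
  events <- list()
  root_eps <- 1e-12 * settings$scale

  # effective (constrained) field: frozen variables do not move
  eff_field <- function(t, y) {
    dy <- field(t, y)
    if (any(frozen)) {
      dy[frozen] <- 0
      fs <- frozen[lay$idx_sizes]
      if (lay$n_vel && any(fs)) dy[lay$idx_vel[fs]] <- 0
    }
    dy
  }
  func <- function(t, y, parms) list(unname(eff_field(t, y)))

  # Sizes whose boundary acceleration can vary in time and therefore need
  # release monitoring when frozen. For partitioned models a clone at 0
  # receives no interleukin share, so its boundary acceleration is the
  # constant antigenic force A_i; only the single population (whole force
  # lambda*h) and the memory compartment of the two-compartment model
  # (IL-15 term without partition) feel a time-varying force at 0.
  release_dynamic <- rep(FALSE, nvar)
  if (model$model_id == "single") release_dynamic[lay$idx_sizes] <- TRUE
  if (model$model_id == "two_compartment") release_dynamic[1] <- TRUE

  log_event <- function(t, i, kind) {
    events[[length(events) + 1L]] <<-
      data.frame(time = t, variable = lay$names[i], kind = kind)
  }

  # clamp a size (or interleukin) sitting at the boundary; freeze it when
  # the unconstrained field still points out of the domain
  clamp_var <- function(t, i) {
    y[i] <<- 0
    if (i %in% lay$idx_sizes && lay$n_vel) {
      y[vel_of[i]] <<- 0
      accel <- field(t, y)[vel_of[i]]
      if (accel <= 0 && !frozen[i]) {
        frozen[i] <<- TRUE
        log_event(t, i, "clamped_at_zero")
      }
    } else {
      # first-order variable (interleukin, or Lotka-Volterra size)
      if (field(t, y)[i] <= 0 && !frozen[i]) {
        frozen[i] <<- TRUE
        log_event(t, i, "clamped_at_zero")
      }
    }
  }

  # clamp/freeze every constrained variable at (or just past) the
  # boundary with an inward push, and release frozen variables whose
  # unconstrained derivative has turned non-negative
  boundary_sweep <- function(t, hit_tol) {
    dyu <- field(t, y)
    for (i in constrained) {
      if (frozen[i]) {
        ok <- if (i %in% lay$idx_il) dyu[i] >= 0
              else release_dynamic[i] && dyu[vel_of[i]] > 0
        if (ok) {
          frozen[i] <<- FALSE
          log_event(t, i, "released")
        }
      } else if (y[i] <= hit_tol) {
        # clamp only when at/below zero or still moving inward; a small
        # but growing variable is left untouched
        inward <- if (i %in% lay$idx_sizes && lay$n_vel) {
          y[vel_of[i]] <= 0
        } else {
          dyu[i] <= 0
        }
        if (y[i] < 0 || inward) clamp_var(t, i)
      }
    }
  }
  boundary_sweep(initial$t, root_eps)

  times_out <- initial$t
  states_out <- matrix(y, nrow = 1, dimnames = list(NULL, lay$names))
  t_cur <- initial$t
  t_stop <- initial$t + settings$t_max
  converged <- FALSE
  convergence_time <- NA_real_

  chunk_len <- max(settings$ss_window, settings$t_max / 25)

  deriv_norm <- function(t, y) max(abs(eff_field(t, y)))

  hit_tol <- 1e-8 * settings$scale

  while (t_cur < t_stop - 1e-12 && !converged) {
    t_end <- min(t_cur + chunk_len, t_stop)
    stalls <- 0L
    # integrate this chunk, restarting at every constraint event
    while (t_cur < t_end - 1e-12) {
      # value roots for active constrained variables off the boundary;
      # release roots (unconstrained derivative) for frozen variables
      watch <- constrained[!frozen[constrained] &
                             y[constrained] > root_eps]
      frozen_il <- lay$idx_il[frozen[lay$idx_il]]
      frozen_rel <- lay$idx_sizes[frozen[lay$idx_sizes] &
                                    release_dynamic[lay$idx_sizes]]
      n_watch <- length(watch)
      rootfunc <- if (n_watch + length(frozen_il) + length(frozen_rel) >
                        0) {
        function(t, y, parms) {
          g <- numeric(0)
          if (n_watch) g <- unname(y[watch])
          if (length(frozen_il) || length(frozen_rel)) {
            dyu <- field(t, y)
            if (length(frozen_il)) g <- c(g, unname(dyu[frozen_il]))
            if (length(frozen_rel)) {
              g <- c(g, unname(dyu[vel_of[frozen_rel]]))
            }
          }
          g
        }
      } else NULL

      times <- seq(t_cur, t_end, by = settings$dt_out)
      if (times[length(times)] < t_end - 1e-12) times <- c(times, t_end)
      if (length(times) < 2L) times <- c(t_cur, t_end)

      out <- tryCatch(
        deSolve::lsodar(y = y, times = times, func = func, parms = NULL,
                        rtol = settings$rel_tol, atol = settings$abs_tol,
                        rootfunc = rootfunc, maxsteps = 100000,
                        hmax = settings$max_step),
        error = function(e) {
          stop(pm_condition("pm_integration_failure",
                            paste0("ODE solver failed: ",
                                   conditionMessage(e)),
                            last_state = unflatten_state(y, model, t_cur)))
        })
      if (any(!is.finite(out[, -1]))) {
        stop(pm_condition("pm_nonfinite_state",
                          "non-finite state encountered during integration",
                          last_state = unflatten_state(y, model, t_cur)))
      }
      nr <- nrow(out)
      troot <- attr(out, "troot")
      if (nr > 1L) {
        keep <- which(out[2:nr, 1] > times_out[length(times_out)] + 1e-12)
        if (length(keep)) {
          new_t <- out[1 + keep, 1]
          new_y <- out[1 + keep, -1, drop = FALSE]
          # absorb root-location noise just below zero
          low <- new_y[, constrained, drop = FALSE]
          low[low < 0] <- 0
          new_y[, constrained] <- low
          times_out <- c(times_out, new_t)
          states_out <- rbind(states_out, new_y)
        }
        t_new <- out[nr, 1]
        y <- stats::setNames(out[nr, -1], lay$names)
        stalls <- if (t_new > t_cur + 1e-12) 0L else stalls + 1L
        t_cur <- t_new
      } else {
        stalls <- stalls + 1L
      }
      if (!is.null(troot) && length(troot) > 0) {
        # lsodar stopped at a constraint event: clamp whichever watched
        # variable reached zero, release whichever frozen variable is
        # being pushed back into the domain
        boundary_sweep(t_cur, hit_tol)
        y[constrained][y[constrained] < 0] <- 0
        states_out[nrow(states_out), ] <- y
      } else {
        t_cur <- t_end
        break
      }
      if (stalls > 10L) {
        stop(pm_condition("pm_integration_failure",
                          "integration stalled at a constraint boundary",
                          last_state = unflatten_state(y, model, t_cur)))
      }
    }
    # convergence check over the trailing window
    tail_from <- t_cur - settings$ss_window
    if (tail_from >= times_out[1]) {
      idx <- which(times_out >= tail_from - 1e-9)
      ok <- TRUE
      for (ii in idx) {
        if (deriv_norm(times_out[ii],
                       stats::setNames(states_out[ii, ], lay$names)) >=
            settings$ss_tol) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        converged <- TRUE
        convergence_time <- times_out[idx[1]]
      }
    }
  }

  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(time = numeric(0), variable = character(0),
               kind = character(0))
  structure(list(times = times_out, states = states_out,
                 converged = converged, convergence_time = convergence_time,
                 constraint_events = ev, model = model,
                 settings = settings),
            class = "pm_trajectory")
}

#' @export
print.pm_trajectory <- function(x, ...) {
  cat("<pm_trajectory>", x$model$model_id, "|",
      length(x$times), "points over t in [",
      format(x$times[1]), ",", format(x$times[length(x$times)]), "]\n")
  cat("  converged:", x$converged,
      if (x$converged) paste0("(t = ", signif(x$convergence_time, 6), ")"),
      "\n")
  if (nrow(x$constraint_events)) {
    cat("  constraint events:", nrow(x$constraint_events), "\n")
  }
  invisible(x)
}

#' Final state of a trajectory
#' @param trajectory A `pm_trajectory`.
#' @return A [system_state()].
#' @export
final_state <- function(trajectory) {
  stopifnot(inherits(trajectory, "pm_trajectory"))
  n <- nrow(trajectory$states)
  unflatten_state(trajectory$states[n, ], trajectory$model,
                  t = trajectory$times[n])
}

#' Tidy data frame view of a trajectory
#'
#' @param x A `pm_trajectory`.
#' @param row.names,optional,... Ignored (data frame method signature).
#' @return A long data frame with columns `t`, `variable`, `value`,
#'   variables ordered as in the flat state layout.
#' @export
as.data.frame.pm_trajectory <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  nm <- colnames(x$states)
  data.frame(
    t = rep(x$times, times = length(nm)),
    variable = factor(rep(nm, each = length(x$times)), levels = nm),
    value = as.vector(x$states))
}

#' Integrate to a steady state
#'
#' Numerical oracle for the closed-form equilibria: integrates until the
#' steady-state criterion holds and returns the final state.
#'
#' @inheritParams integrate_pm
#' @return The converged final [system_state()].
#' @export
find_steady_state <- function(model, initial,
                              settings = integrator_settings()) {
  tr <- integrate_pm(model, initial, settings)
  if (!tr$converged) {
    stop(pm_condition("pm_nonconvergence",
                      sprintf("no steady state within t_max = %g",
                              tr$settings$t_max),
                      last_state = final_state(tr)))
  }
  final_state(tr)
}

#' Shift a state by additive perturbations
#'
#' Used to realize discrete events (clone activations, population drops) on
#' an equilibrated state.
#'
#' @param state A [system_state()].
#' @param d_sizes Additive change per population (recycled scalar allowed).
#' @param d_interleukins Additive change per interleukin.
#' @param new_clones Sizes of clones appended to the state (entering with
#'   zero velocity); the model must be grown accordingly by the caller.
#' @param zero_velocities If `TRUE`, reset all velocities to 0.
#' @return The perturbed [system_state()] (time preserved).
#' @export
perturb <- function(state, d_sizes = 0, d_interleukins = 0,
                    new_clones = numeric(0), zero_velocities = FALSE) {
  stopifnot(inherits(state, "pm_state"))
  sizes <- state$sizes + d_sizes
  if (any(sizes < 0)) {
    stop("perturbation would drive a population size below 0")
  }
  il <- state$interleukins
  if (length(il)) {
    il <- il + d_interleukins
    if (any(il < 0)) stop("perturbation would drive an interleukin below 0")
  } else if (any(d_interleukins != 0)) {
    stop("model has no interleukins to perturb")
  }
  vel <- state$velocities
  if (length(new_clones)) {
    if (any(new_clones < 0)) stop("new clone sizes must be non-negative")
    sizes <- c(sizes, new_clones)
    if (length(vel)) vel <- c(vel, rep(0, length(new_clones)))
  }
  if (zero_velocities && length(vel)) vel <- rep(0, length(vel))
  system_state(sizes = sizes, velocities = vel, interleukins = il,
               t = state$t)
}

#' Write a trajectory as tidy CSV
#'
#' Columns `t`, `variable`, `value`; deterministic variable order (the flat
#' state layout).
#'
#' @param trajectory A `pm_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  df <- as.data.frame(trajectory)
  df$variable <- as.character(df$variable)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' JSON summary of a trajectory
#'
#' @param trajectory A `pm_trajectory`.
#' @param path Optional file to write to.
#' @return The summary list (convergence flag and time, final state),
#'   invisibly when writing.
#' @export
trajectory_summary <- function(trajectory, path = NULL) {
  fs <- final_state(trajectory)
  s <- list(model_id = trajectory$model$model_id,
            converged = trajectory$converged,
            convergence_time = if (trajectory$converged)
              trajectory$convergence_time else NULL,
            t_final = fs$t,
            final_state = list(sizes = fs$sizes,
                               velocities = fs$velocities,
                               interleukins = fs$interleukins),
            constraint_events = trajectory$constraint_events)
  if (!is.null(path)) {
    jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(s))
  }
  s
}
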