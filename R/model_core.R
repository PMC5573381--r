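# Domain types and right-hand-side vector fields for the population
# mechanics models: cell populations treated as damped elastic systems
# driven by interleukin "forces", written as first-order systems with
# state layout [sizes, velocities, interleukins].

#' Mechanical parameters of one cell population (or clone)
#'
#' A population of cells is modelled as a damped elastic system: `k` is the
#' elastic constant (restoring force per cell), `c` the damping coefficient
#' (force per unit rate of change), `lam` the homeostatic force exerted on
#' the population per unit of interleukin, and `mu` the rate at which one
#' cell consumes the interleukin.
#'
#' @param k Elastic constant, `> 0`.
#' @param c Damping coefficient, `> 0`.
#' @param lam Homeostatic force per unit interleukin, `> 0`.
#' @param mu Interleukin consumption rate per cell, `>= 0` (`0` only for
#'   populations that do not consume the interleukin).
#' @return An object of class `pm_clone_params`.
#' @export
clone_params <- function(k, c, lam, mu) {
  stopifnot(is.numeric(k), is.numeric(c), is.numeric(lam), is.numeric(mu),
            length(k) == 1L, length(c) == 1L, length(lam) == 1L,
            length(mu) == 1L)
  if (!(k > 0 && c > 0 && lam > 0 && mu >= 0)) {
    stop("clone_params requires k > 0, c > 0, lam > 0, mu >= 0")
  }
  structure(list(k = k, c = c, lam = lam, mu = mu),
            class = "pm_clone_params")
}

#' Interleukin source parameters
#'
#' @param phi Constant interleukin production rate, `>= 0`.
#' @return An object of class `pm_interleukin_params`.
#' @export
interleukin_params <- function(phi) {
  stopifnot(is.numeric(phi), length(phi) == 1L, phi >= 0)
  structure(list(phi = phi), class = "pm_interleukin_params")
}

#' Per-clone constant antigenic forces
#'
#' Naive T cell clones perceive a constant antigenic force `A[i]`,
#' proportional to the affinity of their TCR for antigens presented by
#' dendritic cells in the lymph nodes.
#'
#' @param A Numeric vector of per-clone antigenic forces, all `>= 0`.
#' @return An object of class `pm_affinity_profile` with fields `A` and
#'   `A_sum`.
#' @export
affinity_profile <- function(A) {
  A <- as.numeric(A)
  if (length(A) < 1L || any(!is.finite(A)) || any(A < 0)) {
    stop("affinity_profile requires a non-empty vector of finite A_i >= 0")
  }
  structure(list(A = A, A_sum = sum(A)), class = "pm_affinity_profile")
}

#' System state at one time point
#'
#' @param sizes Per-population cell counts (continuous), all `>= 0`.
#' @param velocities Per-population rates of change; defaults to zeros.
#'   Length 0 is allowed for first-order models (Lotka-Volterra).
#' @param interleukins Interleukin amounts, all `>= 0` (length 0, 1 or 2
#'   depending on the model).
#' @param t Time, default 0.
#' @return An object of class `pm_state`.
#' @export
system_state <- function(sizes, velocities = NULL, interleukins = numeric(0),
                         t = 0) {
  sizes <- as.numeric(sizes)
  interleukins <- as.numeric(interleukins)
  if (is.null(velocities)) velocities <- rep(0, length(sizes))
  velocities <- as.numeric(velocities)
  if (any(!is.finite(c(sizes, velocities, interleukins, t)))) {
    stop("system_state components must be finite")
  }
  if (any(sizes < 0)) stop("sizes must be non-negative")
  if (any(interleukins < 0)) stop("interleukin amounts must be non-negative")
  if (!(length(velocities) %in% c(0L, length(sizes)))) {
    stop("velocities must have length 0 or length(sizes)")
  }
  structure(list(t = t, sizes = sizes, velocities = velocities,
                 interleukins = interleukins),
            class = "pm_state")
}

#' @export
print.pm_state <- function(x, ...) {
  cat("<pm_state> t =", format(x$t), "\n")
  cat("  sizes:       ", paste(signif(x$sizes, 6), collapse = " "), "\n")
  if (length(x$velocities)) {
    cat("  velocities:  ", paste(signif(x$velocities, 6), collapse = " "), "\n")
  }
  if (length(x$interleukins)) {
    cat("  interleukins:", paste(signif(x$interleukins, 6), collapse = " "), "\n")
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Model constructors. Every model is a list with class
# c("pm_model_<id>", "pm_model") and fields:
#   model_id, populations (list of pm_clone_params), interleukins (list of
#   pm_interleukin_params), affinities (pm_affinity_profile or NULL),
#   lv (list or NULL), tc (two-compartment constants or NULL).

new_pm_model <- function(model_id, populations = list(),
                         interleukins = list(), affinities = NULL,
                         lv = NULL, tc = NULL) {
  structure(list(model_id = model_id, populations = populations,
                 interleukins = interleukins, affinities = affinities,
                 lv = lv, tc = tc),
            class = c(paste0("pm_model_", model_id), "pm_model"))
}

#' Single population controlled by one interleukin
#'
#' The inertial model of one cell population `x` whose proliferation is
#' driven by a homeostatic interleukin `h`:
#' \deqn{x'' = -k x - c x' + \lambda h, \qquad h' = \phi - \mu x,}
#' for \eqn{x \ge 0}, \eqn{h \ge 0}. The carrying capacity
#' \eqn{K = \phi/\mu} is emergent, not a parameter.
#'
#' @param k,c,lam,mu Population constants, see [clone_params()].
#' @param phi Interleukin production rate.
#' @return A `pm_model` object with `model_id = "single"`.
#' @export
pm_single <- function(k, c, lam, phi, mu) {
  new_pm_model("single",
               populations = list(clone_params(k, c, lam, mu)),
               interleukins = list(interleukin_params(phi)))
}

#' Two populations competing for one interleukin
#'
#' Each population receives the share `x_i / (x_1 + x_2)` of the
#' homeostatic force:
#' \deqn{x_i'' = -c_i x_i' - k_i x_i + \lambda_i \frac{x_i}{x_1+x_2} h,
#'       \qquad h' = \phi - \mu_1 x_1 - \mu_2 x_2.}
#'
#' @param k1,c1,lam1,mu1 Constants of population 1.
#' @param k2,c2,lam2,mu2 Constants of population 2.
#' @param phi Interleukin production rate.
#' @return A `pm_model` object with `model_id = "two_pop"`.
#' @export
pm_two_pop <- function(k1, c1, lam1, mu1, k2, c2, lam2, mu2, phi) {
  new_pm_model("two_pop",
               populations = list(clone_params(k1, c1, lam1, mu1),
                                  clone_params(k2, c2, lam2, mu2)),
               interleukins = list(interleukin_params(phi)))
}

#' Memory pool: M clones with shared parameters and one interleukin
#'
#' All memory clones share `(k, c, lam, mu)` (clones are assumed not to
#' differ in their ability to compete for interleukins); each receives the
#' share `m_i / sum(m_j)` of the homeostatic force.
#'
#' @param M Number of clones, `>= 0`.
#' @inheritParams pm_single
#' @return A `pm_model` object with `model_id = "memory_pool"`.
#' @export
pm_memory_pool <- function(M, k, c, lam, phi, mu) {
  stopifnot(is.numeric(M), length(M) == 1L, M >= 0, M == round(M))
  pops <- rep(list(clone_params(k, c, lam, mu)), M)
  new_pm_model("memory_pool", populations = pops,
               interleukins = list(interleukin_params(phi)))
}

#' Naive pool: N clones under antigenic forcing
#'
#' As [pm_memory_pool()] but with an additional constant antigenic force
#' `A_i` acting on each clone (affinity of the clone's TCR for its cognate
#' antigens).
#'
#' @param A Numeric vector of per-clone antigenic forces (its length sets
#'   the number of clones), or a [affinity_profile()].
#' @inheritParams pm_single
#' @return A `pm_model` object with `model_id = "naive_pool"`.
#' @export
pm_naive_pool <- function(k, c, lam, phi, mu, A) {
  if (!inherits(A, "pm_affinity_profile")) A <- affinity_profile(A)
  pops <- rep(list(clone_params(k, c, lam, mu)), length(A$A))
  new_pm_model("naive_pool", populations = pops,
               interleukins = list(interleukin_params(phi)),
               affinities = A)
}

#' Naive and memory compartments competing for IL-7 and IL-15
#'
#' Memory cells `m` are driven by IL-7 (`h1`, shared with naive cells in
#' proportion to population size) and by IL-15 (`h2`, which only they
#' consume); naive cells `n` are driven by their IL-7 share plus the total
#' antigenic force `A`:
#' \deqn{m'' = -c_m m' - k_m m + \lambda_{m1}\frac{m}{m+n} h_1 + \lambda_{m2} h_2}
#' \deqn{n'' = -c_n n' - k_n n + \lambda_{n1}\frac{n}{m+n} h_1 + A}
#' \deqn{h_1' = \phi_1 - \mu_1 (m+n), \qquad h_2' = \phi_2 - \mu_2 m.}
#'
#' @param k_m,c_m Elastic/damping constants of the memory population.
#' @param lam_m1,lam_m2 Force on memory cells per unit IL-7 and IL-15.
#' @param k_n,c_n Elastic/damping constants of the naive population.
#' @param lam_n1 Force on naive cells per unit IL-7.
#' @param A Total constant antigenic force on the naive population.
#' @param phi1,mu1 IL-7 production rate and per-cell consumption rate.
#' @param phi2,mu2 IL-15 production rate and per-memory-cell consumption
#'   rate.
#' @return A `pm_model` object with `model_id = "two_compartment"`.
#' @export
pm_two_compartment <- function(k_m, c_m, lam_m1, lam_m2,
                               k_n, c_n, lam_n1, A,
                               phi1, mu1, phi2, mu2) {
  vals <- c(k_m = k_m, c_m = c_m, lam_m1 = lam_m1, lam_m2 = lam_m2,
            k_n = k_n, c_n = c_n, lam_n1 = lam_n1, A = A,
            phi1 = phi1, mu1 = mu1, phi2 = phi2, mu2 = mu2)
  if (any(!is.finite(vals))) stop("two_compartment constants must be finite")
  pos <- c("k_m", "c_m", "lam_m1", "lam_m2", "k_n", "c_n", "lam_n1",
           "phi1", "mu1", "phi2", "mu2")
  if (any(vals[pos] <= 0) || vals["A"] < 0) {
    stop("two_compartment constants must be positive (A >= 0)")
  }
  new_pm_model("two_compartment",
               populations = list(
                 clone_params(k_m, c_m, lam_m1, mu1),
                 clone_params(k_n, c_n, lam_n1, mu1)),
               interleukins = list(interleukin_params(phi1),
                                   interleukin_params(phi2)),
               tc = as.list(vals))
}

#' Classical Lotka-Volterra competition model
#'
#' The contrast class: two logistic populations with fixed carrying
#' capacities `K1`, `K2` and competition coefficients `alpha12`, `alpha21`:
#' \deqn{x_1' = r_1 x_1 (1 - (x_1 + \alpha_{12} x_2)/K_1)}
#' \deqn{x_2' = r_2 x_2 (1 - (x_2 + \alpha_{21} x_1)/K_2).}
#'
#' @param r1,r2 Intrinsic growth rates, `> 0`.
#' @param K1,K2 Carrying capacities (parameters here, unlike the
#'   population-mechanics models where capacity is emergent), `> 0`.
#' @param alpha12,alpha21 Competition coefficients, `> 0`.
#' @return A `pm_model` object with `model_id = "lotka_volterra"`.
#' @export
pm_lotka_volterra <- function(r1, r2, K1, K2, alpha12, alpha21) {
  vals <- c(r1 = r1, r2 = r2, K1 = K1, K2 = K2,
            alpha12 = alpha12, alpha21 = alpha21)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("Lotka-Volterra constants must be finite and positive")
  }
  new_pm_model("lotka_volterra", lv = as.list(vals))
}

#' @export
print.pm_model <- function(x, ...) {
  cat("<pm_model>", x$model_id, "\n")
  cat("  populations:", length(x$populations),
      " interleukins:", length(x$interleukins), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# State layout

#' State layout of a model
#'
#' The flat state vector used throughout the package is laid out as
#' `[sizes, velocities, interleukins]`, making Jacobian indexing
#' unambiguous. First-order models (Lotka-Volterra) have no velocity block.
#'
#' @param model A `pm_model`.
#' @return A list with the number of populations (`n_pop`), velocity block
#'   length (`n_vel`), interleukin count (`n_il`), index vectors
#'   (`idx_sizes`, `idx_vel`, `idx_il`) and flat-variable `names`.
#' @export
model_layout <- function(model) {
  stopifnot(inherits(model, "pm_model"))
  id <- model$model_id
  if (id == "lotka_volterra") {
    n_pop <- 2L; n_vel <- 0L; n_il <- 0L
    pop_names <- c("x1", "x2")
    il_names <- character(0)
  } else {
    n_pop <- length(model$populations)
    n_vel <- n_pop
    n_il <- length(model$interleukins)
    pop_names <- switch(id,
      single = "x",
      two_pop = c("x1", "x2"),
      memory_pool = if (n_pop) paste0("m", seq_len(n_pop)) else character(0),
      naive_pool = if (n_pop) paste0("n", seq_len(n_pop)) else character(0),
      two_compartment = c("m", "n"),
      stop("unknown model_id: ", id))
    il_names <- if (n_il == 1L) "h" else if (n_il == 2L) c("h1", "h2")
                else character(0)
  }
  idx_sizes <- seq_len(n_pop)
  idx_vel <- if (n_vel) n_pop + seq_len(n_vel) else integer(0)
  idx_il <- if (n_il) n_pop + n_vel + seq_len(n_il) else integer(0)
  list(n_pop = n_pop, n_vel = n_vel, n_il = n_il,
       idx_sizes = idx_sizes, idx_vel = idx_vel, idx_il = idx_il,
       names = c(pop_names,
                 if (n_vel) paste0("v_", pop_names) else character(0),
                 il_names))
}

#' Flatten a system state to the model's flat vector (and back)
#'
#' @param state A [system_state()].
#' @param model The `pm_model` the state belongs to.
#' @return `flatten_state` returns a named numeric vector laid out as
#'   `[sizes, velocities, interleukins]`; `unflatten_state` inverts it.
#' @export
flatten_state <- function(state, model) {
  stopifnot(inherits(state, "pm_state"))
  lay <- model_layout(model)
  if (length(state$sizes) != lay$n_pop) {
    stop("state has ", length(state$sizes), " sizes; model expects ",
         lay$n_pop)
  }
  vel <- state$velocities
  if (lay$n_vel == 0L) {
    vel <- numeric(0)
  } else if (length(vel) == 0L) {
    vel <- rep(0, lay$n_vel)
  }
  if (length(vel) != lay$n_vel) stop("velocity block length mismatch")
  if (length(state$interleukins) != lay$n_il) {
    stop("state has ", length(state$interleukins),
         " interleukins; model expects ", lay$n_il)
  }
  stats::setNames(c(state$sizes, vel, state$interleukins), lay$names)
}

#' @rdname flatten_state
#' @param y Flat numeric state vector.
#' @param t Time to stamp on the rebuilt state.
#' @export
unflatten_state <- function(y, model, t = 0) {
  lay <- model_layout(model)
  if (length(y) != lay$n_pop + lay$n_vel + lay$n_il) {
    stop("flat state has length ", length(y), "; model expects ",
         lay$n_pop + lay$n_vel + lay$n_il)
  }
  system_state(sizes = unname(y[lay$idx_sizes]),
               velocities = unname(y[lay$idx_vel]),
               interleukins = unname(y[lay$idx_il]),
               t = t)
}

# ---------------------------------------------------------------------------
# Vector fields

# Per-population constant force (antigenic stimulation); zero except for
# naive clones and the naive compartment of the two-compartment model.
const_forces <- function(model) {
  lay <- model_layout(model)
  A <- rep(0, lay$n_pop)
  if (model$model_id == "naive_pool") A <- model$affinities$A
  if (model$model_id == "two_compartment") A[2] <- model$tc$A
  A
}

#' Build the right-hand-side vector field of a model
#'
#' Returns the first-order vector field `f(t, y)` of the model, with each
#' second-order population equation rewritten as `x' = v`,
#' `v' = -c v - k x + force terms`, over the flat layout
#' `[sizes, velocities, interleukins]`. The interleukin share
#' `x_i / sum(x_j)` is defined as 0 for every population when the total is
#' 0 (an empty pool receives no homeostatic force).
#'
#' @param model A `pm_model`.
#' @return A function `(t, y) -> dy` returning the named derivative vector.
#' @export
build_vector_field <- function(model) {
  stopifnot(inherits(model, "pm_model"))
  lay <- model_layout(model)
  id <- model$model_id

  if (id == "lotka_volterra") {
    p <- model$lv
    return(function(t, y) {
      x1 <- y[1]; x2 <- y[2]
      c(x1 = p$r1 * x1 * (1 - (x1 + p$alpha12 * x2) / p$K1),
        x2 = p$r2 * x2 * (1 - (x2 + p$alpha21 * x1) / p$K2))
    })
  }

  if (id == "two_compartment") {
    p <- model$tc
    return(function(t, y) {
      m <- y[1]; n <- y[2]; vm <- y[3]; vn <- y[4]
      h1 <- y[5]; h2 <- y[6]
      S <- m + n
      fm <- if (S > 0) m / S else 0
      fn <- if (S > 0) n / S else 0
      c(m = vm, n = vn,
        v_m = -p$c_m * vm - p$k_m * m + p$lam_m1 * fm * h1 + p$lam_m2 * h2,
        v_n = -p$c_n * vn - p$k_n * n + p$lam_n1 * fn * h1 + p$A,
        h1 = p$phi1 - p$mu1 * S,
        h2 = p$phi2 - p$mu2 * m)
    })
  }

  # shared-interleukin second-order models: single, two_pop, memory_pool,
  # naive_pool. The single-population model has no partition factor (the
  # whole force lambda*h acts on the population).
  np <- lay$n_pop
  if (np == 0L) stop("model has no populations")
  k <- vapply(model$populations, `[[`, numeric(1), "k")
  cc <- vapply(model$populations, `[[`, numeric(1), "c")
  lam <- vapply(model$populations, `[[`, numeric(1), "lam")
  mu <- vapply(model$populations, `[[`, numeric(1), "mu")
  phi <- model$interleukins[[1]]$phi
  A <- const_forces(model)
  partition <- id != "single"
  nm <- lay$names

  function(t, y) {
    x <- y[seq_len(np)]
    v <- y[np + seq_len(np)]
    h <- y[2L * np + 1L]
    if (partition) {
      S <- sum(x)
      frac <- if (S > 0) x / S else rep(0, np)
    } else {
      frac <- 1
    }
    dv <- -cc * v - k * x + lam * frac * h + A
    stats::setNames(c(v, dv, phi - sum(mu * x)), nm)
  }
}

# ---------------------------------------------------------------------------
# Config (de)serialization

#' Serialize a model to a plain config list / rebuild it from one
#'
#' The config mapping (used for YAML/JSON scenario files) has keys
#' `model_id`, `populations` (list of `{k, c, lam, mu}`), `interleukins`
#' (list of `{phi}`), `affinities` (numeric list), `lv`
#' (`{r1, r2, K1, K2, alpha12, alpha21}`) and, for the two-compartment
#' model, `constants` with its named parameter block.
#'
#' @param model A `pm_model`.
#' @return `model_to_config` returns a plain list; `model_from_config`
#'   returns the rebuilt `pm_model`.
#' @export
model_to_config <- function(model) {
  stopifnot(inherits(model, "pm_model"))
  cfg <- list(model_id = model$model_id)
  if (model$model_id == "lotka_volterra") {
    cfg$lv <- model$lv
    return(cfg)
  }
  if (model$model_id == "two_compartment") {
    cfg$constants <- model$tc
    return(cfg)
  }
  cfg$populations <- lapply(model$populations, function(p) {
    list(k = p$k, c = p$c, lam = p$lam, mu = p$mu)
  })
  cfg$interleukins <- lapply(model$interleukins, function(h) list(phi = h$phi))
  if (!is.null(model$affinities)) {
    cfg$affinities <- as.list(model$affinities$A)
  }
  cfg
}

#' @rdname model_to_config
#' @param config A list as produced by `model_to_config` (or parsed from a
#'   YAML/JSON scenario file).
#' @export
model_from_config <- function(config) {
  id <- config$model_id
  if (is.null(id)) stop("config is missing key 'model_id'")
  if (id == "lotka_volterra") {
    lv <- config$lv
    need <- c("r1", "r2", "K1", "K2", "alpha12", "alpha21")
    miss <- setdiff(need, names(lv))
    if (length(miss)) stop("config key 'lv' is missing: ",
                           paste(miss, collapse = ", "))
    return(do.call(pm_lotka_volterra, lv[need]))
  }
  if (id == "two_compartment") {
    cst <- config$constants
    need <- c("k_m", "c_m", "lam_m1", "lam_m2", "k_n", "c_n", "lam_n1",
              "A", "phi1", "mu1", "phi2", "mu2")
    miss <- setdiff(need, names(cst))
    if (length(miss)) stop("config key 'constants' is missing: ",
                           paste(miss, collapse = ", "))
    return(do.call(pm_two_compartment, cst[need]))
  }
  pops <- config$populations
  ils <- config$interleukins
  if (is.null(pops) || (id != "memory_pool" && length(pops) == 0L)) {
    stop("config is missing key 'populations'")
  }
  if (is.null(ils) || length(ils) != 1L) {
    stop("config key 'interleukins' must list exactly one interleukin for ",
         "model '", id, "'")
  }
  getp <- function(i, f) {
    v <- pops[[i]][[f]]
    if (is.null(v)) stop("populations[[", i, "]] is missing field '", f, "'")
    v
  }
  phi <- ils[[1]]$phi
  if (is.null(phi)) stop("interleukins[[1]] is missing field 'phi'")
  switch(id,
    single = {
      if (length(pops) != 1L) stop("model 'single' needs exactly 1 population")
      pm_single(getp(1, "k"), getp(1, "c"), getp(1, "lam"), phi, getp(1, "mu"))
    },
    two_pop = {
      if (length(pops) != 2L) stop("model 'two_pop' needs exactly 2 populations")
      pm_two_pop(getp(1, "k"), getp(1, "c"), getp(1, "lam"), getp(1, "mu"),
                 getp(2, "k"), getp(2, "c"), getp(2, "lam"), getp(2, "mu"),
                 phi)
    },
    memory_pool = {
      if (length(pops) >= 1L) {
        same <- all(vapply(pops, function(p) {
          isTRUE(all.equal(unlist(p[c("k", "c", "lam", "mu")]),
                           unlist(pops[[1]][c("k", "c", "lam", "mu")])))
        }, logical(1)))
        if (!same) stop("memory_pool clones must share parameters")
        pm_memory_pool(length(pops), getp(1, "k"), getp(1, "c"),
                       getp(1, "lam"), phi, getp(1, "mu"))
      } else {
        stop("memory_pool config needs at least one population entry")
      }
    },
    naive_pool = {
      A <- unlist(config$affinities)
      if (is.null(A) || length(A) != length(pops)) {
        stop("naive_pool config needs 'affinities' of the same length as ",
             "'populations'")
      }
      pm_naive_pool(getp(1, "k"), getp(1, "c"), getp(1, "lam"), phi,
                    getp(1, "mu"), A)
    },
    stop("unknown model_id: ", id))
}

# Characteristic state scale of a model (used for default tolerances):
# the emergent carrying capacity where defined, else the LV capacities.
pm_scale <- function(model, initial = NULL) {
  s <- 1
  if (model$model_id == "lotka_volterra") {
    s <- max(model$lv$K1, model$lv$K2)
  } else if (model$model_id == "two_compartment") {
    s <- max(model$tc$phi1 / model$tc$mu1, model$tc$phi2 / model$tc$mu2)
  } else if (length(model$populations)) {
    mu <- vapply(model$populations, `[[`, numeric(1), "mu")
    phi <- model$interleukins[[1]]$phi
    if (any(mu > 0)) s <- phi / min(mu[mu > 0])
  }
  if (!is.null(initial)) {
    s <- max(s, initial$sizes, initial$interleukins, 1)
  }
  max(s, 1)
}
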