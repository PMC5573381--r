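# Closed-form equilibria, emergent carrying capacities and linear
# stability for every model, including the coexistence/exclusion
# trichotomy of two populations competing for one interleukin.

new_equilibrium <- function(values, feasible, kind,
                            free_parameter_range = NULL, notes = NULL) {
  structure(list(values = values, feasible = feasible, kind = kind,
                 free_parameter_range = free_parameter_range,
                 notes = notes),
            class = "pm_equilibrium")
}

#' @export
print.pm_equilibrium <- function(x, ...) {
  cat("<pm_equilibrium>", x$kind,
      if (x$feasible) "(feasible)" else "(INFEASIBLE)", "\n")
  print(x$values)
  if (!is.null(x$free_parameter_range)) {
    cat("  free x2* range: [", x$free_parameter_range[1], ",",
        x$free_parameter_range[2], "]\n")
  }
  invisible(x)
}

#' Emergent carrying capacity of a model
#'
#' The capacity is not a parameter: it emerges as the ratio of interleukin
#' production to consumption, `K = phi / mu`. For the two-compartment
#' model the memory capacity is set by IL-15 alone (`K_m = phi2/mu2`), the
#' total compartment by IL-7 (`K_total = phi1/mu1`) and the naive capacity
#' is the difference `K_n = K_total - K_m`, flagged infeasible when
#' non-positive.
#'
#' @param model A `pm_model` (not Lotka-Volterra, whose capacities are
#'   inputs).
#' @return An object of class `pm_carrying_capacity`: for shared-
#'   interleukin models a list with `K` and `feasible`; for the
#'   two-compartment model also `K_m`, `K_n`, `K_total`.
#' @export
carrying_capacity <- function(model) {
  stopifnot(inherits(model, "pm_model"))
  if (model$model_id == "lotka_volterra") {
    stop("Lotka-Volterra capacities are parameters, not emergent; ",
         "see model$lv")
  }
  if (model$model_id == "two_compartment") {
    p <- model$tc
    K_m <- p$phi2 / p$mu2
    K_total <- p$phi1 / p$mu1
    K_n <- K_total - K_m
    return(structure(list(K = K_total, K_m = K_m, K_n = K_n,
                          K_total = K_total, feasible = K_n > 0),
                     class = "pm_carrying_capacity"))
  }
  mu <- vapply(model$populations, `[[`, numeric(1), "mu")
  phi <- model$interleukins[[1]]$phi
  if (all(mu == 0)) stop("carrying capacity requires mu > 0")
  if (model$model_id == "two_pop" && length(unique(mu)) > 1L) {
    # with unequal consumption rates the equilibrium total depends on the
    # split; report the range endpoints phi/mu_i
    return(structure(list(K = phi / mu, feasible = phi > 0,
                          note = "total depends on the equilibrium split"),
                     class = "pm_carrying_capacity"))
  }
  structure(list(K = phi / mu[1], feasible = phi > 0 && mu[1] > 0),
            class = "pm_carrying_capacity")
}

#' Closed-form equilibrium of the single-population model
#'
#' All derivatives vanish at `x* = phi/mu`, `h* = k*phi/(lambda*mu)`,
#' `v* = 0`.
#'
#' @param model A `pm_model` with `model_id = "single"` (or the same
#'   parameter set given as `k, c, lam, phi, mu` via [pm_single()]).
#' @return A `pm_equilibrium` of kind `"point"`.
#' @export
single_equilibrium <- function(model) {
  stopifnot(inherits(model, "pm_model_single"))
  p <- model$populations[[1]]
  phi <- model$interleukins[[1]]$phi
  if (p$mu <= 0) stop("single equilibrium requires mu > 0")
  xs <- phi / p$mu
  hs <- p$k * phi / (p$lam * p$mu)
  new_equilibrium(system_state(sizes = xs, velocities = 0,
                               interleukins = hs),
                  feasible = xs > 0 && hs > 0, kind = "point")
}

#' Equilibria of two populations competing for one interleukin
#'
#' The sign of `lam1*k2 - lam2*k1` decides the outcome. On the balance
#' manifold (`lam1*k2 = lam2*k1`) a whole line of equilibria exists:
#' \deqn{h^* = \frac{k_1\phi}{\lambda_1\mu_1}
#'       + \frac{k_1(\mu_1-\mu_2)}{\lambda_1\mu_1} x_2^*, \qquad
#'       x_1^* = \frac{\phi}{\mu_1} - \frac{\mu_2}{\mu_1} x_2^*,}
#' and the realized point depends on the initial conditions. Off the
#' manifold the disadvantaged population is excluded: if
#' `lam1*k2 > lam2*k1` then `x2* = 0`, `x1* = phi/mu1`,
#' `h* = k1*phi/(lam1*mu1)` (and symmetrically).
#'
#' @param model A `pm_model` with `model_id = "two_pop"`.
#' @param x2_star For the line-of-equilibria case, the point on the line to
#'   report (defaults to the midpoint of the feasible `x2*` range).
#' @return A `pm_equilibrium` of kind `"line_of_equilibria"`,
#'   `"exclusion_x1"` or `"exclusion_x2"`, with `free_parameter_range`
#'   giving the admissible `x2*` interval in the line case.
#' @export
two_pop_equilibria <- function(model, x2_star = NULL) {
  stopifnot(inherits(model, "pm_model_two_pop"))
  p1 <- model$populations[[1]]; p2 <- model$populations[[2]]
  phi <- model$interleukins[[1]]$phi
  disc <- p1$lam * p2$k - p2$lam * p1$k
  if (disc > 0) {
    # population 2 is driven to extinction
    xs <- c(phi / p1$mu, 0)
    hs <- p1$k * phi / (p1$lam * p1$mu)
    return(new_equilibrium(system_state(sizes = xs, velocities = c(0, 0),
                                        interleukins = hs),
                           feasible = xs[1] > 0 && hs > 0,
                           kind = "exclusion_x2"))
  }
  if (disc < 0) {
    xs <- c(0, phi / p2$mu)
    hs <- p2$k * phi / (p2$lam * p2$mu)
    return(new_equilibrium(system_state(sizes = xs, velocities = c(0, 0),
                                        interleukins = hs),
                           feasible = xs[2] > 0 && hs > 0,
                           kind = "exclusion_x1"))
  }
  # balance manifold: line of equilibria parameterized by x2*
  h_of <- function(x2) p1$k * phi / (p1$lam * p1$mu) +
    p1$k * (p1$mu - p2$mu) / (p1$lam * p1$mu) * x2
  x1_of <- function(x2) phi / p1$mu - (p2$mu / p1$mu) * x2
  # feasible x2* range: x1* >= 0, x2* >= 0, h* > 0
  hi <- if (p2$mu > 0) phi / p2$mu else Inf
  lo <- 0
  if (h_of(lo) <= 0 && h_of(hi) <= 0) {
    rng <- c(NA_real_, NA_real_)
  } else {
    if (h_of(hi) <= 0) {
      # h decreasing in x2; solve h(x2) = 0
      slope <- p1$k * (p1$mu - p2$mu) / (p1$lam * p1$mu)
      hi <- min(hi, -p1$k * phi / (p1$lam * p1$mu) / slope)
    }
    rng <- c(lo, hi)
  }
  if (is.null(x2_star)) {
    x2_star <- if (anyNA(rng)) 0 else mean(rng[is.finite(rng)])
    if (!is.finite(x2_star)) x2_star <- 0
  }
  xs <- c(x1_of(x2_star), x2_star)
  hs <- h_of(x2_star)
  new_equilibrium(system_state(sizes = pmax(xs, 0), velocities = c(0, 0),
                               interleukins = max(hs, 0)),
                  feasible = !anyNA(rng) && all(xs >= 0) && hs > 0,
                  kind = "line_of_equilibria",
                  free_parameter_range = rng)
}

#' Affinity-proportional equilibrium of the naive pool
#'
#' With equal clone parameters and constant antigenic forces `A_i`, the
#' naive pool has the equilibrium
#' \deqn{n_i^* = \frac{A_i}{A} K, \qquad
#'       h^* = \frac{k\phi - \mu A}{\lambda\mu},}
#' where `A = sum(A_i)` and `K = phi/mu`; the carrying capacity does not
#' depend on the antigenic forces. Feasibility requires `h* > 0`.
#'
#' @param model A `pm_model` with `model_id = "naive_pool"`, or parameters
#'   via [pm_naive_pool()].
#' @return A `pm_equilibrium` of kind `"point"` (flagged infeasible rather
#'   than raising when `h* <= 0`).
#' @export
naive_equilibrium <- function(model) {
  stopifnot(inherits(model, "pm_model_naive_pool"))
  p <- model$populations[[1]]
  phi <- model$interleukins[[1]]$phi
  A <- model$affinities$A
  A_sum <- model$affinities$A_sum
  if (A_sum <= 0) stop("naive equilibrium requires a positive total affinity")
  K <- phi / p$mu
  ns <- (A / A_sum) * K
  hs <- (p$k * phi - p$mu * A_sum) / (p$lam * p$mu)
  new_equilibrium(system_state(sizes = ns, velocities = rep(0, length(ns)),
                               interleukins = max(hs, 0)),
                  feasible = hs > 0 && all(ns >= 0), kind = "point",
                  notes = list(h_star = hs))
}

#' Equilibrium of the naive/memory two-compartment model
#'
#' The compartment sizes at equilibrium are set by the two interleukins
#' alone: `m* = phi2/mu2 = K_m` and `n* = phi1/mu1 - phi2/mu2 = K_n`. The
#' interleukin levels follow from the two force-balance equations at
#' `(m*, n*)`:
#' \deqn{h_1^* = \frac{(k_n n^* - A)(m^*+n^*)}{\lambda_{n1} n^*}, \qquad
#'       h_2^* = \frac{k_m m^* - \lambda_{m1} h_1^* m^*/(m^*+n^*)}
#'                    {\lambda_{m2}}.}
#' Feasibility requires `h1* > 0` and `h2* > 0`.
#'
#' @param model A `pm_model` with `model_id = "two_compartment"`.
#' @return A `pm_equilibrium` of kind `"point"` (or `"degenerate"` when
#'   `n* <= 0`, where `h1*` is undefined).
#' @export
two_compartment_equilibrium <- function(model) {
  stopifnot(inherits(model, "pm_model_two_compartment"))
  p <- model$tc
  ms <- p$phi2 / p$mu2
  ns <- p$phi1 / p$mu1 - p$phi2 / p$mu2
  if (ns <= 0) {
    return(new_equilibrium(
      system_state(sizes = c(ms, max(ns, 0)), velocities = c(0, 0),
                   interleukins = c(0, 0)),
      feasible = FALSE, kind = "degenerate",
      notes = list(reason = "K_n <= 0: naive capacity infeasible")))
  }
  S <- ms + ns
  h1 <- (p$k_n * ns - p$A) * S / (p$lam_n1 * ns)
  h2 <- (p$k_m * ms - p$lam_m1 * h1 * ms / S) / p$lam_m2
  new_equilibrium(system_state(sizes = c(ms, ns), velocities = c(0, 0),
                               interleukins = c(max(h1, 0), max(h2, 0))),
                  feasible = h1 > 0 && h2 > 0, kind = "point",
                  notes = list(h1_star = h1, h2_star = h2))
}

#' Equilibrium of a model (generic dispatcher)
#'
#' Routes to the model-appropriate closed form.
#'
#' @param model A `pm_model`.
#' @param ... Passed on (e.g. `x2_star` for the two-population line).
#' @return A `pm_equilibrium`.
#' @export
equilibrium <- function(model, ...) {
  switch(model$model_id,
    single = single_equilibrium(model),
    two_pop = two_pop_equilibria(model, ...),
    naive_pool = naive_equilibrium(model),
    two_compartment = two_compartment_equilibrium(model),
    memory_pool = {
      # equal-parameter pool: any split summing to K, with h* = k*K/lam;
      # report the symmetric point
      M <- length(model$populations)
      if (M == 0L) stop("memory_pool with no clones has no equilibrium")
      p <- model$populations[[1]]
      K <- model$interleukins[[1]]$phi / p$mu
      new_equilibrium(
        system_state(sizes = rep(K / M, M), velocities = rep(0, M),
                     interleukins = p$k * K / p$lam),
        feasible = K > 0, kind = "line_of_equilibria",
        free_parameter_range = c(0, K))
    },
    lotka_volterra = lv_equilibrium(model),
    stop("unknown model_id: ", model$model_id))
}

# central finite-difference Jacobian of the unconstrained field, with a
# per-variable step scaled to the variable's magnitude
pm_jacobian <- function(model, y, t = 0) {
  field <- build_vector_field(model)
  n <- length(y)
  J <- matrix(0, n, n)
  hstep <- (.Machine$double.eps)^(1/3) * pmax(abs(y), pm_scale(model) * 1e-6)
  for (j in seq_len(n)) {
    yp <- y; ym <- y
    yp[j] <- y[j] + hstep[j]
    ym[j] <- y[j] - hstep[j]
    J[, j] <- (field(t, yp) - field(t, ym)) / (2 * hstep[j])
  }
  dimnames(J) <- list(model_layout(model)$names, model_layout(model)$names)
  J
}

#' Linear stability of an equilibrium
#'
#' Builds the Jacobian of the first-order field at the equilibrium by
#' central finite differences and reports its spectrum, together with the
#' analytic criterion `c*k > lambda*mu` where the model admits one (for the
#' single-population model the characteristic polynomial is
#' `s^3 + c s^2 + k s + lambda*mu`, so the criterion is exactly
#' Routh-Hurwitz). For a line of equilibria one zero mode (eigenvalue with
#' vanishing real part, along the manifold) is expected and tolerated.
#'
#' @param model A `pm_model`.
#' @param eq A `pm_equilibrium` (defaults to [equilibrium()] of the model).
#' @param zero_tol Modulus below which an eigenvalue real part counts as a
#'   zero mode; default `1e-7` times the spectral scale.
#' @return An object of class `pm_stability_report` with fields
#'   `condition_holds` (`NA` where no analytic criterion is stated),
#'   `eigenvalues`, `zero_modes`, `expected_zero_modes` and
#'   `numerically_stable`.
#' @export
stability <- function(model, eq = equilibrium(model), zero_tol = NULL) {
  stopifnot(inherits(model, "pm_model"), inherits(eq, "pm_equilibrium"))
  if (!eq$feasible) {
    stop("stability analysis requires a feasible equilibrium")
  }
  y <- flatten_state(eq$values, model)
  J <- pm_jacobian(model, y)
  ev <- eigen(J, only.values = TRUE)$values
  if (is.null(zero_tol)) {
    zero_tol <- 1e-7 * max(1, max(abs(ev)))
  }
  re <- Re(ev)
  zero_modes <- sum(abs(re) < zero_tol)
  expected <- if (identical(eq$kind, "line_of_equilibria")) 1L else 0L
  numerically_stable <- (zero_modes == expected) &&
    all(re < zero_tol) && all(re[abs(re) >= zero_tol] < 0)

  condition_holds <- switch(model$model_id,
    single = ,
    memory_pool = ,
    naive_pool = {
      p <- model$populations[[1]]
      p$c * p$k > p$lam * p$mu
    },
    two_pop = {
      # per-population analogue of the single-model criterion
      all(vapply(model$populations,
                 function(p) p$c * p$k > p$lam * p$mu, logical(1)))
    },
    NA)

  structure(list(condition_holds = condition_holds,
                 eigenvalues = ev,
                 zero_modes = zero_modes,
                 expected_zero_modes = expected,
                 numerically_stable = numerically_stable,
                 zero_tol = zero_tol,
                 jacobian = J),
            class = "pm_stability_report")
}

#' @export
print.pm_stability_report <- function(x, ...) {
  cat("<pm_stability_report>\n")
  cat("  analytic condition (ck > lambda*mu):",
      if (is.na(x$condition_holds)) "not stated for this model"
      else x$condition_holds, "\n")
  cat("  numerically stable:", x$numerically_stable,
      sprintf("(zero modes: %d, expected: %d)\n", x$zero_modes,
              x$expected_zero_modes))
  cat("  Re(eigenvalues):",
      paste(signif(Re(x$eigenvalues), 4), collapse = " "), "\n")
  invisible(x)
}

#' Roots of the single-model characteristic polynomial
#'
#' Analytic cross-check for [stability()]: the linearization of the
#' single-population model has characteristic polynomial
#' `s^3 + c s^2 + k s + lambda*mu`, stable by Routh-Hurwitz exactly when
#' `c*k > lambda*mu` (with `c, k, lambda*mu > 0`).
#'
#' @param model A `pm_model` with `model_id = "single"`.
#' @return Complex roots of the characteristic polynomial.
#' @export
single_characteristic_roots <- function(model) {
  stopifnot(inherits(model, "pm_model_single"))
  p <- model$populations[[1]]
  polyroot(c(p$lam * p$mu, p$k, p$c, 1))
}

#' Equilibrium total of an equal-parameter memory pool
#'
#' For any number of clones sharing parameters, the equilibrium total is
#' the emergent capacity `K = phi/mu`, independent of the clone count: new
#' clones redistribute but never enlarge the pool.
#'
#' @param model A `pm_model` with `model_id = "memory_pool"` (equal clone
#'   parameters by construction).
#' @param clone_count Optional clone count to check against the model.
#' @return The equilibrium total `phi/mu`.
#' @export
uninvadable_total <- function(model, clone_count = NULL) {
  stopifnot(inherits(model, "pm_model_memory_pool"))
  if (!is.null(clone_count) && clone_count != length(model$populations)) {
    stop("clone_count (", clone_count, ") does not match the model (",
         length(model$populations), " clones)")
  }
  if (length(model$populations) == 0L) return(0)
  p <- model$populations[[1]]
  model$interleukins[[1]]$phi / p$mu
}

#' Serialize equilibrium/stability results to JSON
#'
#' @param eq A `pm_equilibrium`.
#' @param report Optional `pm_stability_report`.
#' @param path Optional output file.
#' @return The serializable list (invisibly if written to `path`).
#' @export
equilibrium_json <- function(eq, report = NULL, path = NULL) {
  out <- list(kind = eq$kind, feasible = eq$feasible,
              sizes = eq$values$sizes,
              velocities = eq$values$velocities,
              interleukins = eq$values$interleukins,
              free_parameter_range = eq$free_parameter_range)
  if (!is.null(report)) {
    out$stability <- list(
      condition_holds = report$condition_holds,
      numerically_stable = report$numerically_stable,
      zero_modes = report$zero_modes,
      eigenvalues_re = Re(report$eigenvalues),
      eigenvalues_im = Im(report$eigenvalues))
  }
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(out))
  }
  out
}
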