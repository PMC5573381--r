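# Classical Lotka-Volterra competition: the contrast class. Here the
# carrying capacities are parameters and coexistence requires a narrow
# parameter range, whereas in the interleukin-competition models the
# capacity emerges and equal-parameter clones always coexist.

#' Classify the outcome of Lotka-Volterra competition
#'
#' Standard phase-plane analysis: coexistence iff
#' `alpha12*K2 < K1` and `alpha21*K1 < K2`; both inequalities reversed
#' gives bistability (founder control); exactly one satisfied excludes the
#' disadvantaged population. Boundary equalities are reported as
#' `"degenerate"` rather than coerced into a class.
#'
#' @param model A `pm_model` with `model_id = "lotka_volterra"`.
#' @return One of `"coexistence"`, `"exclusion_of_x1"`,
#'   `"exclusion_of_x2"`, `"bistable"`, `"degenerate"`.
#' @export
lv_classify <- function(model) {
  stopifnot(inherits(model, "pm_model_lotka_volterra"))
  p <- model$lv
  a <- p$alpha12 * p$K2 - p$K1   # > 0: pop 1 can be invaded out
  b <- p$alpha21 * p$K1 - p$K2   # > 0: pop 2 can be invaded out
  if (a == 0 || b == 0) return("degenerate")
  if (a < 0 && b < 0) return("coexistence")
  if (a > 0 && b > 0) return("bistable")
  if (a > 0) "exclusion_of_x1" else "exclusion_of_x2"
}

#' Equilibria of the Lotka-Volterra model
#'
#' Returns the interior equilibrium
#' `x1* = (K1 - alpha12*K2) / (1 - alpha12*alpha21)` (and symmetrically
#' `x2*`) when the classification is coexistence, otherwise the surviving
#' boundary equilibrium; in the bistable case the interior point exists
#' but is a saddle, and the realized boundary depends on the initial
#' condition.
#'
#' @param model A `pm_model` with `model_id = "lotka_volterra"`.
#' @return A `pm_equilibrium` whose `kind` carries the classification.
#' @export
lv_equilibrium <- function(model) {
  stopifnot(inherits(model, "pm_model_lotka_volterra"))
  p <- model$lv
  cls <- lv_classify(model)
  interior <- function() {
    den <- 1 - p$alpha12 * p$alpha21
    c((p$K1 - p$alpha12 * p$K2) / den, (p$K2 - p$alpha21 * p$K1) / den)
  }
  xs <- switch(cls,
    coexistence = interior(),
    exclusion_of_x1 = c(0, p$K2),
    exclusion_of_x2 = c(p$K1, 0),
    bistable = interior(),       # saddle; reported for reference
    degenerate = c(NA_real_, NA_real_))
  feasible <- !anyNA(xs) && all(xs >= 0) && cls != "degenerate"
  vals <- if (anyNA(xs)) {
    system_state(sizes = c(0, 0))
  } else {
    system_state(sizes = pmax(xs, 0))
  }
  new_equilibrium(vals, feasible = feasible, kind = cls)
}

#' Integrate the Lotka-Volterra model
#'
#' Thin wrapper around [integrate_pm()]; the LV state is first order
#' (`[x1, x2]`, no velocities or interleukins).
#'
#' @param model A `pm_model` with `model_id = "lotka_volterra"`.
#' @param initial_sizes Non-negative initial `c(x1, x2)`.
#' @param settings [integrator_settings()].
#' @return A `pm_trajectory`.
#' @export
lv_integrate <- function(model, initial_sizes,
                         settings = integrator_settings()) {
  stopifnot(inherits(model, "pm_model_lotka_volterra"),
            length(initial_sizes) == 2L, all(initial_sizes >= 0))
  integrate_pm(model, system_state(sizes = initial_sizes,
                                   velocities = numeric(0)),
               settings)
}

#' The diversity-paradox contrast, as a paired computation
#'
#' Runs the two models that frame the diversity paradox side by side.
#' In the Lotka-Volterra model, two populations with identical niches
#' (`alpha12 = alpha21 = 1`, `K1 = K2`) are degenerate — a line of neutral
#' equilibria that any parameter asymmetry collapses into exclusion. In
#' the interleukin-competition model, two clones with identical parameters
#' always satisfy the balance condition `lam1*k2 = lam2*k1`, so robust
#' coexistence (with emergent total `phi/mu`) is a necessary outcome, not
#' a knife-edge.
#'
#' @param K Shared LV carrying capacity (and target scale of the
#'   mechanical model, whose `phi/mu` is set equal to it).
#' @param eps Relative asymmetry applied to `alpha12` to break the LV tie.
#' @return A list with the LV classification at the tie and after the
#'   asymmetry, and the mechanical model's equilibrium kind.
#' @export
diversity_contrast <- function(K = 1000, eps = 0.01) {
  lv_tie <- pm_lotka_volterra(1, 1, K, K, 1, 1)
  lv_broken <- pm_lotka_volterra(1, 1, K, K, 1 + eps, 1 - eps)
  mech <- pm_two_pop(100, 50, 8, 10, 100, 50, 8, 10, phi = 10 * K)
  list(lv_tie = lv_classify(lv_tie),
       lv_broken = lv_classify(lv_broken),
       mechanical = two_pop_equilibria(mech)$kind,
       mechanical_total = carrying_capacity(mech)$K)
}
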