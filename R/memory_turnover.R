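# Discrete calculus of memory clone turnover. Between well-separated
# activation events the pool relaxes to its carrying capacity K = phi/mu;
# the post-relaxation clone sizes follow the shrink factor K/(K + delta),
# where delta is the number of memory cells the event injected. Clones
# falling below one cell are removed from the pool.

#' An activation event of the memory pool
#'
#' @param kind `"naive_activation"` (a naive clone is activated and enters
#'   the memory pool as a new clone of `m_new_0` cells) or
#'   `"memory_reactivation"` (an existing memory clone `clone_id` gains
#'   `delta_m` cells).
#' @param m_new_0 Size of the newly formed memory clone (naive activation).
#' @param clone_id Identifier of the reactivated clone.
#' @param delta_m Size increment of the reactivated clone.
#' @param label Optional pathogen tag.
#' @return An object of class `pm_activation_event`.
#' @export
activation_event <- function(kind = c("naive_activation",
                                      "memory_reactivation"),
                             m_new_0 = NULL, clone_id = NULL,
                             delta_m = NULL, label = NULL) {
  kind <- match.arg(kind)
  if (kind == "naive_activation") {
    if (is.null(m_new_0) || m_new_0 <= 0) {
      stop("naive_activation requires m_new_0 > 0")
    }
  } else {
    if (is.null(clone_id)) stop("memory_reactivation requires clone_id")
    if (is.null(delta_m) || delta_m <= 0) {
      stop("memory_reactivation requires delta_m > 0")
    }
  }
  structure(list(kind = kind, m_new_0 = m_new_0, clone_id = clone_id,
                 delta_m = delta_m, label = label),
            class = "pm_activation_event")
}

#' Memory pool ledger
#'
#' Book-keeping container for the discrete turnover calculus: current
#' clone sizes, the pool's carrying capacity, the event history and the
#' set of extinct clones. At rest the sizes sum to `K`.
#'
#' @param clones Named numeric vector of clone sizes (may be empty).
#' @param K Carrying capacity of the memory pool, `> 0`.
#' @param removal_threshold Clones strictly below this size are removed
#'   (default 1 cell).
#' @return An object of class `pm_memory_ledger`.
#' @export
memory_ledger <- function(clones = numeric(0), K,
                          removal_threshold = 1) {
  stopifnot(is.numeric(K), length(K) == 1L, K > 0)
  clones <- unlist(clones)
  if (length(clones)) {
    if (is.null(names(clones)) || any(names(clones) == "")) {
      names(clones) <- paste0("clone", seq_along(clones))
    }
    if (any(clones < 0)) stop("clone sizes must be non-negative")
  }
  structure(list(clones = clones, K = K,
                 removal_threshold = removal_threshold,
                 history = make_ledger_history(), extinct = character(0)),
            class = "pm_memory_ledger")
}

make_ledger_history <- function() {
  data.frame(event_index = integer(0), clone_id = character(0),
             pre_size = numeric(0), post_size = numeric(0),
             extinct_flag = logical(0))
}

#' @export
print.pm_memory_ledger <- function(x, ...) {
  cat("<pm_memory_ledger> K =", x$K, "|", length(x$clones), "clones,",
      length(x$extinct), "extinct\n")
  if (length(x$clones)) print(signif(x$clones, 6))
  invisible(x)
}

ledger_record <- function(ledger, pre, post) {
  idx <- if (nrow(ledger$history)) max(ledger$history$event_index) + 1L
         else 1L
  ids <- union(names(pre), names(post))
  rows <- data.frame(
    event_index = idx, clone_id = ids,
    pre_size = ifelse(ids %in% names(pre), pre[ids], 0),
    post_size = ifelse(ids %in% names(post), post[ids], 0),
    extinct_flag = FALSE)
  rownames(rows) <- NULL
  ledger$history <- rbind(ledger$history, rows)
  ledger
}

ledger_remove_extinct <- function(ledger) {
  below <- ledger$clones < ledger$removal_threshold
  if (any(below)) {
    gone <- names(ledger$clones)[below]
    ledger$extinct <- c(ledger$extinct, gone)
    if (nrow(ledger$history)) {
      last <- ledger$history$event_index == max(ledger$history$event_index)
      ledger$history$extinct_flag[last &
        ledger$history$clone_id %in% gone] <- TRUE
    }
    ledger$clones <- ledger$clones[!below]
  }
  ledger
}

next_clone_id <- function(ledger) {
  existing <- c(names(ledger$clones), ledger$extinct)
  i <- length(existing) + 1L
  repeat {
    id <- paste0("clone", i)
    if (!(id %in% existing)) return(id)
    i <- i + 1L
  }
}

#' Apply the activation of a naive clone to the memory pool
#'
#' A new memory clone of initial size `m_new_0` enters the pool; after
#' relaxation back to the carrying capacity the new clone holds
#' `m_new_0 * K / (K + m_new_0)` cells and every pre-existing clone of
#' size `m0` shrinks to `m0 * K / (K + m_new_0)`. Clones below the removal
#' threshold are then dropped.
#'
#' @param ledger A [memory_ledger()].
#' @param m_new_0 Initial size of the entering clone, `> 0`.
#' @param clone_id Optional identifier for the new clone.
#' @return The updated ledger.
#' @export
apply_naive_activation <- function(ledger, m_new_0, clone_id = NULL) {
  stopifnot(inherits(ledger, "pm_memory_ledger"), m_new_0 > 0)
  if (is.null(clone_id)) clone_id <- next_clone_id(ledger)
  if (clone_id %in% names(ledger$clones)) {
    stop("clone_id '", clone_id, "' already exists")
  }
  K <- ledger$K
  shrink <- K / (K + m_new_0)
  pre <- c(ledger$clones, stats::setNames(m_new_0, clone_id))
  post <- c(ledger$clones * shrink,
            stats::setNames(m_new_0 * shrink, clone_id))
  ledger$clones <- post
  ledger <- ledger_record(ledger, pre, post)
  ledger_remove_extinct(ledger)
}

#' Apply the reactivation of an existing memory clone
#'
#' The reactivated clone transiently gains `delta_m` cells; after
#' relaxation it holds `(delta_m + m0) * K / (K + delta_m)` cells, while
#' every other clone shrinks by the factor `K / (K + delta_m)`.
#' Reactivation boosts the activated clone whenever its size is below `K`.
#'
#' @param ledger A [memory_ledger()].
#' @param clone_id Identifier of the reactivated clone.
#' @param delta_m Size increment, `> 0`.
#' @return The updated ledger.
#' @export
apply_memory_reactivation <- function(ledger, clone_id, delta_m) {
  stopifnot(inherits(ledger, "pm_memory_ledger"), delta_m > 0)
  if (!(clone_id %in% names(ledger$clones))) {
    stop("unknown clone_id '", clone_id, "'")
  }
  K <- ledger$K
  shrink <- K / (K + delta_m)
  pre <- ledger$clones
  post <- pre * shrink
  post[clone_id] <- (delta_m + pre[clone_id]) * shrink
  ledger$clones <- post
  ledger <- ledger_record(ledger, pre, post)
  ledger_remove_extinct(ledger)
}

#' Clone size after a sequence of activations of other clones
#'
#' A non-activated clone of initial size `m_i_0` shrinks by one factor
#' `K / (K + delta_m_j)` per activation event, i.e.
#' `m_i_n = m_i_0 * prod(K / (K + deltas))`. This is exactly the
#' composition of the per-event updates.
#'
#' @param m_i_0 Initial clone size.
#' @param deltas Sizes injected by the successive activations (each `> 0`).
#' @param K Carrying capacity of the memory pool.
#' @return The clone size after all events.
#' @export
sequential_size <- function(m_i_0, deltas, K) {
  stopifnot(m_i_0 >= 0, K > 0)
  deltas <- as.numeric(deltas)
  if (length(deltas) && any(deltas <= 0)) stop("all deltas must be > 0")
  m_i_0 * prod(K / (K + deltas))
}

#' Will a non-reactivated clone drop below one cell?
#'
#' The exact predicate evaluates `sequential_size(...) < 1`. The
#' logarithmic approximation (obtained from the exact product via
#' `log(1 + delta/K) ~ delta/K`) predicts extinction when
#' `log(m_i_0) < sum(deltas) / K` (natural logarithm). Both are returned,
#' with a flag marking disagreement: the approximation overestimates the
#' shrinkage needed, so the two can differ when some `delta` is comparable
#' to `K`.
#'
#' @inheritParams sequential_size
#' @return A list with `exact`, `log_approx`, `disagree` and the final
#'   `size` under the exact product.
#' @export
extinction_predicate <- function(m_i_0, deltas, K) {
  size <- sequential_size(m_i_0, deltas, K)
  exact <- size < 1
  log_approx <- log(m_i_0) < sum(deltas) / K
  list(exact = exact, log_approx = log_approx,
       disagree = exact != log_approx, size = size)
}

#' Read an event sequence from CSV
#'
#' Columns: `order`, `kind` (`naive_activation` or `memory_reactivation`),
#' `clone_id` (empty for naive activations), `size` (`m_new_0` or
#' `delta_m`).
#'
#' @param path CSV file path.
#' @return A list of [activation_event()]s in `order`.
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("order", "kind", "clone_id", "size")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("events CSV is missing columns: ", paste(miss, collapse = ", "))
  }
  df <- df[order(df$order), , drop = FALSE]
  lapply(seq_len(nrow(df)), function(i) {
    if (df$kind[i] == "naive_activation") {
      activation_event("naive_activation", m_new_0 = df$size[i])
    } else {
      activation_event("memory_reactivation", clone_id = df$clone_id[i],
                       delta_m = df$size[i])
    }
  })
}

#' Write a ledger history as tidy CSV
#'
#' Columns `event_index`, `clone_id`, `pre_size`, `post_size`,
#' `extinct_flag`.
#'
#' @param ledger A ledger with a `history` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ledger_csv <- function(ledger, path) {
  utils::write.csv(ledger$history, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run an activation event sequence through the memory pool
#'
#' In `closed_form` mode each event is applied with the discrete shrink
#' factors (see [apply_naive_activation()], [apply_memory_reactivation()]).
#' In `ode` mode the equal-parameter memory pool ODE system is perturbed
#' by the event (the new or boosted clone enters with zero velocity,
#' interleukin left at its pre-event equilibrium level) and relaxed to
#' steady state; events are assumed well separated in time, so each
#' relaxation completes before the next event. Clones below the removal
#' threshold are removed after each event.
#'
#' @param params A list with `k`, `c`, `lam`, `phi`, `mu` (shared by all
#'   clones); the carrying capacity is `K = phi/mu`. In `closed_form` mode
#'   only `K` matters and may be supplied directly as `params = list(K=)`.
#' @param events List of [activation_event()]s (or a data frame as read by
#'   [read_events_csv()]).
#' @param initial_clones Named numeric vector of resting clone sizes; they
#'   are rescaled to sum to `K` if they do not (the pool is assumed at
#'   rest when the sequence starts).
#' @param mode `"closed_form"` or `"ode"`.
#' @param settings [integrator_settings()] for `ode` mode.
#' @return The final [memory_ledger()]; its `history` holds per-event
#'   pre/post sizes and extinction flags.
#' @export
run_event_sequence <- function(params, events,
                               initial_clones = numeric(0),
                               mode = c("closed_form", "ode"),
                               settings = integrator_settings()) {
  mode <- match.arg(mode)
  if (!is.null(params$K)) {
    K <- params$K
  } else {
    stopifnot(!is.null(params$phi), !is.null(params$mu), params$mu > 0)
    K <- params$phi / params$mu
  }
  if (mode == "ode" &&
      any(vapply(c("k", "c", "lam", "phi", "mu"),
                 function(f) is.null(params[[f]]), logical(1)))) {
    stop("ode mode requires params k, c, lam, phi, mu")
  }
  if (is.data.frame(events)) {
    stop("pass events as a list of activation_event(); ",
         "use read_events_csv() for CSV input")
  }
  ledger <- memory_ledger(initial_clones, K)
  if (length(ledger$clones)) {
    tot <- sum(ledger$clones)
    if (tot > 0 && abs(tot - K) > 1e-9 * K) {
      ledger$clones <- ledger$clones * (K / tot)
    }
  }

  for (ev in events) {
    stopifnot(inherits(ev, "pm_activation_event"))
    if (mode == "closed_form") {
      ledger <- if (ev$kind == "naive_activation") {
        apply_naive_activation(ledger, ev$m_new_0)
      } else {
        apply_memory_reactivation(ledger, ev$clone_id, ev$delta_m)
      }
    } else {
      ledger <- ode_apply_event(ledger, ev, params, settings)
    }
  }
  ledger
}

# one event in ode mode: perturb the equilibrated pool and relax
ode_apply_event <- function(ledger, ev, params, settings) {
  clones <- ledger$clones
  if (ev$kind == "naive_activation") {
    id <- next_clone_id(ledger)
    pre <- c(clones, stats::setNames(ev$m_new_0, id))
  } else {
    if (!(ev$clone_id %in% names(clones))) {
      stop("unknown clone_id '", ev$clone_id, "'")
    }
    pre <- clones
    pre[ev$clone_id] <- pre[ev$clone_id] + ev$delta_m
  }
  M <- length(pre)
  model <- pm_memory_pool(M, params$k, params$c, params$lam,
                          params$phi, params$mu)
  h_eq <- params$k * ledger$K / params$lam   # pre-event equilibrium level
  st <- system_state(sizes = unname(pre), velocities = rep(0, M),
                     interleukins = h_eq)
  fs <- find_steady_state(model, st, settings)
  post <- stats::setNames(fs$sizes, names(pre))
  ledger$clones <- post
  ledger <- ledger_record(ledger, pre, post)
  ledger_remove_extinct(ledger)
}
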