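# Naive-pool diversity: affinity-proportional resting sizes, the dynamic
# peripheral positive-selection threshold A/K, turnover under thymic
# influx, and the diversity consequence of capping affinities (negative
# selection).

#' Naive pool ledger
#'
#' Clones of the naive pool with their antigenic affinities and current
#' sizes. At rest each surviving clone holds the affinity-proportional
#' share `(A_i / A) * K` of the carrying capacity.
#'
#' @param affinities Named numeric vector of per-clone affinities
#'   (`>= 0`); names are clone identifiers.
#' @param K Naive carrying capacity, `> 0`.
#' @param removal_threshold Clones whose resting size falls strictly below
#'   this are removed (default 1 cell).
#' @return An object of class `pm_naive_ledger`.
#' @export
naive_ledger <- function(affinities = numeric(0), K,
                         removal_threshold = 1) {
  stopifnot(is.numeric(K), length(K) == 1L, K > 0)
  affinities <- unlist(affinities)
  if (length(affinities)) {
    if (is.null(names(affinities)) || any(names(affinities) == "")) {
      names(affinities) <- paste0("clone", seq_along(affinities))
    }
    if (any(affinities < 0) || any(!is.finite(affinities))) {
      stop("affinities must be finite and non-negative")
    }
  }
  lg <- structure(list(affinities = affinities,
                       sizes = stats::setNames(rep(NA_real_,
                                                   length(affinities)),
                                               names(affinities)),
                       K = K, removal_threshold = removal_threshold,
                       extinct = character(0),
                       influx_history = data.frame(
                         entry_index = integer(0), clone_id = character(0),
                         affinity = numeric(0), accepted = logical(0))),
                  class = "pm_naive_ledger")
  lg
}

#' @export
print.pm_naive_ledger <- function(x, ...) {
  cat("<pm_naive_ledger> K =", x$K, "|", length(x$affinities), "clones,",
      length(x$extinct), "removed\n")
  if (length(x$affinities)) {
    df <- data.frame(affinity = x$affinities, size = x$sizes)
    print(signif(as.matrix(df), 6))
  }
  invisible(x)
}

#' Current total affinity of the surviving clones
#' @param ledger A [naive_ledger()].
#' @return `sum(A_i)` over surviving clones.
#' @export
total_affinity <- function(ledger) {
  stopifnot(inherits(ledger, "pm_naive_ledger"))
  sum(ledger$affinities)
}

#' Peripheral positive-selection threshold
#'
#' A clone survives in the resting pool only if its resting size
#' `(A_i / A) * K` is at least one cell, i.e. if its affinity is at least
#' `A / K` where `A` is the total affinity of the pool. The threshold is
#' dynamic: the entry of any new clone raises `A` and with it the
#' threshold.
#'
#' @param ledger A [naive_ledger()] with at least one clone.
#' @return The minimum viable affinity `A / K` (scaled by the removal
#'   threshold if it is not 1 cell).
#' @export
selection_threshold <- function(ledger) {
  stopifnot(inherits(ledger, "pm_naive_ledger"))
  A <- total_affinity(ledger)
  if (length(ledger$affinities) == 0L || A <= 0) {
    stop("selection threshold is undefined for an empty pool")
  }
  ledger$removal_threshold * A / ledger$K
}

#' Relax the naive pool to its selection fixed point
#'
#' Iterates: compute the affinity-proportional resting sizes of the
#' current survivors; if any clone sits strictly below the removal
#' threshold, remove the lowest-affinity one (which is always the
#' smallest) and recompute — until no clone is below threshold. Removing
#' one clone at a time, lowest affinity first, makes the fixed point
#' exact: a clone survives if and only if its affinity-proportional share
#' of `K` among the survivors is at least one cell, and re-adding any
#' removed clone to the final pool would again put it below one cell. At
#' the fixed point sizes are proportional to affinities and sum to `K`.
#'
#' @param ledger A [naive_ledger()].
#' @return The ledger at rest (possibly with all clones removed, reported
#'   via `length(ledger$affinities) == 0`, not an error).
#' @export
equilibrate_pool <- function(ledger) {
  stopifnot(inherits(ledger, "pm_naive_ledger"))
  repeat {
    A <- ledger$affinities
    if (length(A) == 0L) {
      ledger$sizes <- stats::setNames(numeric(0), character(0))
      return(ledger)
    }
    A_sum <- sum(A)
    if (A_sum <= 0) {
      ledger$extinct <- c(ledger$extinct, names(A))
      ledger$affinities <- ledger$affinities[0]
      ledger$sizes <- stats::setNames(numeric(0), character(0))
      return(ledger)
    }
    sizes <- (A / A_sum) * ledger$K
    below <- sizes < ledger$removal_threshold
    if (!any(below)) {
      ledger$sizes <- sizes
      return(ledger)
    }
    # the below-threshold clone with the lowest affinity is the global
    # minimum; drop it alone and re-test (ties: first of the minima)
    drop <- which(A == min(A[below]))[1]
    ledger$extinct <- c(ledger$extinct, names(A)[drop])
    ledger$affinities <- ledger$affinities[-drop]
  }
}

#' Sequential entry of new clones from the thymus
#'
#' Each entering clone is added to the pool, which is then re-equilibrated
#' before the next entry: an entrant whose affinity is below the current
#' threshold is immediately removed, while a high-affinity entrant raises
#' the threshold and can displace incumbents just above the old one.
#'
#' @param ledger A [naive_ledger()] (equilibrated or not).
#' @param new_affinities Numeric vector of entrant affinities (optionally
#'   named); entries are processed in order.
#' @return The ledger after all entries, at rest; `influx_history` records
#'   each entrant and whether it was accepted.
#' @export
thymic_influx <- function(ledger, new_affinities) {
  stopifnot(inherits(ledger, "pm_naive_ledger"))
  new_affinities <- unlist(new_affinities)
  if (length(new_affinities) == 0L) return(equilibrate_pool(ledger))
  if (any(new_affinities < 0)) stop("entrant affinities must be >= 0")
  nm <- names(new_affinities)
  ledger <- equilibrate_pool(ledger)
  for (i in seq_along(new_affinities)) {
    id <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else {
      existing <- c(names(ledger$affinities), ledger$extinct,
                    ledger$influx_history$clone_id)
      j <- length(existing) + 1L
      while (paste0("entrant", j) %in% existing) j <- j + 1L
      paste0("entrant", j)
    }
    ledger$affinities <- c(ledger$affinities,
                           stats::setNames(new_affinities[[i]], id))
    ledger <- equilibrate_pool(ledger)
    accepted <- id %in% names(ledger$affinities)
    ledger$influx_history <- rbind(
      ledger$influx_history,
      data.frame(entry_index = nrow(ledger$influx_history) + 1L,
                 clone_id = id, affinity = new_affinities[[i]],
                 accepted = accepted))
  }
  ledger
}

#' Shannon entropy of clone sizes
#' @param sizes Numeric vector of clone sizes.
#' @return Shannon entropy (natural log) of the size distribution; 0 for
#'   an empty or single-clone pool.
#' @export
shannon_entropy <- function(sizes) {
  sizes <- sizes[sizes > 0]
  if (length(sizes) < 2L) return(0)
  p <- sizes / sum(sizes)
  -sum(p * log(p))
}

#' Diversity under an affinity cap (negative selection)
#'
#' Draws `n_draws` candidate clone affinities from `draw_fun`, then for
#' each cap in `A_max_grid` removes draws above the cap (mimicking the
#' deletion of high-affinity cells in the thymus) and feeds the survivors
#' sequentially into an empty naive pool via [thymic_influx()]. Because
#' uncapped high-affinity clones monopolize the pool and raise the
#' peripheral selection threshold, a tighter cap typically leaves more
#' surviving clones: negative selection maximizes diversity.
#'
#' @param A_max_grid Numeric vector of affinity caps (use `Inf` for the
#'   uncapped control).
#' @param K Naive carrying capacity.
#' @param n_draws Number of candidate clones per run.
#' @param seed Integer seed for the draws.
#' @param draw_fun Function `n -> n affinities`; default log-normal with
#'   `meanlog = 0, sdlog = 2` (a fixture choice standing in for a
#'   heavy-tailed affinity distribution).
#' @return A data frame with one row per cap: `cap`, `n_entering`,
#'   `survivors` (richness), `entropy` (Shannon, secondary metric), `seed`.
#' @export
negative_selection_experiment <- function(A_max_grid, K, n_draws, seed,
                                          draw_fun = function(n)
                                            stats::rlnorm(n, 0, 2)) {
  stopifnot(n_draws > 0, length(A_max_grid) >= 1L)
  set.seed(seed)
  draws <- draw_fun(n_draws)
  if (any(draws < 0)) stop("draw_fun produced negative affinities")
  out <- lapply(A_max_grid, function(cap) {
    keep <- draws[draws <= cap]
    if (length(keep) == 0L) {
      return(data.frame(cap = cap, n_entering = 0L, survivors = 0L,
                        entropy = 0, seed = seed))
    }
    lg <- thymic_influx(naive_ledger(K = K), keep)
    data.frame(cap = cap, n_entering = length(keep),
               survivors = length(lg$affinities),
               entropy = shannon_entropy(lg$sizes), seed = seed)
  })
  do.call(rbind, out)
}

#' Read / write affinity profiles as CSV
#'
#' Columns `clone_id`, `affinity`.
#'
#' @param path CSV file path.
#' @return `read_affinities_csv` returns a named numeric vector.
#' @export
read_affinities_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("clone_id", "affinity") %in% names(df))) {
    stop("affinity CSV needs columns clone_id, affinity")
  }
  stats::setNames(df$affinity, df$clone_id)
}

#' @rdname read_affinities_csv
#' @param affinities Named numeric vector.
#' @export
write_affinities_csv <- function(affinities, path) {
  df <- data.frame(clone_id = names(affinities),
                   affinity = unname(affinities))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
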