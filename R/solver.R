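#' Pool vectors and steady-state iteration
#'
#' A pool vector holds the fraction of each metabolite's cellular pool in
#' each positional isotopomer, indexed by the enumerated state space; each
#' metabolite's slice sums to 1. Before any label is administered the whole
#' pool of every intermediate is unlabelled, so the initial vector places
#' mass 1 on each metabolite's all-unlabelled state.
#'
#' @param space A `tca_states` object.
#' @return A `tca_pool`: a numeric vector over state indices with an
#'   `iteration` attribute.
#' @examples
#' tab <- default_transition_table()
#' sp <- enumerate_states(tab)
#' p0 <- initial_pool(sp)
#' @export
initial_pool <- function(space) {
  stopifnot(inherits(space, "tca_states"))
  v <- numeric(nrow(space$states))
  for (met in tca_cycle_order) {
    zero <- rep(0L, space$metabolites[[met]])
    v[state_index(space, met, zero)] <- 1
  }
  new_tca_pool(v, 0L)
}

new_tca_pool <- function(values, iteration) {
  structure(as.numeric(values), iteration = as.integer(iteration),
            class = "tca_pool")
}

#' @export
print.tca_pool <- function(x, ...) {
  cat(sprintf(
    "<tca_pool> %d states, iteration %d\n", length(x), attr(x, "iteration")
  ))
  invisible(x)
}

#' Advance the pool by one synchronous cycle step
#'
#' Each metabolite's isotopomer slice at time T is computed entirely from
#' the slice of the preceding metabolite in the cycle at time T - 1, by
#' right-multiplying the row pool vector with the combined transition
#' matrix. Per-metabolite totals are conserved.
#'
#' @param pool A `tca_pool`.
#' @param model A `tca_model`.
#' @param alpha Labelled acetyl-CoA fraction in \[0, 1\].
#' @return The updated `tca_pool` with its iteration count incremented.
#' @export
step_pool <- function(pool, model, alpha) {
  stopifnot(inherits(pool, "tca_pool"))
  M <- combine_alpha(model, alpha)
  new_tca_pool(as.numeric(pool) %*% M, attr(pool, "iteration") + 1L)
}

#' Iterate the network model to isotopic steady state
#'
#' Repeats the synchronous cycle step from the all-unlabelled initial pool
#' until the largest absolute change of any state fraction falls below
#' `tol`. The fixed point is the isotopic steady state: the isotopologue
#' proportions it implies no longer change with further turns.
#'
#' @inheritParams step_pool
#' @param tol Convergence tolerance on the max-norm change per step.
#' @param max_iter Maximum number of steps before failing.
#' @param init Optional starting `tca_pool` (defaults to the all-unlabelled
#'   pool); the fixed point does not depend on any lawful start.
#' @return A `tca_pool` at the fixed point, with attributes `iterations`
#'   (steps used) and `residual` (last max-norm change).
#' @examples
#' tab <- default_transition_table()
#' model <- build_transition_model(tab, enumerate_states(tab))
#' ss <- steady_state(model, alpha = 0.5)
#' @export
steady_state <- function(model, alpha, tol = 1e-12, max_iter = 10000L,
                         init = NULL) {
  stopifnot(inherits(model, "tca_model"))
  check_fraction(alpha, "alpha")
  if (!is.numeric(tol) || tol <= 0) abort("`tol` must be > 0.")
  if (max_iter < 1) abort("`max_iter` must be >= 1.")
  M <- combine_alpha(model, alpha)
  v <- if (is.null(init)) {
    as.numeric(initial_pool(model$space))
  } else {
    as.numeric(init)
  }
  for (it in seq_len(max_iter)) {
    v_new <- as.numeric(v %*% M)
    delta <- max(abs(v_new - v))
    v <- v_new
    if (delta < tol) {
      out <- new_tca_pool(v, it)
      attr(out, "iterations") <- it
      attr(out, "residual") <- delta
      return(out)
    }
  }
  abort(sprintf(
    "Steady state not reached in %d iterations (residual %.3e).",
    max_iter, delta
  ))
}

#' Collapse positional isotopomers to mass-isotopologue distributions
#'
#' Sums the state fractions of each metabolite by number of labelled
#' carbons, yielding the M+0 .. M+n mass-shift proportions that LC-MS
#' measures (n = carbon count: citrate 6, alpha-ketoglutarate 5, succinate
#' and malate 4).
#'
#' @param pool A `tca_pool`.
#' @param space The `tca_states` the pool is indexed by.
#' @return A tibble with columns `metabolite`, `mass_shift`, `proportion`;
#'   proportions sum to 1 within each metabolite.
#' @export
collapse_isotopologues <- function(pool, space) {
  stopifnot(inherits(space, "tca_states"))
  v <- as.numeric(pool)
  if (length(v) != nrow(space$states)) {
    abort("Pool length does not match the state space.")
  }
  purrr::map_dfr(tca_cycle_order, function(met) {
    idx <- slice_indices(space, met)
    n_c <- space$metabolites[[met]]
    shifts <- space$states$mass_shift[idx]
    props <- vapply(
      0:n_c, function(k) sum(v[idx][shifts == k]), numeric(1)
    )
    tibble::tibble(metabolite = met, mass_shift = 0:n_c, proportion = props)
  })
}

#' Predict steady-state isotopologue distributions at a given alpha
#'
#' Convenience wrapper: iterate to steady state and collapse to
#' mass-isotopologue proportions.
#'
#' @inheritParams steady_state
#' @return A tibble as returned by [collapse_isotopologues()].
#' @examples
#' tab <- default_transition_table()
#' model <- build_transition_model(tab, enumerate_states(tab))
#' predict_isotopologues(model, alpha = 0.145)
#' @export
predict_isotopologues <- function(model, alpha, tol = 1e-12,
                                  max_iter = 10000L) {
  ss <- steady_state(model, alpha, tol = tol, max_iter = max_iter)
  collapse_isotopologues(ss, model$space)
}

#' Scan steady-state isotopologue proportions across alpha
#'
#' Computes the steady-state mass-isotopologue distribution of every
#' tracked metabolite at each alpha on a regular grid, producing the data
#' behind bifurcation plots: the unlabelled isotopologue of each
#' intermediate falls monotonically with alpha, the fully labelled one
#' rises, and every intermediate-mass isotopologue peaks at an interior
#' alpha before returning to 0 at alpha = 1.
#'
#' @param model A `tca_model`.
#' @param grid_step Grid spacing in (0, 0.1].
#' @inheritParams steady_state
#' @return A `tca_bifurcation` tibble with columns `alpha`, `metabolite`,
#'   `mass_shift`, `proportion`.
#' @examples
#' tab <- default_transition_table()
#' model <- build_transition_model(tab, enumerate_states(tab))
#' scan <- bifurcation_scan(model, grid_step = 0.1)
#' @export
bifurcation_scan <- function(model, grid_step = 0.001, tol = 1e-12,
                             max_iter = 10000L) {
  stopifnot(inherits(model, "tca_model"))
  if (!is.numeric(grid_step) || grid_step <= 0 || grid_step > 0.1) {
    abort("`grid_step` must lie in (0, 0.1].")
  }
  out <- scan_alphas(model, alpha_grid(grid_step), tol, max_iter)
  class(out) <- c("tca_bifurcation", class(out))
  attr(out, "table_checksum") <- model$table_checksum
  out
}

scan_alphas <- function(model, alphas, tol = 1e-12, max_iter = 10000L) {
  purrr::map_dfr(alphas, function(a) {
    dplyr::mutate(
      predict_isotopologues(model, a, tol = tol, max_iter = max_iter),
      alpha = a, .before = 1
    )
  })
}

# Regular alpha grid covering [0, 1] exactly, robust to non-representable
# steps (e.g. 0.001): the endpoint is always included.
alpha_grid <- function(grid_step) {
  n <- ceiling(1 / grid_step - 1e-9)
  unique(pmin(seq(0, n) * grid_step, 1))
}
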