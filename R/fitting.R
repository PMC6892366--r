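#' Normalise raw peak-area tables to isotopologue distributions
#'
#' Raw LC-MS peak areas are used as-is (no natural-abundance correction:
#' natural abundance scales the distributions by an unknown factor that is
#' inversely related to the unknown labelled fraction, so correcting would
#' presuppose the answer). Per replicate and metabolite, areas are divided
#' by their sum; mass shifts absent from the input are filled with 0 up to
#' the metabolite's carbon count. Glutamate rows are attributed to
#' alpha-ketoglutarate, whose labelling distribution glutamate mirrors.
#'
#' @param measurements A data frame with columns `replicate`, `metabolite`
#'   (citrate, glutamate, alpha_ketoglutarate, succinate or malate),
#'   `mass_shift` and `peak_area` (arbitrary units, non-negative).
#' @return A tibble with columns `replicate`, `metabolite`, `mass_shift`
#'   (complete 0..n per metabolite) and `proportion`.
#' @examples
#' m <- tibble::tibble(
#'   replicate = 1, metabolite = "malate",
#'   mass_shift = 0:2, peak_area = c(80, 10, 10)
#' )
#' normalize_measurements(m)
#' @export
normalize_measurements <- function(measurements) {
  measurements <- validate_measurements(measurements)
  measurements$metabolite <- resolve_metabolites(measurements$metabolite)

  full <- tidyr::expand_grid(
    replicate = unique(measurements$replicate),
    purrr::map_dfr(
      tca_cycle_order,
      ~ tibble::tibble(metabolite = .x, mass_shift = 0:tca_metabolite_carbons[[.x]])
    )
  )
  out <- dplyr::left_join(
    full, measurements,
    by = c("replicate", "metabolite", "mass_shift")
  )
  out$peak_area[is.na(out$peak_area)] <- 0
  out <- dplyr::group_by(out, .data$replicate, .data$metabolite)
  out <- dplyr::mutate(out, total = sum(.data$peak_area))
  out <- dplyr::ungroup(out)
  measured <- unique(measurements[c("replicate", "metabolite")])
  measured$measured <- TRUE
  out <- dplyr::left_join(out, measured, by = c("replicate", "metabolite"))
  zero <- out$measured %in% TRUE & out$total <= 0
  if (any(zero)) {
    bad <- unique(out$metabolite[zero])
    abort(sprintf(
      "All peak areas are zero for metabolite(s): %s.",
      paste(bad, collapse = ", ")
    ))
  }
  out <- dplyr::filter(out, .data$measured %in% TRUE)
  out$proportion <- out$peak_area / out$total
  dplyr::select(
    out, "replicate", "metabolite", "mass_shift", "proportion"
  )
}

# Column, range, duplicate and carbon-count checks shared by the reader and
# the normaliser. Returns the table with canonical column types.
validate_measurements <- function(measurements, source = "measurements") {
  required <- c("replicate", "metabolite", "mass_shift", "peak_area")
  missing <- setdiff(required, names(measurements))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing column(s): %s.", source, paste(missing, collapse = ", ")
    ))
  }
  m <- tibble::as_tibble(measurements)[required]
  m$metabolite <- as.character(m$metabolite)
  m$mass_shift <- as.integer(m$mass_shift)
  m$peak_area <- as.numeric(m$peak_area)

  bad_met <- !m$metabolite %in% measurement_metabolites
  if (any(bad_met)) {
    abort(sprintf(
      "Row %d: unknown metabolite '%s'. Allowed: %s.",
      which(bad_met)[1], m$metabolite[which(bad_met)[1]],
      paste(measurement_metabolites, collapse = ", ")
    ))
  }
  neg <- m$peak_area < 0 | is.na(m$peak_area)
  if (any(neg)) {
    abort(sprintf(
      "Row %d: negative or missing peak_area.", which(neg)[1]
    ))
  }
  carbons <- tca_metabolite_carbons[resolve_metabolites(m$metabolite)]
  out_of_range <- m$mass_shift < 0 | m$mass_shift > carbons
  if (any(out_of_range)) {
    i <- which(out_of_range)[1]
    abort(sprintf(
      "Row %d: mass shift M+%d exceeds the carbon count of %s (%d); check the metabolite assignment.",
      i, m$mass_shift[i], m$metabolite[i], carbons[i]
    ))
  }
  key <- paste(m$replicate, resolve_metabolites(m$metabolite), m$mass_shift)
  if (anyDuplicated(key)) {
    abort(sprintf(
      "Row %d: duplicate (replicate, metabolite, mass_shift) entry.",
      which(duplicated(key))[1]
    ))
  }
  m
}

#' Total-variation distance between two discrete distributions
#'
#' `0.5 * sum(|p - q|)`: 0 for identical distributions, 1 for distributions
#' with disjoint support.
#'
#' @param p,q Non-negative numeric vectors of equal length summing to 1.
#' @return A number in \[0, 1\].
#' @examples
#' tv_distance(c(0.8, 0.2), c(0.6, 0.4))
#' @export
tv_distance <- function(p, q) {
  if (length(p) != length(q)) {
    abort("Distributions must share the same mass-shift support.")
  }
  0.5 * sum(abs(p - q))
}

#' Discrepancy between predicted and observed isotopologue distributions
#'
#' The fit objective: the total-variation distance between the predicted
#' and observed mass-isotopologue distribution of each included metabolite,
#' averaged with equal weight across metabolites (and equal weight to every
#' isotopologue within a metabolite). 0 is a perfect fit and 1 the worst
#' possible fit.
#'
#' @param predicted,observed Tibbles with columns `metabolite`,
#'   `mass_shift`, `proportion` (one distribution per metabolite).
#' @param included Character vector of metabolites to compare
#'   ("glutamate" is an alias for alpha_ketoglutarate).
#' @return A number in \[0, 1\].
#' @export
discrepancy <- function(predicted, observed,
                        included = tca_cycle_order) {
  per <- per_metabolite_discrepancy(predicted, observed, included)
  mean(per)
}

per_metabolite_discrepancy <- function(predicted, observed, included) {
  included <- unique(resolve_metabolites(included))
  if (length(included) == 0) abort("`included` must name at least one metabolite.")
  vapply(included, function(met) {
    p <- dplyr::filter(predicted, .data$metabolite == met)
    q <- dplyr::filter(observed, .data$metabolite == met)
    if (nrow(p) == 0 || nrow(q) == 0) {
      abort(sprintf("Metabolite '%s' missing from predicted or observed.", met))
    }
    p <- p[order(p$mass_shift), ]
    q <- q[order(q$mass_shift), ]
    if (!identical(as.numeric(p$mass_shift), as.numeric(q$mass_shift))) {
      abort(sprintf("Mass-shift support mismatch for '%s'.", met))
    }
    tv_distance(p$proportion, q$proportion)
  }, numeric(1))
}

#' Precompute steady-state predictions over an alpha grid
#'
#' Fitting scans a regular alpha grid; when many replicates or datasets are
#' fitted against the same model, compute the grid once and pass it to
#' [fit_alpha()].
#'
#' @inheritParams bifurcation_scan
#' @return A `tca_grid_predictions` object.
#' @export
alpha_grid_predictions <- function(model, grid_step = 0.001, tol = 1e-12,
                                   max_iter = 10000L) {
  stopifnot(inherits(model, "tca_model"))
  if (!is.numeric(grid_step) || grid_step <= 0 || grid_step > 1) {
    abort("`grid_step` must lie in (0, 1].")
  }
  alphas <- alpha_grid(grid_step)
  # per metabolite: matrix (n_alpha x n_bins) of steady-state proportions
  mats <- setNames(
    lapply(tca_cycle_order, function(met) {
      matrix(0, length(alphas), tca_metabolite_carbons[[met]] + 1L)
    }),
    tca_cycle_order
  )
  for (i in seq_along(alphas)) {
    pred <- predict_isotopologues(model, alphas[i], tol = tol,
                                  max_iter = max_iter)
    for (met in tca_cycle_order) {
      mats[[met]][i, ] <-
        pred$proportion[pred$metabolite == met][order(pred$mass_shift[pred$metabolite == met])]
    }
  }
  structure(
    list(alphas = alphas, proportions = mats, grid_step = grid_step,
         table_checksum = model$table_checksum, tol = tol,
         max_iter = max_iter),
    class = "tca_grid_predictions"
  )
}

#' Fit the labelled acetyl-CoA fraction alpha to measured distributions
#'
#' For each replicate, performs a grid search over alpha followed by a
#' golden-section refinement inside the best grid bracket, minimising the
#' [discrepancy()] between the model's steady-state isotopologue
#' distributions and the measured ones. Ties are broken toward smaller
#' alpha. Replicates are fitted independently and summarised as
#' mean +/- SEM; the percent contribution of the labelled substrate to
#' acetyl-CoA production is `100 * mean(alpha) / labelled_fraction`.
#'
#' @param measurements A data frame of raw peak areas (see
#'   [normalize_measurements()]).
#' @param model A `tca_model`.
#' @param included_metabolites Metabolites used in the fit. Citrate is
#'   typically excluded when heavy labelling makes 6+ amu citrate exceed
#'   the detection range; this is the analyst's call, not an automatic cut.
#' @param labelled_fraction Fraction `f` of the substrate pool that is
#'   uniformly 13C-labelled, in (0, 1\]. The fitted alpha is the labelled
#'   fraction of acetyl-CoA; dividing by `f` converts it to the substrate's
#'   share of acetyl-CoA production.
#' @param grid_step Alpha grid spacing for the initial search.
#' @param refine Run the golden-section refinement (default TRUE).
#' @param grid_predictions Optional precomputed [alpha_grid_predictions()]
#'   for this model and `grid_step`.
#' @param tol,max_iter Steady-state convergence controls.
#' @return A `tca_fit` object. `tidy()` gives per-replicate rows
#'   (`replicate`, `alpha_hat`, `discrepancy`); `glance()` gives the
#'   one-row summary (`alpha_mean`, `alpha_sem`, `contribution_percent`,
#'   `contribution_sem`, `discrepancy_mean`, `n_replicates`,
#'   `contribution_flagged`).
#' @examples
#' tab <- default_transition_table()
#' model <- build_transition_model(tab, enumerate_states(tab))
#' meas <- generate_measurements(model, alpha_true = 0.3, n_replicates = 1,
#'                               noise_cv = 0, seed = 1)
#' fit <- fit_alpha(meas, model, labelled_fraction = 1, grid_step = 0.01)
#' glance(fit)
#' @export
fit_alpha <- function(measurements, model,
                      included_metabolites = tca_cycle_order,
                      labelled_fraction = 1,
                      grid_step = 0.001,
                      refine = TRUE,
                      grid_predictions = NULL,
                      tol = 1e-12, max_iter = 10000L) {
  stopifnot(inherits(model, "tca_model"))
  check_fraction(labelled_fraction, "labelled_fraction", open_lo = TRUE)
  included <- unique(resolve_metabolites(included_metabolites))
  if (length(included) == 0) abort("`included_metabolites` must be non-empty.")

  observed <- normalize_measurements(measurements)
  reps <- unique(observed$replicate)
  if (length(reps) == 0) abort("No replicates found in `measurements`.")
  missing_met <- setdiff(included, unique(observed$metabolite))
  if (length(missing_met) > 0) {
    abort(sprintf(
      "Included metabolite(s) not measured: %s.",
      paste(missing_met, collapse = ", ")
    ))
  }

  if (is.null(grid_predictions)) {
    grid_predictions <- alpha_grid_predictions(
      model, grid_step = grid_step, tol = tol, max_iter = max_iter
    )
  } else {
    stopifnot(inherits(grid_predictions, "tca_grid_predictions"))
    if (!identical(grid_predictions$table_checksum, model$table_checksum)) {
      abort("`grid_predictions` was computed from a different model.")
    }
  }
  alphas <- grid_predictions$alphas

  per_rep <- purrr::map_dfr(reps, function(r) {
    obs <- dplyr::filter(observed, .data$replicate == r)
    obs_vec <- lapply(setNames(included, included), function(met) {
      d <- dplyr::filter(obs, .data$metabolite == met)
      d$proportion[order(d$mass_shift)]
    })
    # vectorised grid objective: mean TV over included metabolites
    grid_d <- Reduce(`+`, lapply(included, function(met) {
      P <- grid_predictions$proportions[[met]]
      0.5 * rowSums(abs(P - rep(obs_vec[[met]], each = nrow(P))))
    })) / length(included)

    best <- which.min(grid_d) # first minimum = smallest alpha on ties
    a_hat <- alphas[best]
    d_hat <- grid_d[best]

    if (refine && length(alphas) > 1) {
      lo <- alphas[max(1L, best - 1L)]
      hi <- alphas[min(length(alphas), best + 1L)]
      obj <- function(a) {
        pred <- predict_isotopologues(model, a, tol = tol,
                                      max_iter = max_iter)
        mean(per_metabolite_discrepancy(pred, obs, included))
      }
      gs <- golden_section(obj, lo, hi)
      # keep the refinement only if it strictly improves; ties -> smaller a
      if (gs$value < d_hat - 1e-15 ||
          (abs(gs$value - d_hat) <= 1e-15 && gs$minimum < a_hat)) {
        a_hat <- gs$minimum
        d_hat <- gs$value
      }
    }

    pred_hat <- predict_isotopologues(model, a_hat, tol = tol,
                                      max_iter = max_iter)
    per_met <- per_metabolite_discrepancy(pred_hat, obs, included)
    tibble::tibble(
      replicate = r,
      alpha_hat = a_hat,
      discrepancy = d_hat,
      per_metabolite = list(per_met)
    )
  })

  alpha_mean <- mean(per_rep$alpha_hat)
  alpha_sem <- if (nrow(per_rep) > 1) {
    sd(per_rep$alpha_hat) / sqrt(nrow(per_rep))
  } else {
    NA_real_
  }
  contribution <- contribution_from_alpha(alpha_mean, labelled_fraction,
                                          warn = FALSE)

  structure(
    list(
      per_replicate = per_rep,
      included_metabolites = included,
      labelled_fraction = labelled_fraction,
      grid_step = grid_predictions$grid_step,
      alpha_mean = alpha_mean,
      alpha_sem = alpha_sem,
      contribution_percent = contribution,
      contribution_sem = if (is.na(alpha_sem)) NA_real_ else
        100 * alpha_sem / labelled_fraction,
      contribution_flagged = contribution > 100,
      discrepancy_mean = mean(per_rep$discrepancy),
      table_checksum = model$table_checksum
    ),
    class = "tca_fit"
  )
}

# Deterministic golden-section minimisation on [lo, hi]; ties resolve toward
# the smaller abscissa because intervals shrink from the right on equality.
golden_section <- function(f, lo, hi, tol = 1e-7, max_iter = 200L) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a)
  x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  it <- 0L
  while (b - a > tol && it < max_iter) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- f(x2)
    }
    it <- it + 1L
  }
  if (f1 <= f2) {
    list(minimum = x1, value = f1)
  } else {
    list(minimum = x2, value = f2)
  }
}

#' Convert a fitted alpha to a percent substrate contribution
#'
#' If a fraction `f` of a substrate pool is uniformly 13C-labelled and the
#' fitted labelled acetyl-CoA fraction is `alpha_hat`, the substrate's
#' relative contribution to acetyl-CoA entering the cycle is
#' `100 * alpha_hat / f` percent (e.g. alpha 0.145 with a quarter of the
#' substrate labelled is a 58.0% contribution). Values above 100% are
#' reported but flagged with a warning: they indicate inconsistent
#' labelling assumptions.
#'
#' @param alpha_hat Fitted labelled acetyl-CoA fraction in \[0, 1\].
#' @param labelled_fraction Labelled fraction `f` of the substrate, (0, 1\].
#' @param warn Emit the >100% warning (default TRUE).
#' @return The percent contribution.
#' @examples
#' contribution_from_alpha(0.145, 0.25)
#' contribution_from_alpha(0.089, 0.25)
#' @export
contribution_from_alpha <- function(alpha_hat, labelled_fraction,
                                    warn = TRUE) {
  check_fraction(alpha_hat, "alpha_hat")
  check_fraction(labelled_fraction, "labelled_fraction", open_lo = TRUE)
  pct <- 100 * alpha_hat / labelled_fraction
  if (warn && pct > 100) {
    warn(sprintf(
      "Contribution %.1f%% exceeds 100%%: labelled-fraction assumptions are inconsistent.",
      pct
    ))
  }
  pct
}

#' @export
print.tca_fit <- function(x, ...) {
  cat(sprintf(
    "<tca_fit> alpha = %.4f%s, discrepancy = %.4f, contribution = %.1f%%%s (n = %d; %s)\n",
    x$alpha_mean,
    if (is.na(x$alpha_sem)) "" else sprintf(" +/- %.4f", x$alpha_sem),
    x$discrepancy_mean,
    x$contribution_percent,
    if (x$contribution_flagged) " [FLAGGED > 100%]" else "",
    nrow(x$per_replicate),
    paste(x$included_metabolites, collapse = ", ")
  ))
  invisible(x)
}

#' @param x A `tca_fit`.
#' @param ... Unused.
#' @rdname fit_alpha
#' @method tidy tca_fit
#' @export
tidy.tca_fit <- function(x, ...) {
  dplyr::select(x$per_replicate, "replicate", "alpha_hat", "discrepancy")
}

#' @rdname fit_alpha
#' @method glance tca_fit
#' @export
glance.tca_fit <- function(x, ...) {
  tibble::tibble(
    alpha_mean = x$alpha_mean,
    alpha_sem = x$alpha_sem,
    contribution_percent = x$contribution_percent,
    contribution_sem = x$contribution_sem,
    contribution_flagged = x$contribution_flagged,
    discrepancy_mean = x$discrepancy_mean,
    n_replicates = nrow(x$per_replicate),
    labelled_fraction = x$labelled_fraction
  )
}
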