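#' Molecule-level Monte-Carlo simulation of label propagation
#'
#' An independent stochastic check on the matrix model: a cohort of
#' molecules starts as all-unlabelled malate and is propagated through
#' full cycle turns. Each turn samples, per molecule, whether the entering
#' acetyl-CoA is \[1,2-13C2\]-labelled (probability `alpha`) and which
#' branch each probabilistic atom-transition takes; carbons are moved by
#' direct column indexing of the bit matrices, never through the
#' enumeration or transition-matrix code. The empirical mass-shift
#' distribution of each tracked metabolite is taken from the snapshots of
#' the final turn.
#'
#' @param table A `tca_table`.
#' @param alpha Labelled acetyl-CoA fraction in \[0, 1\].
#' @param n_molecules Number of molecules tracked (>= 1).
#' @param n_turns Number of full cycle turns (>= 1); distributions converge
#'   to the isotopic steady state as turns accumulate.
#' @param seed Integer seed for the sampler.
#' @return A tibble with columns `metabolite`, `mass_shift`, `proportion`.
#' @examples
#' sim <- simulate_molecules(default_transition_table(), alpha = 0.5,
#'                           n_molecules = 1000, n_turns = 50, seed = 1)
#' @export
simulate_molecules <- function(table, alpha, n_molecules, n_turns, seed) {
  stopifnot(inherits(table, "tca_table"))
  check_fraction(alpha, "alpha")
  if (n_molecules < 1) abort("`n_molecules` must be >= 1.")
  if (n_turns < 1) abort("`n_turns` must be >= 1.")
  n <- as.integer(n_molecules)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old))
  set.seed(as.integer(seed))

  # order reactions around the cycle starting from the malate consumer
  rx_order <- list()
  met <- "malate"
  repeat {
    rx <- reaction_from(table, met)
    rx_order[[length(rx_order) + 1L]] <- rx
    met <- rx$product
    if (met == "malate") break
  }

  bits <- matrix(0L, n, table$metabolites[["malate"]]) # start: malate, unlabelled
  snapshots <- NULL
  for (turn in seq_len(n_turns)) {
    final <- turn == n_turns
    if (final) snapshots <- list(malate = rowSums(bits))
    for (rx in rx_order) {
      acetyl <- cbind(rbinom(n, 1L, alpha))
      acetyl <- cbind(acetyl, acetyl) # both carbons labelled together
      probs <- vapply(rx$branches, function(b) b$probability, numeric(1))
      choice <- if (length(probs) == 1L) {
        rep(1L, n)
      } else {
        1L + findInterval(runif(n), cumsum(probs)[-length(probs)] , left.open = FALSE)
      }
      out <- matrix(0L, n, table$metabolites[[rx$product]])
      for (bi in seq_along(rx$branches)) {
        rows <- choice == bi
        if (!any(rows)) next
        mapping <- rx$branches[[bi]]$mapping
        for (p in seq_along(mapping)) {
          spec <- mapping[[p]]
          out[rows, p] <- if (is.character(spec)) {
            acetyl[rows, match(spec, acetyl_refs)]
          } else {
            bits[rows, as.integer(spec)]
          }
        }
      }
      bits <- out
      if (final && rx$product != "malate") {
        snapshots[[rx$product]] <- rowSums(bits)
      }
    }
  }
  # the malate snapshot must reflect the final turn's product
  snapshots[["malate"]] <- rowSums(bits)

  purrr::map_dfr(tca_cycle_order, function(m) {
    n_c <- table$metabolites[[m]]
    counts <- tabulate(snapshots[[m]] + 1L, nbins = n_c + 1L)
    tibble::tibble(
      metabolite = m, mass_shift = 0:n_c, proportion = counts / n
    )
  })
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate synthetic replicate peak-area tables
#'
#' Emulates per-replicate LC-MS peak-area tables: steady-state isotopologue
#' proportions at `alpha_true` are scaled to a total peak area and
#' perturbed with independent multiplicative log-normal noise per
#' mass-shift bin (peak areas are positive with roughly constant
#' coefficient of variation). Alpha-ketoglutarate rows are emitted under
#' the name "glutamate", mirroring real inputs where glutamate is measured
#' as its proxy. Output is deterministic for a fixed seed; each replicate
#' draws from its own derived substream.
#'
#' @param model A `tca_model`.
#' @param alpha_true True labelled acetyl-CoA fraction.
#' @param n_replicates Number of replicates (>= 1).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0; 0 gives noiseless tables).
#' @param total_area_scale Total peak area per metabolite (arbitrary
#'   units); a single number or a named vector per metabolite.
#' @param seed Integer seed.
#' @param tol,max_iter Steady-state convergence controls.
#' @return A tibble with columns `replicate`, `metabolite`, `mass_shift`,
#'   `peak_area`, suitable for [fit_alpha()] and [write_measurement_csv()].
#' @examples
#' tab <- default_transition_table()
#' model <- build_transition_model(tab, enumerate_states(tab))
#' generate_measurements(model, alpha_true = 0.145, n_replicates = 3,
#'                       noise_cv = 0.05, seed = 42)
#' @export
generate_measurements <- function(model, alpha_true, n_replicates = 3,
                                  noise_cv = 0.05, total_area_scale = 1e6,
                                  seed = 1, tol = 1e-12, max_iter = 10000L) {
  stopifnot(inherits(model, "tca_model"))
  check_fraction(alpha_true, "alpha_true")
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.")
  if (noise_cv < 0) abort("`noise_cv` must be >= 0.")
  if (any(total_area_scale <= 0)) abort("`total_area_scale` must be > 0.")

  scales <- if (is.null(names(total_area_scale))) {
    setNames(rep(total_area_scale[1], 4), tca_cycle_order)
  } else {
    s <- setNames(rep(NA_real_, 4), tca_cycle_order)
    s[resolve_metabolites(names(total_area_scale))] <- total_area_scale
    if (anyNA(s)) abort("`total_area_scale` must cover all four metabolites.")
    s
  }

  pred <- predict_isotopologues(model, alpha_true, tol = tol,
                                max_iter = max_iter)
  sdlog <- sqrt(log(1 + noise_cv^2))

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old))

  purrr::map_dfr(seq_len(n_replicates), function(r) {
    set.seed(replicate_seed(seed, r))
    d <- pred
    noise <- if (noise_cv > 0) {
      rlnorm(nrow(d), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      rep(1, nrow(d))
    }
    d$peak_area <- d$proportion * scales[d$metabolite] * noise
    d$replicate <- r
    d$metabolite[d$metabolite == "alpha_ketoglutarate"] <- "glutamate"
    dplyr::select(d, "replicate", "metabolite", "mass_shift", "peak_area")
  })
}

# Per-replicate substream seed, kept inside the 32-bit integer range.
replicate_seed <- function(seed, replicate) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(replicate)) %%
               .Machine$integer.max)
}
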