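# Shared fixtures, memoised so the enumeration/matrix/grid work is done once
# per test run.
.tt_cache <- new.env(parent = emptyenv())

tt_table <- function() {
  if (is.null(.tt_cache$table)) .tt_cache$table <- default_transition_table()
  .tt_cache$table
}

tt_space <- function() {
  if (is.null(.tt_cache$space)) .tt_cache$space <- enumerate_states(tt_table())
  .tt_cache$space
}

tt_model <- function() {
  if (is.null(.tt_cache$model)) {
    .tt_cache$model <- build_transition_model(tt_table(), tt_space())
  }
  .tt_cache$model
}

# Steady-state prediction grids, keyed by step size.
tt_grid <- function(step = 0.001) {
  key <- paste0("grid_", step)
  if (is.null(.tt_cache[[key]])) {
    .tt_cache[[key]] <- alpha_grid_predictions(tt_model(), grid_step = step)
  }
  .tt_cache[[key]]
}

# Distribution tibble for a single metabolite.
dist_tbl <- function(metabolite, proportions) {
  tibble::tibble(
    metabolite = metabolite,
    mass_shift = seq_along(proportions) - 1L,
    proportion = proportions
  )
}

# Per-metabolite steady-state proportion vector from a prediction tibble.
pred_vec <- function(pred, metabolite) {
  d <- pred[pred$metabolite == metabolite, ]
  d$proportion[order(d$mass_shift)]
}
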