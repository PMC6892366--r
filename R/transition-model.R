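#' Build the isotopomer transition model
#'
#' Constructs the pair of stochastic matrices over the enumerated state
#' space: `M_unlabelled` applies one cycle step with 0-amu acetyl-CoA,
#' `M_labelled` with \[1,2-13C2\]acetyl-CoA. The model for a labelled
#' acetyl-CoA fraction `alpha` is their convex combination
#' `(1 - alpha) * M_unlabelled + alpha * M_labelled`; the acetyl input only
#' enters at citrate formation, so the two matrices differ only in the
#' malate rows. Pool vectors are rows and are updated by right
#' multiplication; each row sends total weight 1 to the states of the
#' source's successor metabolite.
#'
#' @param table A `tca_table`.
#' @param space The `tca_states` enumerated from the same table.
#' @return A `tca_model` object with elements `M_unlabelled`, `M_labelled`,
#'   `space` and `table_checksum`.
#' @examples
#' tab <- default_transition_table()
#' model <- build_transition_model(tab, enumerate_states(tab))
#' @export
build_transition_model <- function(table, space) {
  stopifnot(inherits(table, "tca_table"), inherits(space, "tca_states"))
  if (!identical(space$table_checksum, transition_table_checksum(table))) {
    abort("State space was enumerated from a different transition table.")
  }
  n <- nrow(space$states)
  build_one <- function(acetyl) {
    M <- matrix(0, n, n)
    for (i in seq_len(n)) {
      met <- space$states$metabolite[i]
      bits <- string_to_bits(space$states$labels[i])
      rx <- reaction_from(table, met)
      for (prod in apply_reaction(rx, bits, acetyl)) {
        j <- state_index(space, rx$product, prod$bits)
        M[i, j] <- M[i, j] + prod$probability
      }
    }
    M
  }
  structure(
    list(
      M_unlabelled = build_one(c(0L, 0L)),
      M_labelled = build_one(c(1L, 1L)),
      space = space,
      table_checksum = space$table_checksum
    ),
    class = "tca_model"
  )
}

#' Combine the transition matrices at a given labelled fraction
#'
#' @param model A `tca_model`.
#' @param alpha Fraction of the acetyl-CoA input that is
#'   \[1,2-13C2\]acetyl-CoA, in \[0, 1\].
#' @return The combined square transition matrix.
#' @export
combine_alpha <- function(model, alpha) {
  stopifnot(inherits(model, "tca_model"))
  check_fraction(alpha, "alpha")
  (1 - alpha) * model$M_unlabelled + alpha * model$M_labelled
}

check_fraction <- function(x, name, lo = 0, hi = 1, open_lo = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) ||
      x > hi || x < lo || (open_lo && x == lo)) {
    abort(sprintf(
      "`%s` must be a single number in %s%g, %g].",
      name, if (open_lo) "(" else "[", lo, hi
    ))
  }
  invisible(x)
}

#' @export
print.tca_model <- function(x, ...) {
  cat(sprintf(
    "<tca_model> %d x %d transition matrices (table %s)\n",
    nrow(x$M_unlabelled), ncol(x$M_unlabelled),
    substr(x$table_checksum, 1, 8)
  ))
  invisible(x)
}
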