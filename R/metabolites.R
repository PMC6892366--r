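# Carbon bookkeeping conventions shared across the package.
#
# The four tracked intermediates, in cycle order. All untracked intermediates
# (citrate->isocitrate, alpha-ketoglutarate->succinyl-CoA, succinate->fumarate,
# malate->oxaloacetate) have labelling distributions identical to one of these
# four and are composed into the tracked steps.
tca_metabolite_carbons <- c(
  citrate = 6L,
  alpha_ketoglutarate = 5L,
  succinate = 4L,
  malate = 4L
)

tca_cycle_order <- names(tca_metabolite_carbons)

# glutamate exchanges rapidly with alpha-ketoglutarate, so measured glutamate
# stands in for alpha-ketoglutarate (5 carbons).
measurement_metabolites <- c(tca_cycle_order, "glutamate")

#' Carbon counts of the tracked Krebs-cycle intermediates
#'
#' @return A named integer vector giving the number of carbon atoms of each
#'   tracked metabolite, in cycle order (citrate, alpha_ketoglutarate,
#'   succinate, malate).
#' @examples
#' metabolite_carbons()
#' @export
metabolite_carbons <- function() {
  tca_metabolite_carbons
}

# Resolve user-supplied metabolite names, mapping the glutamate proxy onto
# alpha-ketoglutarate. Errors name the offending value and the allowed set.
resolve_metabolites <- function(x, allow_glutamate = TRUE) {
  allowed <- if (allow_glutamate) measurement_metabolites else tca_cycle_order
  bad <- setdiff(unique(x), allowed)
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown metabolite(s): %s. Allowed: %s.",
      paste(bad, collapse = ", "), paste(allowed, collapse = ", ")
    ))
  }
  ifelse(x == "glutamate", "alpha_ketoglutarate", x)
}

# bits are integer 0/1 vectors, position 1 first; the ordering value treats
# position 1 as the most significant bit.
bits_to_value <- function(bits) {
  sum(bits * 2^(rev(seq_along(bits)) - 1))
}

bits_to_string <- function(bits) {
  paste(bits, collapse = "")
}

string_to_bits <- function(s) {
  as.integer(strsplit(s, "", fixed = TRUE)[[1]])
}

state_key <- function(metabolite, bits) {
  paste0(metabolite, ":", bits_to_string(bits))
}
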