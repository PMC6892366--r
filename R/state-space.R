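#' Enumerate the reachable positional-isotopomer state space
#'
#' Starting from the all-unlabelled state of each tracked metabolite, one
#' cycle turn is applied repeatedly with every admitted acetyl-CoA input
#' (unlabelled and/or \[1,2-13C2\]) and every reaction branch, until no new
#' labelling state appears. States are ordered deterministically: by
#' metabolite in cycle order (citrate, alpha-ketoglutarate, succinate,
#' malate), then by the bit-tuple read as a binary number with carbon 1 as
#' the most significant bit.
#'
#' @param table A `tca_table` (see [default_transition_table()]).
#' @param acetyl_inputs Which acetyl-CoA inputs the closure admits; the
#'   model's alphabet is 0-amu and 2-amu acetyl-CoA only.
#' @return A `tca_states` object; `tidy()` it for a tibble with columns
#'   `index`, `metabolite`, `labels` (the bit-tuple as a string, carbon 1
#'   first) and `mass_shift`.
#' @examples
#' sp <- enumerate_states(default_transition_table())
#' nrow(tidy(sp))
#' @export
enumerate_states <- function(table,
                             acetyl_inputs = c("unlabelled", "labelled")) {
  stopifnot(inherits(table, "tca_table"))
  acetyl_inputs <- match.arg(acetyl_inputs, several.ok = TRUE)
  acetyls <- list(unlabelled = c(0L, 0L), labelled = c(1L, 1L))[acetyl_inputs]

  seen <- new.env(parent = emptyenv())
  queue <- list()
  for (met in tca_cycle_order) {
    bits <- rep(0L, table$metabolites[[met]])
    assign(state_key(met, bits), TRUE, envir = seen)
    queue[[length(queue) + 1L]] <- list(metabolite = met, bits = bits)
  }

  while (length(queue) > 0) {
    st <- queue[[1L]]
    queue <- queue[-1L]
    rx <- reaction_from(table, st$metabolite)
    for (acetyl in acetyls) {
      for (prod in apply_reaction(rx, st$bits, acetyl)) {
        if (prod$probability <= 0) next
        key <- state_key(rx$product, prod$bits)
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          queue[[length(queue) + 1L]] <-
            list(metabolite = rx$product, bits = prod$bits)
        }
      }
    }
  }

  keys <- ls(seen)
  met_of <- sub(":.*$", "", keys)
  bits_of <- sub("^[^:]*:", "", keys)
  ord <- order(
    match(met_of, tca_cycle_order),
    vapply(bits_of, function(s) bits_to_value(string_to_bits(s)), numeric(1))
  )
  states <- tibble::tibble(
    index = seq_along(keys),
    metabolite = met_of[ord],
    labels = bits_of[ord],
    mass_shift = unname(vapply(
      bits_of[ord], function(s) sum(string_to_bits(s)), integer(1)
    ))
  )

  slices <- lapply(split(states$index, states$metabolite), range)
  slices <- slices[tca_cycle_order]
  index_of <- setNames(
    states$index,
    paste0(states$metabolite, ":", states$labels)
  )

  structure(
    list(
      states = states,
      index_of = index_of,
      slices = slices,
      metabolites = table$metabolites,
      acetyl_inputs = acetyl_inputs,
      table_checksum = transition_table_checksum(table)
    ),
    class = "tca_states"
  )
}

#' @export
print.tca_states <- function(x, ...) {
  counts <- table(factor(x$states$metabolite, levels = tca_cycle_order))
  cat(sprintf(
    "<tca_states> %d isotopomers (%s)\n",
    nrow(x$states),
    paste(sprintf("%s: %d", names(counts), counts), collapse = ", ")
  ))
  invisible(x)
}

#' @param x A `tca_states` object.
#' @param ... Unused.
#' @rdname enumerate_states
#' @method tidy tca_states
#' @export
tidy.tca_states <- function(x, ...) {
  x$states
}

# Integer indices of a metabolite's contiguous slice.
slice_indices <- function(space, metabolite) {
  r <- space$slices[[metabolite]]
  seq.int(r[1L], r[2L])
}

state_index <- function(space, metabolite, bits) {
  idx <- space$index_of[[state_key(metabolite, bits)]]
  if (is.null(idx) || is.na(idx)) {
    abort(sprintf(
      "State %s not in the enumerated space: transition table and state space disagree.",
      state_key(metabolite, bits)
    ))
  }
  idx
}

#' Export a state space as delimited text
#'
#' Writes one row per isotopomer (index, metabolite, labels, mass_shift),
#' preceded by comment lines recording the package version and the
#' transition-table checksum.
#'
#' @param space A `tca_states` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_state_space <- function(space, path) {
  stopifnot(inherits(space, "tca_states"))
  write_stamped_csv(space$states, path, space$table_checksum)
}
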