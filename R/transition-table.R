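#' Atom-transition tables
#'
#' An atom-transition table records, for every composed reaction step of the
#' cycle, where each carbon of the product comes from: a numbered carbon of
#' the source metabolite, or one of the two acetyl-CoA carbons (`ACETYL_C1`,
#' the carbonyl carbon; `ACETYL_C2`, the methyl carbon). Source carbons not
#' mapped to the product must be listed as `lost` (released as CO2). A
#' reaction may have several branches with probabilities summing to 1; the
#' default table uses a single 50:50 branch at the succinate -> malate step
#' to encode the positional scrambling caused by the symmetric intermediates
#' succinate and fumarate.
#'
#' @name transition_table
NULL

new_tca_table <- function(metabolites, reactions, schema_version = 1L) {
  structure(
    list(
      schema_version = schema_version,
      metabolites = metabolites,
      reactions = reactions
    ),
    class = "tca_table"
  )
}

#' Built-in atom-transition table for one turn of the Krebs cycle
#'
#' Encodes the carbon fates of one full turn over the four tracked
#' intermediates, with untracked intermediates composed into the tracked
#' steps:
#'
#' * `citrate_synthase` (malate -> citrate, via oxaloacetate): oxaloacetate
#'   carbons o1..o4 plus the two acetyl carbons form citrate as
#'   (c1..c6) = (a1, a2, o2, o3, o4, o1), with c6 the central carboxyl. The
#'   acetyl-derived arm is handled stereospecifically by aconitase (the
#'   Ogston effect), so the acetyl carbons are never among the CO2 released
#'   during the turn they enter.
#' * `isocitrate_dehydrogenase` (citrate -> alpha-ketoglutarate): releases
#'   c6 (the carbon derived from oxaloacetate C1) as CO2;
#'   (k1..k5) = (c5, c4, c3, c2, c1).
#' * `alpha_ketoglutarate_dehydrogenase` (alpha-ketoglutarate -> succinate,
#'   via succinyl-CoA): releases k1 (derived from oxaloacetate C4) as CO2;
#'   (s1..s4) = (k2, k3, k4, k5).
#' * `succinate_to_malate` (via fumarate): because fumarate is symmetric,
#'   the chain is retained or reversed with probability 0.5 each.
#'
#' Malate positions carry over to oxaloacetate unchanged (m = o).
#'
#' @return A `tca_table` object.
#' @examples
#' tab <- default_transition_table()
#' tidy(tab)
#' @seealso [read_transition_table()], [enumerate_states()]
#' @export
default_transition_table <- function() {
  reactions <- list(
    list(
      id = "citrate_synthase",
      source = "malate",
      product = "citrate",
      branches = list(
        list(
          probability = 1,
          mapping = list("ACETYL_C1", "ACETYL_C2", 2L, 3L, 4L, 1L),
          lost = integer(0)
        )
      )
    ),
    list(
      id = "isocitrate_dehydrogenase",
      source = "citrate",
      product = "alpha_ketoglutarate",
      branches = list(
        list(
          probability = 1,
          mapping = list(5L, 4L, 3L, 2L, 1L),
          lost = 6L
        )
      )
    ),
    list(
      id = "alpha_ketoglutarate_dehydrogenase",
      source = "alpha_ketoglutarate",
      product = "succinate",
      branches = list(
        list(
          probability = 1,
          mapping = list(2L, 3L, 4L, 5L),
          lost = 1L
        )
      )
    ),
    list(
      id = "succinate_to_malate",
      source = "succinate",
      product = "malate",
      branches = list(
        list(
          probability = 0.5,
          mapping = list(1L, 2L, 3L, 4L),
          lost = integer(0)
        ),
        list(
          probability = 0.5,
          mapping = list(4L, 3L, 2L, 1L),
          lost = integer(0)
        )
      )
    )
  )
  validate_transition_table(new_tca_table(tca_metabolite_carbons, reactions))
}

acetyl_refs <- c("ACETYL_C1", "ACETYL_C2")

# Enforce the structural invariants: branch probabilities sum to 1, every
# product position assigned exactly once, mapped + lost source positions
# partition the source carbons, and the reactions form the 4-metabolite cycle.
validate_transition_table <- function(table) {
  if (!is.list(table$reactions) || length(table$reactions) == 0) {
    abort("Transition table has no reactions.")
  }
  mets <- table$metabolites
  if (is.null(names(mets)) || !setequal(names(mets), tca_cycle_order)) {
    abort(sprintf(
      "Transition table must declare carbon counts for exactly: %s.",
      paste(tca_cycle_order, collapse = ", ")
    ))
  }
  mets <- vapply(mets, as.integer, integer(1))[tca_cycle_order]
  table$metabolites <- mets

  for (rx in table$reactions) {
    rid <- rx$id %||% "<unnamed>"
    for (field in c("id", "source", "product", "branches")) {
      if (is.null(rx[[field]])) {
        abort(sprintf("Reaction '%s': missing field '%s'.", rid, field))
      }
    }
    if (!rx$source %in% names(mets) || !rx$product %in% names(mets)) {
      abort(sprintf(
        "Reaction '%s': source/product must be tracked metabolites.", rid
      ))
    }
    n_src <- mets[[rx$source]]
    n_prod <- mets[[rx$product]]
    probs <- vapply(rx$branches, function(b) as.numeric(b$probability), numeric(1))
    if (any(probs < 0 | probs > 1) || abs(sum(probs) - 1) > 1e-9) {
      abort(sprintf(
        "Reaction '%s': branch probabilities (%s) must lie in [0,1] and sum to 1.",
        rid, paste(format(probs), collapse = ", ")
      ))
    }
    for (b in rx$branches) {
      mapping <- b$mapping
      if (length(mapping) != n_prod) {
        abort(sprintf(
          "Reaction '%s': branch mapping assigns %d product positions; '%s' has %d carbons.",
          rid, length(mapping), rx$product, n_prod
        ))
      }
      src_used <- integer(0)
      for (p in seq_along(mapping)) {
        spec <- mapping[[p]]
        if (is.character(spec)) {
          if (!spec %in% acetyl_refs) {
            abort(sprintf(
              "Reaction '%s': product position %d maps to unknown source '%s'.",
              rid, p, spec
            ))
          }
        } else {
          s <- as.integer(spec)
          if (is.na(s) || s < 1L || s > n_src) {
            abort(sprintf(
              "Reaction '%s': product position %d maps to invalid source carbon %s.",
              rid, p, format(spec)
            ))
          }
          src_used <- c(src_used, s)
        }
      }
      lost <- as.integer(b$lost %||% integer(0))
      if (any(lost < 1L | lost > n_src)) {
        abort(sprintf("Reaction '%s': lost positions out of range.", rid))
      }
      if (length(intersect(lost, src_used)) > 0) {
        abort(sprintf(
          "Reaction '%s': lost positions overlap mapped positions.", rid
        ))
      }
      accounted <- sort(c(src_used, lost))
      if (!identical(accounted, seq_len(n_src))) {
        abort(sprintf(
          "Reaction '%s': source carbons must each be mapped or lost exactly once (got %s).",
          rid, paste(accounted, collapse = ",")
        ))
      }
    }
  }

  sources <- vapply(table$reactions, `[[`, character(1), "source")
  products <- vapply(table$reactions, `[[`, character(1), "product")
  if (anyDuplicated(sources) || !setequal(sources, names(mets)) ||
      !setequal(products, names(mets))) {
    abort("Reactions must form a single cycle with one reaction per metabolite.")
  }
  table
}

# Reaction whose source is `metabolite`; validation guarantees uniqueness.
reaction_from <- function(table, metabolite) {
  for (rx in table$reactions) {
    if (rx$source == metabolite) return(rx)
  }
  abort(sprintf("No reaction consumes '%s'.", metabolite))
}

# Apply one reaction to a source bit-tuple given the acetyl bit pair.
# Returns a list of (probability, bits) product alternatives.
apply_reaction <- function(reaction, bits, acetyl) {
  lapply(reaction$branches, function(b) {
    out <- integer(length(b$mapping))
    for (p in seq_along(b$mapping)) {
      spec <- b$mapping[[p]]
      out[p] <- if (is.character(spec)) {
        acetyl[match(spec, acetyl_refs)]
      } else {
        bits[as.integer(spec)]
      }
    }
    list(probability = as.numeric(b$probability), bits = out)
  })
}

# Labelled positions of the CO2 released by one reaction application.
lost_labels <- function(reaction, bits) {
  unlist(lapply(reaction$branches, function(b) bits[as.integer(b$lost)]))
}

#' Read or write an atom-transition table
#'
#' Tables are stored as YAML with a `schema_version` field, per-metabolite
#' carbon counts, and one entry per reaction listing its branches, branch
#' probabilities, per-position carbon mappings (`M<i>` for source carbon i,
#' `ACETYL_C1`/`ACETYL_C2` for the acetyl carbons) and lost positions. A
#' table failing any structural invariant is rejected with a message naming
#' the offending reaction.
#'
#' @param path Path to a YAML transition-table document.
#' @return `read_transition_table()` returns a validated `tca_table`;
#'   `write_transition_table()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_transition_table(default_transition_table(), f)
#' identical_table <- read_transition_table(f)
#' @export
read_transition_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  doc <- yaml::read_yaml(path)
  if (is.null(doc$metabolites) || is.null(doc$reactions)) {
    abort("Transition-table document must have 'metabolites' and 'reactions'.")
  }
  reactions <- lapply(doc$reactions, function(rx) {
    rx$branches <- lapply(rx$branches, function(b) {
      b$mapping <- lapply(b$mapping, parse_mapping_entry)
      b$lost <- as.integer(unlist(b$lost) %||% integer(0))
      b
    })
    rx
  })
  validate_transition_table(new_tca_table(
    unlist(doc$metabolites), reactions,
    schema_version = as.integer(doc$schema_version %||% 1L)
  ))
}

parse_mapping_entry <- function(x) {
  if (is.character(x)) {
    if (x %in% acetyl_refs) return(x)
    s <- suppressWarnings(as.integer(sub("^M", "", x)))
    if (!is.na(s)) return(s)
    abort(sprintf("Unparseable mapping entry '%s'.", x))
  }
  as.integer(x)
}

#' @rdname read_transition_table
#' @param table A `tca_table`.
#' @export
write_transition_table <- function(table, path) {
  stopifnot(inherits(table, "tca_table"))
  doc <- list(
    schema_version = table$schema_version,
    metabolites = as.list(table$metabolites),
    reactions = lapply(table$reactions, function(rx) {
      rx$branches <- lapply(rx$branches, function(b) {
        b$mapping <- lapply(b$mapping, function(m) {
          if (is.character(m)) m else paste0("M", m)
        })
        b$lost <- as.list(b$lost)
        b
      })
      rx
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' MD5 checksum of a transition table
#'
#' Used to stamp output files so results can be traced to the exact
#' atom-transition table that produced them.
#'
#' @param table A `tca_table`.
#' @return A length-1 character MD5 digest.
#' @export
transition_table_checksum <- function(table) {
  stopifnot(inherits(table, "tca_table"))
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_transition_table(table, f)
  unname(tools::md5sum(f))
}

#' @export
print.tca_table <- function(x, ...) {
  cat(sprintf(
    "<tca_table> %d reactions over %s (schema v%d)\n",
    length(x$reactions),
    paste(sprintf("%s(%dC)", names(x$metabolites), x$metabolites), collapse = ", "),
    x$schema_version
  ))
  invisible(x)
}

#' Tidy an atom-transition table into one row per carbon assignment
#'
#' @param x A `tca_table`.
#' @param ... Unused.
#' @return A tibble with columns `reaction`, `source`, `product`, `branch`,
#'   `probability`, `product_position`, `source_carbon` (an `M<i>` or
#'   `ACETYL_*` label), and a `lost` column of comma-separated lost source
#'   positions.
#' @method tidy tca_table
#' @export
tidy.tca_table <- function(x, ...) {
  purrr::map_dfr(x$reactions, function(rx) {
    purrr::imap_dfr(rx$branches, function(b, bi) {
      tibble::tibble(
        reaction = rx$id,
        source = rx$source,
        product = rx$product,
        branch = bi,
        probability = as.numeric(b$probability),
        product_position = seq_along(b$mapping),
        source_carbon = vapply(b$mapping, function(m) {
          if (is.character(m)) m else paste0("M", m)
        }, character(1)),
        lost = paste(b$lost, collapse = ",")
      )
    })
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
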