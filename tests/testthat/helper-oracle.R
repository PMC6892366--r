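# Independent brute-force oracle for the default cycle chemistry.
#
# Hard-codes the carbon fates directly on 0/1 vectors, with no use of the
# package's table encoding, enumeration or matrices:
#   citrate   <- (a, a, m2, m3, m4, m1)          acetyl bits enter together
#   alphaKG   <- (c5, c4, c3, c2, c1)            c6 lost as CO2
#   succinate <- (k2, k3, k4, k5)                k1 lost as CO2
#   malate    <- s or rev(s)                     fumarate symmetry
oracle_products <- function(metabolite, bits) {
  switch(metabolite,
    malate = lapply(c(0L, 1L), function(a) {
      list(metabolite = "citrate",
           bits = c(a, a, bits[2], bits[3], bits[4], bits[1]))
    }),
    citrate = list(list(metabolite = "alpha_ketoglutarate",
                        bits = bits[c(5, 4, 3, 2, 1)])),
    alpha_ketoglutarate = list(list(metabolite = "succinate",
                                    bits = bits[2:5])),
    succinate = list(
      list(metabolite = "malate", bits = bits),
      list(metabolite = "malate", bits = rev(bits))
    )
  )
}

# Reachable set by fixed-point growth from the all-unlabelled pools, then a
# membership filter over every candidate bit-tuple (2^6 + 2^5 + 2^4 + 2^4 =
# 128 candidates). Returns sorted "metabolite:bits" keys.
oracle_reachable_states <- function() {
  key <- function(met, bits) paste0(met, ":", paste(bits, collapse = ""))
  carbons <- c(citrate = 6L, alpha_ketoglutarate = 5L,
               succinate = 4L, malate = 4L)
  reached <- new.env(parent = emptyenv())
  for (met in names(carbons)) {
    assign(key(met, rep(0L, carbons[[met]])), list(met, rep(0L, carbons[[met]])),
           envir = reached)
  }
  repeat {
    grew <- FALSE
    for (k in ls(reached)) {
      st <- get(k, envir = reached)
      for (prod in oracle_products(st[[1]], st[[2]])) {
        pk <- key(prod$metabolite, prod$bits)
        if (!exists(pk, envir = reached, inherits = FALSE)) {
          assign(pk, list(prod$metabolite, prod$bits), envir = reached)
          grew <- TRUE
        }
      }
    }
    if (!grew) break
  }
  candidates <- unlist(lapply(names(carbons), function(met) {
    n <- carbons[[met]]
    vapply(0:(2^n - 1), function(v) {
      bits <- as.integer(intToBits(v))[n:1]
      key(met, bits)
    }, character(1))
  }))
  sort(candidates[candidates %in% ls(reached)])
}
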