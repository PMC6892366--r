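test_that("normalisation divides areas by their per-metabolite total", {
  m <- tibble::tibble(
    replicate = 1, metabolite = "malate",
    mass_shift = 0:2, peak_area = c(80, 10, 10)
  )
  d <- normalize_measurements(m)
  expect_equal(d$proportion[d$mass_shift %in% 0:2], c(0.8, 0.1, 0.1))
  # missing shifts filled with zero up to the carbon count
  expect_identical(d$mass_shift, 0:4)
  expect_equal(d$proportion[d$mass_shift %in% 3:4], c(0, 0))
  expect_equal(sum(d$proportion), 1)
})

test_that("a single nonzero area becomes a point mass", {
  m <- tibble::tibble(replicate = 1, metabolite = "succinate",
                      mass_shift = 2, peak_area = 1234.5)
  d <- normalize_measurements(m)
  expect_equal(d$proportion, c(0, 0, 1, 0, 0))
})

test_that("glutamate rows are attributed to alpha-ketoglutarate with 6 bins", {
  m <- tibble::tibble(replicate = 1, metabolite = "glutamate",
                      mass_shift = 0:5, peak_area = c(50, 20, 10, 10, 5, 5))
  d <- normalize_measurements(m)
  expect_setequal(unique(d$metabolite), "alpha_ketoglutarate")
  expect_identical(d$mass_shift, 0:5)
  expect_equal(sum(d$proportion), 1)
})

test_that("degenerate measurement tables are rejected informatively", {
  zero <- tibble::tibble(replicate = 1, metabolite = "malate",
                         mass_shift = 0:2, peak_area = c(0, 0, 0))
  expect_error(normalize_measurements(zero), "zero.*malate")
  heavy <- tibble::tibble(replicate = 1, metabolite = "succinate",
                          mass_shift = 5, peak_area = 10)
  expect_error(normalize_measurements(heavy), "exceeds the carbon count")
  unknown <- tibble::tibble(replicate = 1, metabolite = "fumarate",
                            mass_shift = 0, peak_area = 10)
  expect_error(normalize_measurements(unknown), "fumarate")
})

test_that("discrepancy matches the total-variation formula and its bounds", {
  p <- dist_tbl("malate", c(0.8, 0.2, 0, 0, 0))
  q <- dist_tbl("malate", c(0.6, 0.4, 0, 0, 0))
  expect_equal(discrepancy(p, q, "malate"), 0.2)
  expect_equal(discrepancy(p, p, "malate"), 0)
  a <- dist_tbl("malate", c(1, 0, 0, 0, 0))
  b <- dist_tbl("malate", c(0, 0, 0, 0, 1))
  expect_equal(discrepancy(a, b, "malate"), 1)
  # averaged with equal weight across included metabolites
  p2 <- dplyr::bind_rows(p, dist_tbl("succinate", c(1, 0, 0, 0, 0)))
  q2 <- dplyr::bind_rows(q, dist_tbl("succinate", c(1, 0, 0, 0, 0)))
  expect_equal(discrepancy(p2, q2, c("malate", "succinate")), 0.1)
  expect_error(discrepancy(p, q, "citrate"), "citrate")
})

test_that("discrepancy behaves as a metric on random distributions", {
  set.seed(3)
  for (i in 1:25) {
    r <- function() {
      x <- runif(5)
      dist_tbl("malate", x / sum(x))
    }
    x <- r(); y <- r(); z <- r()
    dxy <- discrepancy(x, y, "malate")
    dyx <- discrepancy(y, x, "malate")
    expect_gte(dxy, 0)
    expect_equal(dxy, dyx)
    expect_lte(
      discrepancy(x, z, "malate"),
      dxy + discrepancy(y, z, "malate") + 1e-12
    )
  }
  x <- dist_tbl("malate", c(0.25, 0.25, 0.25, 0.25, 0))
  expect_equal(discrepancy(x, x, "malate"), 0)
})

test_that("a noiseless forward dataset refits to its generating alpha", {
  model <- tt_model()
  meas <- generate_measurements(model, alpha_true = 0.3, n_replicates = 1,
                                noise_cv = 0, seed = 1)
  fit <- fit_alpha(meas, model, labelled_fraction = 1,
                   grid_predictions = tt_grid(0.01))
  expect_equal(fit$alpha_mean, 0.3, tolerance = 1e-6)
  expect_lt(fit$discrepancy_mean, 1e-9)
  # boundary self-fit
  meas0 <- generate_measurements(model, alpha_true = 0, n_replicates = 1,
                                 noise_cv = 0, seed = 1)
  fit0 <- fit_alpha(meas0, model, labelled_fraction = 1,
                    grid_predictions = tt_grid(0.01))
  expect_equal(fit0$alpha_mean, 0)
})

test_that("the fit is invariant to per-metabolite peak-area scaling", {
  model <- tt_model()
  meas <- generate_measurements(model, alpha_true = 0.45, n_replicates = 1,
                                noise_cv = 0.05, seed = 5)
  fit1 <- fit_alpha(meas, model, labelled_fraction = 1,
                    grid_predictions = tt_grid(0.01))
  scaled <- meas
  scaled$peak_area <- scaled$peak_area *
    c(citrate = 1e3, glutamate = 0.01, succinate = 7, malate = 1)[scaled$metabolite]
  fit2 <- fit_alpha(scaled, model, labelled_fraction = 1,
                    grid_predictions = tt_grid(0.01))
  expect_equal(fit2$alpha_mean, fit1$alpha_mean, tolerance = 1e-12)
  expect_equal(fit2$discrepancy_mean, fit1$discrepancy_mean, tolerance = 1e-12)
})

test_that("on noiseless data the grid objective has a single global basin", {
  model <- tt_model()
  gp <- tt_grid(0.01)
  obs <- predict_isotopologues(model, 0.4)
  grid_d <- vapply(gp$alphas, function(a) {
    pred <- tibble::tibble(
      metabolite = rep(names(metabolite_carbons()),
                       metabolite_carbons() + 1L),
      mass_shift = unlist(lapply(metabolite_carbons(), seq.int, from = 0)),
      proportion = unlist(lapply(names(metabolite_carbons()), function(m) {
        gp$proportions[[m]][which(gp$alphas == a), ]
      }))
    )
    discrepancy(pred, obs)
  }, numeric(1))
  best <- which.min(grid_d)
  expect_equal(gp$alphas[best], 0.4)
  # discrepancy rises monotonically away from the optimum on each side
  expect_false(is.unsorted(grid_d[best:length(grid_d)]))
  expect_false(is.unsorted(rev(grid_d[1:best])))
})

test_that("replicates are fitted independently and summarised as mean +/- SEM", {
  model <- tt_model()
  meas <- generate_measurements(model, alpha_true = 0.25, n_replicates = 4,
                                noise_cv = 0.05, seed = 9)
  fit <- fit_alpha(meas, model, labelled_fraction = 0.5,
                   grid_predictions = tt_grid(0.01))
  per <- tidy(fit)
  expect_identical(nrow(per), 4L)
  expect_equal(fit$alpha_mean, mean(per$alpha_hat))
  expect_equal(fit$alpha_sem, sd(per$alpha_hat) / 2)
  g <- glance(fit)
  expect_equal(g$contribution_percent, 100 * fit$alpha_mean / 0.5)
  expect_equal(g$contribution_sem, 100 * fit$alpha_sem / 0.5)
})

test_that("fits can use any single metabolite (glutamate aliased to aKG)", {
  model <- tt_model()
  meas <- generate_measurements(model, alpha_true = 0.35, n_replicates = 1,
                                noise_cv = 0, seed = 2)
  for (met in c("malate", "glutamate", "succinate", "citrate")) {
    fit <- fit_alpha(meas, model, included_metabolites = met,
                     labelled_fraction = 1, grid_predictions = tt_grid(0.01))
    expect_equal(fit$alpha_mean, 0.35, tolerance = 1e-5)
  }
  expect_error(
    fit_alpha(meas[meas$metabolite != "citrate", ], model,
              included_metabolites = "citrate", labelled_fraction = 1,
              grid_predictions = tt_grid(0.01)),
    "not measured"
  )
})

test_that("contribution arithmetic scales alpha by the labelled fraction", {
  expect_equal(contribution_from_alpha(0.145, 0.25), 58.0)
  expect_equal(contribution_from_alpha(0.089, 0.25), 35.6)
  expect_equal(contribution_from_alpha(0, 0.7), 0)
  expect_warning(contribution_from_alpha(0.5, 0.25), "exceeds 100")
  expect_error(contribution_from_alpha(0.1, 0), "labelled_fraction")
})
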