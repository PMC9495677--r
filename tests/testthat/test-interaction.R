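test_that("theoretical additive values are the mean of individual activities", {
  expect_equal(theoretical_mixture_value(c(282, 294)), 288)
  expect_equal(theoretical_mixture_value(c(33, 45)), 39)
  expect_equal(theoretical_mixture_value(c(282, 294, 494, 193, 245)), 301.6)

  withr::with_seed(7, {
    for (i in 1:20) {
      v <- runif(1, 1, 1000)
      k <- sample(2:5, 1)
      expect_equal(theoretical_mixture_value(rep(v, k)), v)
    }
  })

  expect_error(theoretical_mixture_value(c(1, 2), k = 3), "equal")
  expect_error(theoretical_mixture_value(5), "at least 2")
  expect_error(theoretical_mixture_value(c(1, Inf)), "finite")
})

test_that("the difference-(%) index behaves as the relative departure from additivity", {
  expect_equal(difference_percent(520, 288), 80.5555555, tolerance = 1e-7)
  expect_equal(format_difference(difference_percent(520, 288)), "81")
  expect_equal(format_difference(difference_percent(74, 68)), "8.8")
  expect_equal(format_difference(difference_percent(229, 343.5)), "-33")

  withr::with_seed(8, {
    e <- runif(50, 1, 5000)
    expect_equal(difference_percent(e, e), rep(0, 50))
  })

  expect_error(difference_percent(100, 0), "theoretical")
  expect_error(difference_percent(100, -5), "theoretical")
  expect_error(difference_percent(-1, 100), ">= 0")
})

test_that("classification uses an inclusive additive band", {
  expect_equal(
    classify_interaction(c(81, 4.0, -58, 5, -5, 5.01, -5.01)),
    c("synergistic", "additive", "antagonistic", "additive", "additive",
      "synergistic", "antagonistic")
  )
  # a zero-width band makes any departure an interaction
  cfg0 <- interaction_config(additive_band_pct = 0)
  expect_equal(classify_interaction(c(0.1, 0, -0.1), cfg0),
               c("synergistic", "additive", "antagonistic"))
  expect_error(interaction_config(-1), ">= 0")
  expect_error(classify_interaction(NaN), "finite")
})

test_that("reporting convention rounds half away from zero with mixed precision", {
  expect_equal(round_half_away(c(2.5, -12.5, 80.5, -3.05), 0), c(3, -13, 81, -3))
  expect_equal(round_half_away(c(-3.05, 1.25), 1), c(-3.1, 1.3))
  expect_equal(format_difference(c(3.985, -3.084, 45.56)), c("4.0", "-3.1", "46"))
})

test_that("mean-based refactoring agrees with the per-k literal formulas to 1e-9", {
  # direct transcription: each individual contributes value/k, and the
  # index divides the combination by their sum
  direct <- function(e, v) {
    k <- length(v)
    switch(as.character(k),
      "2" = (e * 100) / (v[1] / 2 + v[2] / 2) - 100,
      "3" = (e * 100) / (v[1] / 3 + v[2] / 3 + v[3] / 3) - 100,
      "4" = (e * 100) / (v[1] / 4 + v[2] / 4 + v[3] / 4 + v[4] / 4) - 100,
      "5" = (e * 100) / (v[1] / 5 + v[2] / 5 + v[3] / 5 + v[4] / 5 + v[5] / 5) - 100
    )
  }
  withr::with_seed(123, {
    for (i in 1:1000) {
      k <- sample(2:5, 1)
      v <- runif(k, 1, 5000)
      e <- runif(1, 1, 5000)
      expect_equal(
        difference_percent(e, theoretical_mixture_value(v)),
        direct(e, v),
        tolerance = 1e-9
      )
    }
  })
})

test_that("difference is scale invariant and symmetric in the components", {
  withr::with_seed(99, {
    for (i in 1:50) {
      k <- sample(2:5, 1)
      v <- runif(k, 1, 1000)
      e <- runif(1, 1, 1000)
      c_scale <- runif(1, 0.01, 100)
      d0 <- difference_percent(e, theoretical_mixture_value(v))
      expect_equal(
        difference_percent(c_scale * e, theoretical_mixture_value(c_scale * v)),
        d0,
        tolerance = 1e-9
      )
      expect_equal(
        difference_percent(e, theoretical_mixture_value(sample(v))),
        d0,
        tolerance = 1e-12
      )
    }
  })
})

test_that("delta-method uncertainty is zero without noise, scale invariant, and matches Monte Carlo", {
  expect_equal(difference_uncertainty(520, 0, 3, c(282, 294), c(0, 0), 3), 0)

  sd1 <- difference_uncertainty(520, 6, 3, c(282, 294), c(5, 4), 3)
  sd2 <- difference_uncertainty(5200, 60, 3, c(2820, 2940), c(50, 40), 3)
  expect_equal(sd1, sd2, tolerance = 1e-12)

  # Monte-Carlo oracle: resample the means from their standard errors
  withr::with_seed(2024, {
    e_mean <- 520; e_sd <- 6; n <- 3
    means <- c(282, 294); sds <- c(5, 4)
    draws <- replicate(1e5, {
      e <- rnorm(1, e_mean, e_sd / sqrt(n))
      v <- rnorm(2, means, sds / sqrt(n))
      100 * e / mean(v) - 100
    })
    expect_equal(
      difference_uncertainty(e_mean, e_sd, n, means, sds, n),
      sd(draws),
      tolerance = 0.05
    )
  })

  expect_error(difference_uncertainty(520, -1, 3, c(282, 294), c(5, 4), 3), ">= 0")
})

test_that("analyze_panel joins mixtures to individuals and reproduces the index", {
  ind <- tibble::tibble(
    analyte = c("A", "B", "C"), assay = "FRAP", concentration_um = 100,
    mean = c(282, 294, 494), sd = c(5, 4, 3), n = 3L
  )
  mix <- tibble::tibble(
    analyte = c("B+A", "A+B+C"), assay = "FRAP", concentration_um = 100,
    mean = c(520, 600), sd = c(2, 3), n = 3L
  )
  res <- analyze_panel(ind, mix)
  expect_equal(res$mixture, c("A+B", "A+B+C"))
  expect_equal(res$theoretical, c(288, (282 + 294 + 494) / 3))
  expect_equal(res$difference_pct[1], 80.5555555, tolerance = 1e-7)
  expect_equal(res$classification[1], "synergistic")
  expect_false(anyNA(res$difference_sd))

  # additive null: experimental pinned at theoretical => all additive, 0
  null_mix <- tibble::tibble(
    analyte = c("A+B", "A+C", "B+C", "A+B+C"), assay = "FRAP",
    concentration_um = 100,
    mean = c(288, 388, 394, (282 + 294 + 494) / 3)
  )
  null_res <- analyze_panel(ind, null_mix)
  expect_equal(null_res$difference_pct, rep(0, 4))
  expect_true(all(null_res$classification == "additive"))

  # order of components in the measurement label is irrelevant
  res_perm <- analyze_panel(
    ind, dplyr::mutate(mix, analyte = c("A+B", "C+B+A"))
  )
  expect_equal(res_perm$difference_pct, res$difference_pct)

  # scale invariance through the full pipeline
  res_scaled <- analyze_panel(
    dplyr::mutate(ind, mean = mean * 37.5, sd = sd * 37.5),
    dplyr::mutate(mix, mean = mean * 37.5, sd = sd * 37.5)
  )
  expect_equal(res_scaled$difference_pct, res$difference_pct, tolerance = 1e-12)
  expect_equal(res_scaled$classification, res$classification)

  expect_error(
    analyze_panel(ind, tibble::tibble(
      analyte = "A+Z", assay = "FRAP", concentration_um = 100, mean = 100
    )),
    "'Z'.*FRAP.*100"
  )
  expect_warning(
    analyze_panel(dplyr::bind_rows(ind, ind[1, ]), mix),
    "duplicate"
  )
  empty <- analyze_panel(ind, mix[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("concentration trends flag strict dilution-dependent decreases", {
  res <- tibble::tibble(
    mixture = "C+R+pC", assay = "FRAP",
    concentration_um = c(500, 100, 1000),
    difference_pct = c(48, 127, 11),
    classification = c("synergistic", "synergistic", "synergistic")
  )
  tr <- concentration_trend(res)
  expect_true(tr$monotone_decrease)
  expect_equal(tr$trend$concentration_um, c(100, 500, 1000))
  expect_equal(tr$trend$difference_pct, c(127, 48, 11))

  flat <- dplyr::mutate(res, difference_pct = 5)
  expect_false(concentration_trend(flat)$monotone_decrease)

  expect_error(concentration_trend(res[1, ]), ">= 2")
  expect_error(
    concentration_trend(dplyr::mutate(res, mixture = c("a", "b", "c"))),
    "one mixture"
  )
})
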