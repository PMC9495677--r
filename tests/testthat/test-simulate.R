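test_that("the generator is deterministic and linear in concentration", {
  spec <- simulation_spec(seed = 42)
  a <- gen_individual_measurements(spec)
  b <- gen_individual_measurements(spec)
  expect_identical(a, b)
  m1 <- gen_mixture_measurements(spec)
  m2 <- gen_mixture_measurements(spec)
  expect_identical(m1, m2)

  quiet <- simulation_spec(seed = 1, noise_cv = 0)
  ind <- summarize_measurements(gen_individual_measurements(quiet))
  g100 <- dplyr::filter(ind, analyte == "G", concentration_um == 100)
  expect_equal(g100$mean, default_slopes()[["G"]] * 100)
  expect_equal(g100$sd, 0)
  g1000 <- dplyr::filter(ind, analyte == "G", concentration_um == 1000)
  expect_equal(g1000$mean, 10 * g100$mean)
})

test_that("injected interaction effects invert exactly in the noiseless limit", {
  base_interaction <- tibble::tibble(
    mixture = c("Ge+P", "G+P"), delta_pct = c(81, -33)
  )
  spec <- simulation_spec(
    seed = 3, noise_cv = 0,
    slopes = default_slopes()[c("P", "Ge", "G", "V", "Sy")],
    interaction = base_interaction
  )
  study <- simulate_study(spec)
  res <- study$results
  expect_equal(nrow(res), 26 * 3)

  pge <- dplyr::filter(res, mixture == "Ge+P")
  expect_equal(pge$difference_pct, rep(81, 3), tolerance = 1e-9)
  expect_true(all(pge$classification == "synergistic"))
  gp <- dplyr::filter(res, mixture == "G+P")
  expect_equal(gp$difference_pct, rep(-33, 3), tolerance = 1e-9)

  # delta = 0 reproduces the additive null everywhere else
  rest <- dplyr::filter(res, !mixture %in% c("Ge+P", "G+P"))
  expect_equal(rest$difference_pct, rep(0, nrow(rest)), tolerance = 1e-9)
  expect_true(all(rest$classification == "additive"))

  expect_error(
    gen_mixture_measurements(
      spec, tibble::tibble(mixture = "P+Zz")
    ),
    "unknown"
  )
  expect_error(
    simulation_spec(seed = 1, interaction = tibble::tibble(
      mixture = "P+Ge", delta_pct = -100
    )),
    "-100"
  )
})

test_that("false-positive rate of the additive band matches a direct Monte-Carlo estimate", {
  # implementation route: delta = 0, cv = 0.03 binary mixtures through the
  # full generate -> summarize -> analyze pipeline
  slopes <- default_slopes()
  n_runs <- 23 # x 45 binaries = 1035 simulated mixtures
  classified <- unlist(lapply(seq_len(n_runs), function(s) {
    spec <- simulation_spec(
      seed = 1000 + s, slopes = slopes, concentrations_um = 100,
      noise_cv = 0.03
    )
    study <- simulate_study(
      spec, enumerate_equimolar_mixtures(names(slopes), 2)
    )
    study$results$classification
  }))
  p_impl <- mean(classified != "additive")

  # oracle route: simulate the index distribution directly from its
  # definition, without the measurement pipeline
  pairs <- utils::combn(names(slopes), 2, simplify = FALSE)
  p_mc <- withr::with_seed(777, {
    mean(vapply(pairs, function(pr) {
      t_true <- mean(slopes[pr]) * 100
      n_draw <- 4000
      e_obs <- t_true * (1 + rnorm(n_draw, 0, 0.03 / sqrt(3)))
      t_obs <- (slopes[pr[1]] * 100 * (1 + rnorm(n_draw, 0, 0.03 / sqrt(3))) +
                  slopes[pr[2]] * 100 * (1 + rnorm(n_draw, 0, 0.03 / sqrt(3)))) / 2
      mean(abs(100 * e_obs / t_obs - 100) > 5)
    }, numeric(1)))
  })
  expect_lt(abs(p_impl - p_mc), 0.02)
})

test_that("synthetic ORAC plates reduce back to their programmed TE values", {
  plate <- gen_orac_plate(te = c(G = 28, R = 92, V = 56))
  red <- reduce_orac_plate(plate$kinetics)
  expect_equal(red$curve$r_squared, 1, tolerance = 1e-9)
  expect_equal(
    red$te$te_um[match(plate$truth$analyte, red$te$analyte)],
    plate$truth$te_um,
    tolerance = 1e-6
  )

  # a blank-equivalent sample has zero net AUC hence 0 uM TE
  blank_plate <- gen_orac_plate(te = c(zero = 0))
  red0 <- reduce_orac_plate(blank_plate$kinetics)
  expect_equal(red0$te$te_um, 0, tolerance = 1e-6)
  expect_equal(red0$te$net_auc, 0, tolerance = 1e-9)

  # a sample constructed to share a ladder point's net AUC recovers that
  # ladder concentration
  shared <- gen_orac_plate(te = c(match50 = 50),
                           trolox_ladder_um = c(0, 10, 25, 50, 100))
  red50 <- reduce_orac_plate(shared$kinetics)
  expect_equal(red50$te$te_um, 50, tolerance = 1e-6)
})

test_that("a full synthetic plate recovers the injected interaction end to end", {
  # programme individual TE values and a mixture inflated by a known delta
  te_ind <- c(P = 57, Ge = 53)
  delta <- 40
  te_mix <- mean(te_ind) * (1 + delta / 100)
  plate <- gen_orac_plate(te = c(te_ind, `Ge+P` = unname(te_mix)))
  red <- reduce_orac_plate(plate$kinetics)

  measured <- red$te |>
    dplyr::transmute(
      analyte = analyte, assay = "ORAC", concentration_um = 5,
      mean = te_um, sd = 0, n = 1L
    )
  res <- analyze_panel(
    dplyr::filter(measured, analyte %in% names(te_ind)),
    dplyr::filter(measured, analyte == "Ge+P")
  )
  expect_equal(res$difference_pct, delta, tolerance = 1e-5)
  expect_equal(res$classification, "synergistic")
})
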