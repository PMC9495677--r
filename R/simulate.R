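#' Default linear dose-response slopes for the study panel
#'
#' Activity per uM of analyte for each panel compound, matching the
#' magnitude of the observed FRAP responses at the top of the assay range
#' (e.g. gallic acid ~5 uM Fe2+ per uM). Used as generator defaults so
#' simulated studies live on the same scale as real ones.
#'
#' @return Named numeric vector of slopes.
#' @export
default_slopes <- function() {
  c(P = 2.341, Ge = 3.186, G = 5.033, V = 0.850, Sy = 3.207,
    pC = 0.113, C = 2.125, F = 1.706, Si = 2.186, R = 3.656)
}

#' Specification of a simulated mixture study
#'
#' Fixes everything a simulated study needs: the per-compound linear
#' dose-response slopes, the concentration grid, triplicate multiplicative
#' Gaussian noise, and the interaction effects to inject. Identical specs
#' (including the seed) yield byte-identical outputs. One master seed is
#' supplied; each generated table uses a child seed derived as
#' `(seed * 7 + offset) mod (2^31 - 1)` with offsets 1 (individuals),
#' 2 (mixtures) and 3 (ORAC plate), so tables can be regenerated
#' independently.
#'
#' @param seed Integer master seed.
#' @param slopes Named vector of activity-per-uM slopes (> 0), one per
#'   compound; defaults to [default_slopes()].
#' @param concentrations_um Concentration grid (default the FRAP grid
#'   100/500/1000 uM).
#' @param n_replicates Replicates per well (default 3, the study's
#'   triplicates).
#' @param noise_cv Multiplicative replicate coefficient of variation
#'   (default 0.03, matching the relative spread of the printed replicate
#'   SDs).
#' @param interaction Tibble with columns `mixture` (label, any component
#'   order) and `delta_pct` (injected interaction effect, > -100; 0 =
#'   additive null). Mixtures not listed get delta 0.
#' @param assay Assay tag for generated measurements.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(seed, slopes = default_slopes(),
                            concentrations_um = c(100, 500, 1000),
                            n_replicates = 3, noise_cv = 0.03,
                            interaction = NULL, assay = "FRAP") {
  check_assay(assay)
  if (is.null(names(slopes)) || any(names(slopes) == "")) {
    abort("slopes must be a named vector (one entry per compound)")
  }
  if (any(slopes <= 0)) abort("slopes must be > 0")
  if (noise_cv < 0) abort("noise_cv must be >= 0")
  if (is.null(interaction)) {
    interaction <- tibble::tibble(mixture = character(), delta_pct = numeric())
  }
  if (any(interaction$delta_pct <= -100)) {
    abort("injected effects must be > -100 (activity cannot go negative)")
  }
  interaction$mixture <- mixture_label(mixture_components(interaction$mixture))
  structure(
    list(
      seed = as.integer(seed), slopes = slopes,
      concentrations_um = concentrations_um,
      n_replicates = as.integer(n_replicates), noise_cv = noise_cv,
      interaction = interaction, assay = assay
    ),
    class = "simulation_spec"
  )
}

child_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7 + offset) %% (2^31 - 1))
}

sim_delta <- function(spec, label) {
  hit <- match(label, spec$interaction$mixture)
  ifelse(is.na(hit), 0, spec$interaction$delta_pct[hit])
}

#' Simulate single-compound measurements
#'
#' For compound i at concentration C, replicate values are
#' `slope_i * C * (1 + eps)` with `eps ~ Normal(0, noise_cv)`: linear
#' concentration-response with multiplicative replicate noise.
#'
#' @param spec A [simulation_spec()].
#' @return Long replicate tibble (`analyte`, `assay`, `concentration_um`,
#'   `replicate_index`, `value`, `units`).
#' @export
gen_individual_measurements <- function(spec) {
  grid <- tidyr::expand_grid(
    analyte = names(spec$slopes),
    concentration_um = spec$concentrations_um,
    replicate_index = seq_len(spec$n_replicates)
  )
  eps <- withr::with_seed(
    child_seed(spec$seed, 1),
    rnorm(nrow(grid), 0, spec$noise_cv)
  )
  grid |>
    dplyr::mutate(
      assay = spec$assay,
      value = spec$slopes[.data$analyte] * .data$concentration_um * (1 + eps),
      units = activity_units(spec$assay)
    ) |>
    dplyr::select(
      "analyte", "assay", "concentration_um", "replicate_index",
      "value", "units"
    )
}

#' Simulate equimolar mixture measurements
#'
#' The noiseless mixture mean is the expected additive value inflated or
#' deflated by the injected effect:
#' `(sum_i slope_i * C / k) * (1 + delta/100)`; replicate noise is then
#' applied multiplicatively on top. The effect is injected on the mixture
#' mean (not per replicate), so delta is exactly identifiable in the
#' noiseless limit.
#'
#' @param spec A [simulation_spec()].
#' @param mixtures Tibble with a `mixture` label column (and optionally
#'   `k`/`components`), e.g. from [enumerate_equimolar_mixtures()];
#'   defaults to all binary-through-quinary combinations of the spec's
#'   compounds when the panel has 5 or fewer members, otherwise all
#'   binaries.
#' @return Long replicate tibble as in [gen_individual_measurements()].
#' @export
gen_mixture_measurements <- function(spec, mixtures = NULL) {
  ids <- names(spec$slopes)
  if (is.null(mixtures)) {
    kmax <- min(5, length(ids))
    mixtures <- enumerate_equimolar_mixtures(
      ids, if (length(ids) <= 5) 2:kmax else 2
    )
  }
  comps <- mixture_components(mixtures$mixture)
  unknown <- setdiff(unique(unlist(comps)), ids)
  if (length(unknown) > 0) {
    abort(paste0("unknown mixture component(s): ",
                 paste(unknown, collapse = ", ")))
  }
  grid <- tidyr::expand_grid(
    mixture = mixture_label(comps),
    concentration_um = spec$concentrations_um,
    replicate_index = seq_len(spec$n_replicates)
  )
  eps <- withr::with_seed(
    child_seed(spec$seed, 2),
    rnorm(nrow(grid), 0, spec$noise_cv)
  )
  comp_list <- mixture_components(grid$mixture)
  truth <- vapply(seq_len(nrow(grid)), function(i) {
    ki <- length(comp_list[[i]])
    theo <- sum(spec$slopes[comp_list[[i]]]) * grid$concentration_um[i] / ki
    theo * (1 + sim_delta(spec, grid$mixture[i]) / 100)
  }, numeric(1))
  grid |>
    dplyr::mutate(
      analyte = .data$mixture,
      assay = spec$assay,
      value = truth * (1 + eps),
      units = activity_units(spec$assay)
    ) |>
    dplyr::select(
      "analyte", "assay", "concentration_um", "replicate_index",
      "value", "units"
    )
}

#' Simulate a study and analyze it in one call
#'
#' Generates individual and mixture replicates from `spec`, summarizes
#' them, and runs [analyze_panel()].
#'
#' @param spec A [simulation_spec()].
#' @param mixtures Passed to [gen_mixture_measurements()].
#' @param config Passed to [analyze_panel()].
#' @return A list: `individuals`, `mixtures` (summary tibbles) and
#'   `results` (the interaction analysis).
#' @export
simulate_study <- function(spec, mixtures = NULL,
                           config = interaction_config()) {
  ind <- summarize_measurements(gen_individual_measurements(spec))
  mix <- summarize_measurements(gen_mixture_measurements(spec, mixtures))
  list(
    individuals = ind,
    mixtures = mix,
    results = analyze_panel(ind, mix, config)
  )
}

#' Simulate an ORAC kinetic plate with programmed TE values
#'
#' Builds fluorescein-like exponential decay traces `f(t) = exp(-lambda t)`
#' over an 80-minute window: a blank (fast decay), a Trolox ladder, and
#' sample wells. Decay rates are chosen numerically so that each well's
#' blank-relative net AUC on the sampling grid is exactly linear in its
#' programmed Trolox-equivalent value (`net_auc = te_slope * TE`), which
#' makes the plate an exact fixture for the reduction pipeline: reducing
#' it with [reduce_orac_plate()] recovers the programmed TE values.
#'
#' @param te Named numeric vector of programmed sample activities in uM TE.
#' @param trolox_ladder_um Ladder concentrations (default 0-100 uM).
#' @param te_slope Net AUC per uM TE (default 0.4 relative-units x min).
#' @param lambda_blank Blank decay rate per minute (default 0.2).
#' @param time_step_min Sampling interval (default 1 min over 0-80).
#' @param fluorescence_noise_sd Additive Gaussian noise on readings
#'   (default 0: exact plate).
#' @param seed Seed for the optional noise.
#' @return A list: `kinetics` (long tibble: `well`, `role`, `analyte`,
#'   `trolox_um`, `time_min`, `fluorescence`) and `truth` (tibble:
#'   `analyte`, `te_um`).
#' @export
gen_orac_plate <- function(te, trolox_ladder_um = c(0, 10, 25, 50, 100),
                           te_slope = 0.4, lambda_blank = 0.2,
                           time_step_min = 1, fluorescence_noise_sd = 0,
                           seed = 1L) {
  if (is.null(names(te)) && length(te) > 0) {
    names(te) <- paste0("S", seq_along(te))
  }
  times <- seq(0, 80, by = time_step_min)
  grid_auc <- function(lambda) pracma::trapz(times, exp(-lambda * times))
  auc_blank <- grid_auc(lambda_blank)
  auc_max <- 80
  lambda_for_auc <- function(target) {
    if (target >= auc_max) abort("target AUC exceeds the 80-min window")
    if (target <= 0) abort("target AUC must be positive")
    stats::uniroot(
      function(l) grid_auc(l) - target,
      lower = 1e-9, upper = 60, tol = 1e-13
    )$root
  }
  wells <- dplyr::bind_rows(
    tibble::tibble(
      well = "blank1", role = "blank", analyte = NA_character_,
      trolox_um = NA_real_, lambda = lambda_blank
    ),
    tibble::tibble(
      well = paste0("std", seq_along(trolox_ladder_um)),
      role = "trolox_standard", analyte = NA_character_,
      trolox_um = trolox_ladder_um,
      lambda = vapply(trolox_ladder_um, function(cc) {
        lambda_for_auc(auc_blank + te_slope * cc)
      }, numeric(1))
    ),
    tibble::tibble(
      well = paste0("smp", seq_along(te)),
      role = "sample", analyte = names(te), trolox_um = NA_real_,
      lambda = vapply(unname(te), function(v) {
        lambda_for_auc(auc_blank + te_slope * v)
      }, numeric(1))
    )
  )
  kinetics <- tidyr::expand_grid(wells, time_min = times) |>
    dplyr::mutate(fluorescence = exp(-.data$lambda * .data$time_min)) |>
    dplyr::select(
      "well", "role", "analyte", "trolox_um", "time_min", "fluorescence"
    )
  if (fluorescence_noise_sd > 0) {
    noise <- withr::with_seed(
      child_seed(seed, 3),
      rnorm(nrow(kinetics), 0, fluorescence_noise_sd)
    )
    kinetics$fluorescence <- pmax(0, kinetics$fluorescence + noise)
  }
  list(
    kinetics = kinetics,
    truth = tibble::tibble(analyte = names(te), te_um = unname(te))
  )
}
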