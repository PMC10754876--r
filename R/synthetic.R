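# Synthetic gait-cohort generator with planted ground truth.
#
# Each patient deviates from the normative reference along a smooth,
# patient-specific harmonic shape normalized to unit GPS, scaled by a
# severity (degrees). Severity evolves multiplicatively between sessions
# (improve: divide by a progression factor; worsen: multiply), which drives
# the sign of the session-to-session GPS change the pipeline is asked to
# recover.

#' Synthetic cohort configuration
#'
#' Defaults emulate the structure of a clinical motion-laboratory database:
#' about two sessions per patient, about 18 cycles per session (sd 6),
#' roughly 79% of sessions walked without equipment, and consecutive
#' sessions separated by about 740 days.
#'
#' @param n_patients Number of patients (>= 3).
#' @param max_sessions Truncation for the per-patient session count, drawn as
#'   `1 + Poisson(1)` truncated at this value. Default 5.
#' @param cycles_mean,cycles_sd Normal parameters for the per-session cycle
#'   count (rounded, clipped to 5..40). Defaults 18 and 6.
#' @param deviation_scale_range Degrees interval the patient baseline
#'   severity is drawn from (uniform). Default `c(2, 15)`.
#' @param improve_probability Probability a session transition improves when
#'   `improve_rule = "random"`. Default 0.5.
#' @param improve_rule `"random"`: transition directions are independent
#'   coin flips, so progression carries no signal readable from the current
#'   cycles (a null cohort). `"severity_threshold"`: a session improves iff
#'   its severity exceeds the midpoint of `deviation_scale_range`
#'   (regression-to-threshold), planting a progression signal that is
#'   predictable from the observable gait deviation.
#' @param progression_range Range of the multiplicative severity-change
#'   factor, drawn log-uniformly. Default `c(1.1, 1.6)`.
#' @param cycle_noise_sd Per-sample Gaussian noise added to every cycle value
#'   (degrees). Default 1.
#' @param equipment_none_probability Probability a session is equipment-free.
#'   Default 0.79.
#' @param session_gap_mean,session_gap_sd Days between consecutive sessions
#'   (Normal, clipped at >= 4). Defaults 740 and 577.
#' @param seed Integer seed; all randomness derives from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 50L,
                          max_sessions = 5L,
                          cycles_mean = 18, cycles_sd = 6,
                          deviation_scale_range = c(2, 15),
                          improve_probability = 0.5,
                          improve_rule = c("random", "severity_threshold"),
                          progression_range = c(1.1, 1.6),
                          cycle_noise_sd = 1,
                          equipment_none_probability = 0.79,
                          session_gap_mean = 740, session_gap_sd = 577,
                          seed = 1L) {
  improve_rule <- match.arg(improve_rule)
  stopifnot(n_patients >= 3, max_sessions >= 1, cycles_sd >= 0,
            length(deviation_scale_range) == 2,
            deviation_scale_range[1] > 0,
            diff(deviation_scale_range) >= 0,
            improve_probability >= 0, improve_probability <= 1,
            length(progression_range) == 2, all(progression_range > 1),
            cycle_noise_sd >= 0,
            equipment_none_probability >= 0, equipment_none_probability <= 1)
  structure(list(n_patients = as.integer(n_patients),
                 max_sessions = as.integer(max_sessions),
                 cycles_mean = cycles_mean, cycles_sd = cycles_sd,
                 deviation_scale_range = deviation_scale_range,
                 improve_probability = improve_probability,
                 improve_rule = improve_rule,
                 progression_range = progression_range,
                 cycle_noise_sd = cycle_noise_sd,
                 equipment_none_probability = equipment_none_probability,
                 session_gap_mean = session_gap_mean,
                 session_gap_sd = session_gap_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# smooth periodic curve on the 101-point grid from <= 4 Fourier harmonics
harmonic_curve <- function(amps, phases, offset = 0) {
  t <- (0:100) / 100
  y <- rep(offset, 101)
  for (h in seq_along(amps)) {
    y <- y + amps[h] * sin(2 * pi * h * t + phases[h])
  }
  y
}

#' Generate a synthetic normative reference
#'
#' Smooth periodic per-angle mean curves built from at most four Fourier
#' harmonics with angle-specific amplitudes in physiological magnitude ranges
#' (e.g. a knee flexion/extension excursion peaking near 60 degrees).
#' Deterministic per seed.
#'
#' @param seed Integer seed.
#' @return A [normative_reference()].
#' @export
generate_reference <- function(seed = 1L) {
  rng <- local_rng(seed)
  # peak amplitude scale and mean offset (degrees) per canonical angle
  amp_scale <- c(3, 8, 4, 20, 8, 10, 30, 12, 8)
  offsets <- c(10, 0, 5, 20, -3, 0, 30, 0, -8)
  ref <- matrix(0, 101, 9)
  for (n in 1:9) {
    n_harm <- 2L + rng$sample(3L, size = 1L)  # 3 or 4... (2 + 1..3)
    n_harm <- min(n_harm, 4L)
    amps <- amp_scale[n] * c(1, 0.4, 0.2, 0.1)[seq_len(n_harm)] *
      rng$runif(n_harm, 0.7, 1)
    phases <- rng$runif(n_harm, 0, 2 * pi)
    ref[, n] <- harmonic_curve(amps, phases, offsets[n])
  }
  normative_reference(ref, provenance = sprintf("synthetic (seed %d)", seed))
}

# patient-specific smooth deviation shape, normalized to unit GPS vs ref
unit_deviation_shape <- function(rng) {
  shape <- matrix(0, 101, 9)
  for (n in 1:9) {
    n_harm <- 1L + rng$sample(3L, size = 1L)
    amps <- rng$runif(n_harm, 0.2, 1) * c(1, 0.5, 0.25, 0.12)[seq_len(n_harm)]
    phases <- rng$runif(n_harm, 0, 2 * pi)
    shape[, n] <- harmonic_curve(amps, phases, offset = rng$rnorm1(0, 0.3))
  }
  # GPS of (ref + shape) vs ref is sqrt(mean(colMeans(shape^2))); scale to 1
  shape / sqrt(mean(colMeans(shape * shape)))
}

#' Generate one synthetic patient
#'
#' Draws a baseline severity, evolves it across sessions by the planted
#' improve/worsen process, and renders each session's cycles as
#' reference + severity x (unit-GPS patient deviation shape) + noise.
#'
#' @param config A [cohort_config()].
#' @param ref A [normative_reference()].
#' @param patient_id Patient identifier.
#' @param rng A [local_rng()] stream.
#' @return List with `sessions` (list of [gait_session()]) and `truth`
#'   (data frame per transition: `from_severity`, `to_severity`,
#'   `direction`).
#' @export
generate_patient <- function(config, ref, patient_id, rng) {
  n_sessions <- min(1L + rng$rpois(1L, 1), config$max_sessions)
  shape <- unit_deviation_shape(rng)
  sev <- rng$runif1(config$deviation_scale_range[1],
                    config$deviation_scale_range[2])
  sev_mid <- mean(config$deviation_scale_range)
  base_date <- as.POSIXct("2012-01-01 10:00:00", tz = "UTC") +
    round(rng$runif1(0, 3000)) * 86400
  sessions <- list()
  truth <- list()
  date <- base_date
  for (j in seq_len(n_sessions)) {
    k <- round(rng$rnorm1(config$cycles_mean, config$cycles_sd))
    k <- as.integer(min(40, max(5, k)))
    cycles <- lapply(seq_len(k), function(i) {
      v <- ref$ref_values + sev * shape
      if (config$cycle_noise_sd > 0) {
        v <- v + matrix(rng$rnorm(101 * 9, 0, config$cycle_noise_sd), 101, 9)
      }
      gait_cycle(v, cycle_id = sprintf("%s_s%d_c%03d", patient_id, j, i))
    })
    equip <- if (rng$runif1() < config$equipment_none_probability) "none" else
      equipment_levels()[1L + rng$sample(5L, size = 1L)]
    sessions[[j]] <- gait_session(patient_id, date, equip, cycles)
    if (j < n_sessions) {
      f <- exp(rng$runif1(log(config$progression_range[1]),
                          log(config$progression_range[2])))
      improve <- switch(config$improve_rule,
        random = rng$runif1() < config$improve_probability,
        severity_threshold = sev > sev_mid)
      new_sev <- if (improve) sev / f else sev * f
      truth[[j]] <- data.frame(patient_id = patient_id, transition = j,
                               from_severity = sev, to_severity = new_sev,
                               direction = if (improve) "improve" else "worsen",
                               stringsAsFactors = FALSE)
      sev <- new_sev
      gap <- max(4, round(rng$rnorm1(config$session_gap_mean,
                                     config$session_gap_sd)))
      date <- date + gap * 86400
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(patient_id = character(), transition = integer(),
               from_severity = numeric(), to_severity = numeric(),
               direction = character(), stringsAsFactors = FALSE)
  list(sessions = sessions, truth = truth)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' @param config A [cohort_config()].
#' @return List: `cohort` (a [gait_cohort()]), `truth` (data frame of planted
#'   per-transition directions and severities), `reference` (the
#'   [normative_reference()] the cohort deviates from).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  rng <- local_rng(config$seed)
  ref <- generate_reference(rng$derive("reference"))
  sessions <- list()
  truths <- list()
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%04d", p)
    pat <- generate_patient(config, ref, pid, rng)
    sessions <- c(sessions, pat$sessions)
    truths[[p]] <- pat$truth
  }
  list(cohort = gait_cohort(sessions),
       truth = do.call(rbind, truths),
       reference = ref)
}

#' Planted-direction recovery rate
#'
#' Labels the cohort through the scoring pipeline and measures the fraction
#' of labeled cycles whose GPS-change sign matches the planted
#' improvement/worsening direction of their session transition.
#'
#' @param generated Output of [generate_cohort()].
#' @param per_pair If TRUE, measure per session pair (majority over the
#'   pair's cycles is not taken: the pair counts as recovered when the mean
#'   GPS change over its cycles has the planted sign); if FALSE (default),
#'   measure per labeled cycle.
#' @return Fraction in `[0, 1]` (NA when no labeled pairs exist).
#' @export
label_recovery_rate <- function(generated, per_pair = FALSE) {
  labeled <- build_labeled_dataset(generated$cohort, generated$reference,
                                   equipment_free_only = FALSE)
  tab <- labeled$table
  if (!nrow(tab)) return(NA_real_)
  key <- paste(generated$truth$patient_id, generated$truth$transition)
  planted <- stats::setNames(generated$truth$direction, key)
  pair_key <- sub("#", " ", tab$pair_id)
  expect_label <- ifelse(planted[pair_key] == "improve", 1L, 0L)
  if (per_pair) {
    agg <- stats::aggregate(tab$delta_gps, by = list(pair = pair_key), mean)
    exp_pair <- ifelse(planted[agg$pair] == "improve", 1L, 0L)
    mean(classify_delta(agg$x) == exp_pair)
  } else {
    mean(tab$label == expect_label)
  }
}
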