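test_that("the synthetic normative reference is smooth and deterministic", {
  r1 <- generate_reference(7)
  r2 <- generate_reference(7)
  expect_identical(r1$ref_values, r2$ref_values)
  expect_false(identical(r1$ref_values, generate_reference(8)$ref_values))
  # harmonic construction keeps adjacent samples close
  expect_lt(max(abs(apply(r1$ref_values, 2, diff))), 10)
  # the reference deviates from itself by nothing
  expect_equal(gps(gait_cycle(r1$ref_values), r1), 0)
})

test_that("noise-free cycles have GPS equal to the planted severity", {
  cfg <- cohort_config(n_patients = 3, cycle_noise_sd = 0, seed = 71)
  ref <- generate_reference(72)
  rng <- local_rng(73)
  pat <- generate_patient(cfg, ref, "PX", rng)
  s1 <- pat$sessions[[1]]
  g <- gps(s1$cycles[[1]], ref)
  if (nrow(pat$truth) > 0) {
    expect_equal(g, pat$truth$from_severity[1], tolerance = 1e-6)
  }
  expect_gte(g, cfg$deviation_scale_range[1] - 1e-6)
  expect_lte(g, cfg$deviation_scale_range[2] + 1e-6)
  # all cycles of a noise-free session are identical in GPS
  gs <- vapply(s1$cycles, gps, numeric(1), ref = ref)
  expect_lt(max(gs) - min(gs), 1e-9)
})

test_that("improving transitions strictly decrease the session mean GPS", {
  cfg <- cohort_config(n_patients = 30, cycle_noise_sd = 0, seed = 74)
  gen <- generate_cohort(cfg)
  pairs <- pair_consecutive_sessions(gen$cohort)
  key <- paste(gen$truth$patient_id, gen$truth$transition)
  planted <- stats::setNames(gen$truth$direction, key)
  for (pr in pairs) {
    dir <- planted[[sub("#", " ", pr$pair_id)]]
    d <- session_avg_gps(pr$next_session, gen$reference) -
      session_avg_gps(pr$current, gen$reference)
    if (dir == "improve") expect_lt(d, 0) else expect_gt(d, 0)
  }
})

test_that("patient generation is deterministic given the stream", {
  cfg <- cohort_config(n_patients = 3, seed = 75)
  ref <- generate_reference(76)
  p1 <- generate_patient(cfg, ref, "PD", local_rng(77))
  p2 <- generate_patient(cfg, ref, "PD", local_rng(77))
  expect_equal(p1$truth, p2$truth)
  expect_identical(length(p1$sessions), length(p2$sessions))
  expect_equal(unclass(p1$sessions[[1]]$cycles[[1]]),
               unclass(p2$sessions[[1]]$cycles[[1]]))
})

test_that("cohort statistics match the configured study structure", {
  gen <- generate_cohort(cohort_config(n_patients = 40, seed = 78))
  n_sess <- length(gen$cohort$sessions)
  expect_gte(n_sess, 50)
  k <- vapply(gen$cohort$sessions, function(s) length(s$cycles), integer(1))
  expect_gte(mean(k), 14); expect_lte(mean(k), 22)
  expect_true(all(k >= 5 & k <= 40))
  # equipment mix roughly honours the configured equipment-free share
  eq <- vapply(gen$cohort$sessions, `[[`, character(1), "equipment")
  expect_gt(mean(eq == "none"), 0.6)
})

test_that("an all-improve noise-free cohort labels every cycle class 1", {
  gen <- generate_cohort(cohort_config(n_patients = 15,
                                       improve_probability = 1,
                                       cycle_noise_sd = 0, seed = 79))
  labeled <- build_labeled_dataset(gen$cohort, gen$reference,
                                   equipment_free_only = FALSE)
  expect_gt(nrow(labeled$table), 0)
  expect_true(all(labeled$table$label == 1L))
})

test_that("transition directions are balanced at a fair coin", {
  gen <- generate_cohort(cohort_config(n_patients = 550, cycles_mean = 5,
                                       cycles_sd = 0, seed = 80))
  expect_gte(nrow(gen$truth), 500)
  expect_gte(mean(gen$truth$direction == "improve"), 0.45)
  expect_lte(mean(gen$truth$direction == "improve"), 0.55)
})

test_that("GPS increases with planted severity for a fixed shape", {
  ref <- generate_reference(81)
  rng <- local_rng(82)
  shape <- gaitcast:::unit_deviation_shape(rng)
  gs <- vapply(c(2, 5, 9, 14), function(s)
    gps(gait_cycle(ref$ref_values + s * shape), ref), numeric(1))
  expect_true(all(diff(gs) > 0))
  expect_equal(gs, c(2, 5, 9, 14), tolerance = 1e-9)
})

test_that("label recovery is perfect without noise and high with noise", {
  gen0 <- generate_cohort(cohort_config(n_patients = 25, cycle_noise_sd = 0,
                                        seed = 83))
  expect_equal(label_recovery_rate(gen0), 1)
  expect_equal(label_recovery_rate(gen0, per_pair = TRUE), 1)
  gen1 <- generate_cohort(cohort_config(n_patients = 25, seed = 83))
  expect_gte(label_recovery_rate(gen1), 0.9)
})

test_that("the severity-threshold rule plants an observable signal", {
  gen <- generate_cohort(cohort_config(n_patients = 40,
                                       improve_rule = "severity_threshold",
                                       seed = 84))
  mid <- mean(c(2, 15))
  expect_true(all((gen$truth$direction == "improve") ==
                    (gen$truth$from_severity > mid)))
})
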