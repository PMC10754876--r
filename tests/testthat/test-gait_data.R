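test_that("the canonical angle vocabulary is fixed and nine-long", {
  expect_length(angle_names(), 9L)
  expect_identical(angle_names()[1], "pelvis_anteversion_retroversion")
  expect_identical(angle_names()[9], "foot_progression")
  expect_true("none" %in% equipment_levels())
})

test_that("gait_cycle validates shape, finiteness and angle range", {
  expect_s3_class(rand_cycle(1), "gait_cycle")
  expect_error(gait_cycle(matrix(0, 100, 9)), "101 x 9")
  expect_error(gait_cycle(matrix(c(NA, rep(0, 101 * 9 - 1)), 101, 9)),
               "non-finite")
  expect_error(gait_cycle(matrix(400, 101, 9)), "360")
})

test_that("time normalization interpolates linearly onto the percent grid", {
  # constant stride: every resampled row equals the constant
  v <- seq_len(9)
  const <- matrix(rep(v, each = 37), 37, 9)
  out <- time_normalize(const)
  expect_equal(unclass(out), matrix(rep(v, each = 101), 101, 9),
               ignore_attr = TRUE)

  # already on the 101-point grid: unchanged
  cy <- rand_cycle(7)
  expect_equal(unclass(time_normalize(unclass(cy))), unclass(cy),
               tolerance = 1e-12, ignore_attr = TRUE)

  # two samples 0 and 100 degrees: row t must hold exactly t degrees
  two <- matrix(0, 2, 9); two[2, 3] <- 100
  out2 <- time_normalize(two)
  expect_equal(unclass(out2)[, 3], as.numeric(0:100))
  expect_equal(unclass(out2)[, 1], rep(0, 101))

  expect_error(time_normalize(matrix(0, 1, 9)), "at least 2")
  expect_error(time_normalize(matrix(NaN, 5, 9)), "non-finite")
})

test_that("time normalization is idempotent on normalized cycles", {
  for (s in 1:5) {
    cy <- rand_cycle(s)
    once <- time_normalize(unclass(cy))
    twice <- time_normalize(unclass(once))
    expect_equal(unclass(once), unclass(twice), tolerance = 1e-12)
  }
})

test_that("cycle flattening is the 909-sample time-major bijection", {
  cy <- rand_cycle(3)
  flat <- flatten_cycle(cy)
  expect_length(flat, 909L)
  # time-major: first 9 entries are the 9 angles at 0% of the stride
  expect_equal(flat[1:9], unname(unclass(cy)[1, ]))
  expect_equal(flat[10:18], unname(unclass(cy)[2, ]))
  # bijection
  expect_equal(unclass(unflatten_cycle(flat)), unclass(cy),
               ignore_attr = TRUE)

  zero <- gait_cycle(matrix(0, 101, 9))
  expect_equal(flatten_cycle(zero), rep(0, 909))
  one <- matrix(0, 101, 9); one[1, 1] <- 1
  f1 <- flatten_cycle(gait_cycle(one))
  expect_equal(f1[1], 1)
  expect_equal(sum(f1 != 0), 1L)
})

test_that("cohort I/O round-trips values and metadata", {
  ref <- test_reference()
  s1 <- session_with_gps(ref, c(8, 10), patient = "PA",
                         datetime = "2014-01-02 10:30:00", seed = 11)
  s2 <- session_with_gps(ref, c(6, 7, 9), patient = "PA",
                         datetime = "2016-05-20 09:00:00",
                         equipment = "cane", seed = 12)
  s3 <- session_with_gps(ref, 12, patient = "PB",
                         datetime = "2015-07-01 14:00:00", seed = 13)
  cohort <- gait_cohort(list(s1, s2, s3))
  dir <- withr::local_tempdir()
  manifest <- write_cohort(cohort, dir)
  back <- read_cohort(manifest)
  expect_length(back$sessions, 3L)
  for (i in 1:3) {
    expect_identical(back$sessions[[i]]$patient_id,
                     cohort$sessions[[i]]$patient_id)
    expect_identical(back$sessions[[i]]$equipment,
                     cohort$sessions[[i]]$equipment)
    expect_equal(back$sessions[[i]]$session_datetime,
                 cohort$sessions[[i]]$session_datetime)
    for (k in seq_along(back$sessions[[i]]$cycles)) {
      expect_equal(unclass(back$sessions[[i]]$cycles[[k]]),
                   unclass(cohort$sessions[[i]]$cycles[[k]]),
                   tolerance = 1e-6, ignore_attr = TRUE)
    }
  }
})

test_that("a malformed cycle file rejects the read and names the file", {
  ref <- test_reference()
  cohort <- gait_cohort(list(session_with_gps(ref, 5, seed = 21)))
  dir <- withr::local_tempdir()
  manifest <- write_cohort(cohort, dir)
  bad <- file.path(dir, "session_0001", "cycle_0001.csv")
  df <- utils::read.csv(bad, check.names = FALSE)
  utils::write.csv(df[1:100, ], bad, row.names = FALSE)
  expect_error(read_cohort(manifest), "cycle_0001.csv")
  expect_error(read_cohort(manifest), "101")
})

test_that("an empty cohort writes and reads back empty", {
  dir <- withr::local_tempdir()
  manifest <- write_cohort(gait_cohort(list()), dir)
  expect_length(read_cohort(manifest)$sessions, 0L)
})

test_that("cohorts refuse duplicate patient-datetime pairs", {
  ref <- test_reference()
  s <- session_with_gps(ref, 5, seed = 31)
  expect_error(gait_cohort(list(s, s)), "duplicate")
})
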