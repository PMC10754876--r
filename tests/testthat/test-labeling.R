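make_patient_sessions <- function(ref, patient, dates, gps_per_session,
                                  equipment = NULL, seed0 = 100) {
  lapply(seq_along(dates), function(j) {
    session_with_gps(ref, gps_per_session[[j]], patient = patient,
                     datetime = dates[j],
                     equipment = if (is.null(equipment)) "none" else equipment[j],
                     seed = seed0 + j)
  })
}

test_that("consecutive-session pairing follows patient chronology", {
  ref <- test_reference()
  # deliberately out of chronological order in the cohort list
  sa <- make_patient_sessions(ref, "A",
                              c("2015-06-01 10:00:00", "2013-01-01 10:00:00",
                                "2014-03-01 10:00:00"),
                              list(8, 10, 9), seed0 = 110)
  sb <- make_patient_sessions(ref, "B", "2014-01-01 08:00:00", list(7),
                              seed0 = 120)
  pairs <- pair_consecutive_sessions(gait_cohort(c(sa, sb)))
  expect_length(pairs, 2L)
  expect_equal(vapply(pairs, `[[`, character(1), "patient_id"), c("A", "A"))
  d1 <- pairs[[1]]
  expect_true(d1$next_session$session_datetime > d1$current$session_datetime)
  expect_equal(format(d1$current$session_datetime, "%Y"), "2013")
  expect_equal(format(pairs[[2]]$next_session$session_datetime, "%Y"), "2015")
  expect_gt(d1$delta_days, 0)
})

test_that("pair counts equal the per-patient session-count enumeration", {
  ref <- test_reference()
  m_p <- c(1L, 2L, 4L, 3L, 1L)
  sessions <- list()
  for (p in seq_along(m_p)) {
    dates <- sprintf("20%02d-01-01 10:00:00", 10 + seq_len(m_p[p]))
    sessions <- c(sessions, make_patient_sessions(
      ref, paste0("P", p), dates, as.list(rep(5, m_p[p])), seed0 = 200 + 10 * p))
  }
  pairs <- pair_consecutive_sessions(gait_cohort(sessions))
  expect_length(pairs, sum(pmax(m_p - 1L, 0L)))
})

test_that("only pairs with both sessions equipment-free survive filtering", {
  ref <- test_reference()
  mk <- function(pid, eq, seed0) make_patient_sessions(
    ref, pid, c("2014-01-01 10:00:00", "2015-01-01 10:00:00"),
    list(5, 6), equipment = eq, seed0 = seed0)
  cohort <- gait_cohort(c(mk("A", c("none", "none"), 300),
                          mk("B", c("none", "cane"), 310),
                          mk("C", c("rollator", "none"), 320),
                          mk("D", c("none", "none"), 330)))
  pairs <- pair_consecutive_sessions(cohort)
  kept <- filter_equipment_free(pairs)
  brute <- sum(vapply(pairs, function(pr)
    pr$current$equipment == "none" && pr$next_session$equipment == "none",
    logical(1)))
  expect_length(kept, brute)
  expect_setequal(vapply(kept, `[[`, character(1), "patient_id"), c("A", "D"))
})

test_that("the GPS change is next-session mean minus current-cycle GPS", {
  ref <- test_reference()
  cur <- session_with_gps(ref, c(12, 12), patient = "A",
                          datetime = "2014-01-01 10:00:00", seed = 400)
  nxt <- session_with_gps(ref, c(9, 10, 11), patient = "A",
                          datetime = "2015-01-01 10:00:00", seed = 401)
  pairs <- pair_consecutive_sessions(gait_cohort(list(cur, nxt)))
  d <- delta_gps(cur$cycles[[1]], pairs[[1]], ref)
  expect_equal(d, -2, tolerance = 1e-9)

  # tie: next average equals the cycle's own GPS
  nxt_eq <- session_with_gps(ref, c(12, 12), patient = "B",
                             datetime = "2015-01-01 10:00:00", seed = 402)
  cur_b <- session_with_gps(ref, 12, patient = "B",
                            datetime = "2014-06-01 10:00:00", seed = 403)
  pr_b <- pair_consecutive_sessions(gait_cohort(list(cur_b, nxt_eq)))[[1]]
  expect_equal(delta_gps(cur_b$cycles[[1]], pr_b, ref), 0, tolerance = 1e-9)

  # brute-force composition on a random pair
  oracle <- mean(vapply(nxt$cycles, oracle_gps, numeric(1), ref = ref)) -
    oracle_gps(cur$cycles[[2]], ref)
  expect_equal(delta_gps(cur$cycles[[2]], pairs[[1]], ref), oracle,
               tolerance = 1e-12)

  # a cycle not in the current session is rejected
  expect_error(delta_gps(nxt$cycles[[1]], pairs[[1]], ref), "belong")
})

test_that("classification maps negative change to improvement (class 1)", {
  expect_identical(classify_delta(-0.5), 1L)
  expect_identical(classify_delta(0.5), 0L)
  expect_identical(classify_delta(0), 0L)
  expect_identical(classify_delta(c(-2, 3, 0, -1e-9)), c(1L, 0L, 0L, 1L))
  expect_error(classify_delta(NaN), "non-finite")
})

test_that("labeled datasets satisfy the label and pair-mean identities", {
  gen <- generate_cohort(cohort_config(n_patients = 12, seed = 77))
  labeled <- build_labeled_dataset(gen$cohort, gen$reference,
                                   equipment_free_only = FALSE)
  tab <- labeled$table
  expect_gt(nrow(tab), 0)
  expect_identical(tab$label, classify_delta(tab$delta_gps))

  # per pair: mean delta equals next-session average minus current average;
  # and the next-average term is shared, so delta + cycle GPS is constant
  pairs <- pair_consecutive_sessions(gen$cohort)
  for (pr in pairs[seq_len(min(3, length(pairs)))]) {
    rows <- tab$pair_id == pr$pair_id
    expect_equal(mean(tab$delta_gps[rows]),
                 session_avg_gps(pr$next_session, gen$reference) -
                   session_avg_gps(pr$current, gen$reference),
                 tolerance = 1e-9)
    shared <- tab$delta_gps[rows] +
      vapply(labeled$cycles[rows], gps, numeric(1), ref = gen$reference)
    expect_lt(max(shared) - min(shared), 1e-9)
  }
})

test_that("patient-level splitting is deterministic and leak-free", {
  gen <- generate_cohort(cohort_config(n_patients = 20, seed = 88))
  labeled <- build_labeled_dataset(gen$cohort, gen$reference,
                                   equipment_free_only = FALSE)
  s1 <- split_by_patient(labeled, c(0.5, 0.25, 0.25), seed = 5)
  s2 <- split_by_patient(labeled, c(0.5, 0.25, 0.25), seed = 5)
  expect_identical(s1, s2)
  expect_setequal(names(s1), unique(labeled$table$patient_id))
  expect_true(all(s1 %in% c("train", "validation", "test")))

  # cycle shares hit the targets within one patient's worth of cycles
  counts <- table(labeled$table$patient_id)
  shares <- vapply(c("train", "validation", "test"), function(sp)
    sum(counts[names(s1)[s1 == sp]]), numeric(1))
  expect_equal(unname(shares / sum(counts)), c(0.5, 0.25, 0.25),
               tolerance = max(counts) / sum(counts))

  expect_error(split_by_patient(labeled$table[labeled$table$patient_id %in%
    unique(labeled$table$patient_id)[1:2], ], c(0.5, 0.25, 0.25), seed = 1),
    "3 patients")
  expect_error(split_by_patient(labeled, c(0.5, 0.4, 0.2), seed = 1),
               "summing to 1")
})
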