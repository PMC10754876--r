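#' Pair directly consecutive gait sessions
#'
#' For every patient with sessions at datetimes d1 < d2 < ... < dm, emits the
#' pairs (d1,d2), (d2,d3), ..., (d(m-1),dm). Patients with a single session
#' contribute nothing.
#'
#' @param cohort A [gait_cohort()].
#' @return List of `session_pair` objects, each with elements `current`,
#'   `next_session`, `delta_days` (positive), `patient_id` and `pair_id`.
#' @export
pair_consecutive_sessions <- function(cohort) {
  stopifnot(inherits(cohort, "gait_cohort"))
  pid <- vapply(cohort$sessions, `[[`, character(1), "patient_id")
  pairs <- list()
  for (p in unique(pid)) {
    sess <- cohort$sessions[pid == p]
    dts <- as.numeric(vapply(sess, function(s) as.numeric(s$session_datetime), numeric(1)))
    if (anyDuplicated(dts)) {
      stop("duplicate session datetime for patient ", p, call. = FALSE)
    }
    sess <- sess[order(dts)]
    if (length(sess) < 2L) next
    for (j in seq_len(length(sess) - 1L)) {
      cur <- sess[[j]]; nxt <- sess[[j + 1L]]
      pairs[[length(pairs) + 1L]] <- structure(
        list(current = cur,
             next_session = nxt,
             delta_days = as.numeric(difftime(nxt$session_datetime,
                                              cur$session_datetime, units = "days")),
             patient_id = p,
             pair_id = paste0(p, "#", j)),
        class = "session_pair")
    }
  }
  pairs
}

#' Keep only equipment-free session pairs
#'
#' Retains a pair only when both of its sessions were walked without any
#' equipment, so that the two sessions are compared under the same condition.
#'
#' @param pairs List of session pairs from [pair_consecutive_sessions()].
#' @return Filtered list.
#' @export
filter_equipment_free <- function(pairs) {
  Filter(function(pr) pr$current$equipment == "none" &&
           pr$next_session$equipment == "none", pairs)
}

#' Signed GPS change for one cycle of a session pair
#'
#' The prediction target: next-session average GPS minus the GPS of the given
#' cycle of the current session. Negative values mean the patient's gait
#' improves by the next visit.
#'
#' @param cycle A [gait_cycle()] belonging to `pair$current`.
#' @param pair A session pair.
#' @param ref A [normative_reference()].
#' @return Signed GPS change in degrees.
#' @export
delta_gps <- function(cycle, pair, ref) {
  stopifnot(inherits(pair, "session_pair"))
  ids <- vapply(pair$current$cycles, attr, character(1), "cycle_id")
  if (!(attr(cycle, "cycle_id") %in% ids)) {
    stop("cycle ", attr(cycle, "cycle_id"),
         " does not belong to the pair's current session", call. = FALSE)
  }
  session_avg_gps(pair$next_session, ref) - gps(cycle, ref)
}

#' Binary class of a signed GPS change
#'
#' Class 1 ("gait improves") for a negative change, class 0 ("gait worsens")
#' for a positive one. An exactly zero change is classed 0 (not improved).
#'
#' @param delta Finite signed GPS change(s) in degrees.
#' @return Integer vector of 0/1 labels.
#' @export
classify_delta <- function(delta) {
  if (!all(is.finite(delta))) stop("non-finite GPS change", call. = FALSE)
  as.integer(delta < 0)
}

#' Build the labeled per-cycle dataset from a cohort
#'
#' Pairs consecutive sessions, keeps equipment-free pairs, and labels every
#' cycle of each pair's current session with its signed GPS change and binary
#' class.
#'
#' @param cohort A [gait_cohort()].
#' @param ref A [normative_reference()].
#' @param equipment_free_only Keep only pairs with both sessions
#'   equipment-free (default TRUE).
#' @return A list with `table` (data.frame: `patient_id`, `pair_id`,
#'   `cycle_id`, `delta_gps`, `label`) and `cycles` (list of the corresponding
#'   [gait_cycle()] objects, row-aligned with the table).
#' @export
build_labeled_dataset <- function(cohort, ref, equipment_free_only = TRUE) {
  pairs <- pair_consecutive_sessions(cohort)
  if (equipment_free_only) pairs <- filter_equipment_free(pairs)
  rows <- list(); cycles <- list()
  for (pr in pairs) {
    next_avg <- session_avg_gps(pr$next_session, ref)
    for (cy in pr$current$cycles) {
      d <- next_avg - gps(cy, ref)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pr$patient_id, pair_id = pr$pair_id,
        cycle_id = attr(cy, "cycle_id"),
        delta_gps = d, label = classify_delta(d),
        stringsAsFactors = FALSE)
      cycles[[length(cycles) + 1L]] <- cy
    }
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), pair_id = character(),
               cycle_id = character(), delta_gps = numeric(),
               label = integer(), stringsAsFactors = FALSE)
  list(table = table, cycles = cycles)
}

#' Patient-level train/validation/test split
#'
#' Assigns whole patients to splits so that no patient's cycles leak across
#' splits, targeting the requested fractions of total CYCLES. Patients are
#' taken largest-first (cycle count, ties broken by a seeded shuffle) and each
#' is assigned greedily to the split with the largest remaining deficit
#' relative to its target.
#'
#' @param labeled A labeled dataset from [build_labeled_dataset()], or its
#'   `table` component.
#' @param fractions Numeric length-3 vector (train, validation, test),
#'   positive, summing to 1.
#' @param seed Integer seed making the assignment deterministic.
#' @return Named character vector: patient_id -> "train" / "validation" /
#'   "test".
#' @export
split_by_patient <- function(labeled, fractions = c(0.73, 0.12, 0.14) / 0.99,
                             seed = 1L) {
  tab <- if (is.data.frame(labeled)) labeled else labeled$table
  if (any(fractions <= 0) || length(fractions) != 3L ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be 3 positive numbers summing to 1", call. = FALSE)
  }
  counts <- table(tab$patient_id)
  if (length(counts) < 3L) stop("need at least 3 patients to split", call. = FALSE)
  rng <- local_rng(seed)
  ord <- names(counts)[rng$sample(length(counts))]
  counts <- counts[ord]
  counts <- counts[order(-as.integer(counts))]   # stable: ties keep shuffled order
  total <- sum(counts)
  splits <- c("train", "validation", "test")
  assigned <- stats::setNames(numeric(3), splits)
  out <- character(0)
  for (p in names(counts)) {
    deficit <- fractions * total - assigned
    pick <- splits[which.max(deficit)]
    assigned[pick] <- assigned[pick] + counts[[p]]
    out[p] <- pick
  }
  out
}
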