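#' Canonical kinematic variable names
#'
#' The nine joint-angle curves describing one gait cycle, in the fixed column
#' order used by every cycle matrix in the package: three pelvic angles, three
#' hip angles, knee flexion/extension, ankle plantar/dorsiflexion and the
#' foot progression angle.
#'
#' @return Character vector of length 9.
#' @export
#' @examples
#' angle_names()
angle_names <- function() {
  c("pelvis_anteversion_retroversion",
    "pelvis_rotation",
    "pelvic_tilt",
    "hip_flexion_extension",
    "hip_abduction_adduction",
    "hip_rotation",
    "knee_flexion_extension",
    "ankle_plantar_dorsiflexion",
    "foot_progression")
}

#' Recognised walking-equipment conditions
#'
#' @return Character vector of the closed equipment vocabulary. Sessions
#'   recorded with an aid not in the list use `"other"`.
#' @export
equipment_levels <- function() {
  c("none", "cane", "rollator", "orthosis", "prosthesis", "other")
}

# number of samples per normalized stride (0..100% inclusive) and of angles
N_TIME <- 101L
N_ANGLE <- 9L

#' Construct a gait cycle
#'
#' A gait cycle is one stride (initial contact to the next ipsilateral initial
#' contact), time-normalized to 101 samples at 0--100% of the stride, for the
#' nine canonical joint angles in degrees. Row `i` of the matrix is time index
#' `i - 1` (percent of stride, 0-based 0..100).
#'
#' @param values Numeric 101 x 9 matrix of joint angles in degrees, columns in
#'   [angle_names()] order.
#' @param cycle_id Identifier for the cycle (coerced to character).
#' @return An object of class `gait_cycle`: the validated matrix with the
#'   canonical column names and a `cycle_id` attribute.
#' @export
gait_cycle <- function(values, cycle_id = "cycle") {
  values <- as.matrix(values)
  if (!is.numeric(values) || nrow(values) != N_TIME || ncol(values) != N_ANGLE) {
    stop("a gait cycle must be a numeric 101 x 9 matrix, got ",
         nrow(values), " x ", ncol(values), call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("gait cycle contains non-finite values", call. = FALSE)
  }
  if (any(abs(values) > 360)) {
    stop("gait cycle contains angles outside [-360, 360] degrees", call. = FALSE)
  }
  dimnames(values) <- list(NULL, angle_names())
  structure(values, cycle_id = as.character(cycle_id), class = c("gait_cycle", "matrix", "array"))
}

#' @export
print.gait_cycle <- function(x, ...) {
  cat("<gait_cycle> ", attr(x, "cycle_id"), ": 101 x 9 degrees, GPS-ready\n", sep = "")
  invisible(x)
}

is_gait_cycle <- function(x) inherits(x, "gait_cycle")

#' Time-normalize a raw stride to the 101-point grid
#'
#' Resamples a stride sampled at arbitrary (uniform) time points onto the
#' canonical uniform grid of 101 samples covering 0--100% of the stride, by
#' linear interpolation per angle. The first and last input samples are
#' preserved exactly at 0% and 100%; no extrapolation occurs.
#'
#' @param raw_curve Numeric matrix with >= 2 rows and 9 columns (degrees,
#'   columns in [angle_names()] order), rows uniformly spanning one stride.
#' @param cycle_id Identifier for the resulting cycle.
#' @return A [gait_cycle()].
#' @export
time_normalize <- function(raw_curve, cycle_id = "cycle") {
  raw_curve <- as.matrix(raw_curve)
  if (nrow(raw_curve) < 2L) {
    stop("time normalization needs at least 2 samples", call. = FALSE)
  }
  if (ncol(raw_curve) != N_ANGLE) {
    stop("expected 9 angle columns, got ", ncol(raw_curve), call. = FALSE)
  }
  if (!all(is.finite(raw_curve))) {
    stop("raw stride contains non-finite values", call. = FALSE)
  }
  t_in <- seq(0, 100, length.out = nrow(raw_curve))
  t_out <- 0:100
  out <- apply(raw_curve, 2L, function(col) {
    stats::approx(t_in, col, xout = t_out, method = "linear", ties = "ordered")$y
  })
  gait_cycle(out, cycle_id = cycle_id)
}

#' Flatten a gait cycle to a single signal vector
#'
#' Concatenates the cycle time-major (the nine angles at 0%, then the nine
#' angles at 1%, ...) into the 909-sample vector consumed by flat-input
#' models such as the MLP.
#'
#' @param cycle A [gait_cycle()].
#' @return Numeric vector of length 909.
#' @seealso [unflatten_cycle()]
#' @export
flatten_cycle <- function(cycle) {
  stopifnot(is_gait_cycle(cycle))
  as.vector(t(unclass(cycle)))
}

#' Recover the 101 x 9 matrix from a flattened cycle
#'
#' Exact inverse of [flatten_cycle()].
#'
#' @param flat Numeric vector of length 909.
#' @param cycle_id Identifier for the rebuilt cycle.
#' @return A [gait_cycle()].
#' @export
unflatten_cycle <- function(flat, cycle_id = "cycle") {
  if (length(flat) != N_TIME * N_ANGLE) {
    stop("flattened cycle must have length 909, got ", length(flat), call. = FALSE)
  }
  gait_cycle(matrix(flat, nrow = N_TIME, ncol = N_ANGLE, byrow = TRUE),
             cycle_id = cycle_id)
}

#' Construct a gait session
#'
#' One laboratory visit of one patient: its acquisition datetime, the walking
#' equipment used, and the K >= 1 gait cycles recorded during the visit.
#'
#' @param patient_id Patient identifier (character).
#' @param session_datetime A `POSIXct` (or anything [as.POSIXct()] accepts,
#'   ISO-8601 strings included).
#' @param equipment One of [equipment_levels()].
#' @param cycles List of [gait_cycle()] objects, length >= 1.
#' @return An object of class `gait_session`.
#' @export
gait_session <- function(patient_id, session_datetime, equipment = "none", cycles) {
  equipment <- match.arg(equipment, equipment_levels())
  if (is.character(session_datetime)) {
    # accept ISO-8601 "T" separators and a trailing "Z"
    session_datetime <- sub("Z$", "", sub("T", " ", session_datetime))
  }
  session_datetime <- as.POSIXct(session_datetime, tz = "UTC")
  if (is.na(session_datetime)) stop("invalid session datetime", call. = FALSE)
  if (length(cycles) < 1L) stop("a session needs at least one gait cycle", call. = FALSE)
  ok <- vapply(cycles, is_gait_cycle, logical(1))
  if (!all(ok)) stop("all session cycles must be gait_cycle objects", call. = FALSE)
  structure(
    list(patient_id = as.character(patient_id),
         session_datetime = session_datetime,
         equipment = equipment,
         cycles = cycles),
    class = "gait_session"
  )
}

#' @export
print.gait_session <- function(x, ...) {
  cat("<gait_session> patient ", x$patient_id, " @ ",
      format(x$session_datetime, "%Y-%m-%dT%H:%M:%SZ"),
      " [", x$equipment, "], ", length(x$cycles), " cycles\n", sep = "")
  invisible(x)
}

#' Construct a gait cohort
#'
#' A collection of gait sessions across patients. `(patient_id,
#' session_datetime)` pairs must be unique so that per-patient session
#' chronology is well defined.
#'
#' @param sessions List of [gait_session()] objects (may be empty).
#' @return An object of class `gait_cohort`.
#' @export
gait_cohort <- function(sessions = list()) {
  ok <- vapply(sessions, function(s) inherits(s, "gait_session"), logical(1))
  if (length(sessions) && !all(ok)) {
    stop("all cohort entries must be gait_session objects", call. = FALSE)
  }
  key <- vapply(sessions, function(s)
    paste(s$patient_id, format(s$session_datetime, "%Y-%m-%d %H:%M:%OS6")), character(1))
  if (anyDuplicated(key)) {
    stop("duplicate (patient_id, session_datetime) in cohort: ",
         key[duplicated(key)][1], call. = FALSE)
  }
  structure(list(sessions = sessions), class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  n_pat <- length(unique(vapply(x$sessions, `[[`, character(1), "patient_id")))
  n_cyc <- sum(vapply(x$sessions, function(s) length(s$cycles), integer(1)))
  cat("<gait_cohort> ", length(x$sessions), " sessions / ", n_pat,
      " patients / ", n_cyc, " cycles\n", sep = "")
  invisible(x)
}

#' Number of cycles in a cohort
#' @param cohort A [gait_cohort()].
#' @return Integer cycle count.
#' @export
n_cycles <- function(cohort) {
  sum(vapply(cohort$sessions, function(s) length(s$cycles), integer(1)))
}

fmt_dt <- function(dt) format(dt, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

write_cycle_csv <- function(cycle, path) {
  df <- as.data.frame(unclass(cycle))
  utils::write.csv(df, path, row.names = FALSE)
}

read_cycle_csv <- function(path, cycle_id) {
  if (!file.exists(path)) stop("missing cycle file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df), angle_names())) {
    stop("malformed header in cycle file ", path,
         " (expected the 9 canonical angle names)", call. = FALSE)
  }
  if (nrow(df) != N_TIME) {
    stop("cycle file ", path, " has ", nrow(df),
         " data rows; exactly 101 required", call. = FALSE)
  }
  gait_cycle(as.matrix(df), cycle_id = cycle_id)
}

#' Write a cohort to disk
#'
#' Serializes a cohort as a JSON manifest plus one CSV file per gait cycle
#' (header = the nine canonical angle names, 101 data rows, degrees). The
#' manifest lists, per session: patient id, ISO-8601 datetime, equipment and
#' the relative cycle-file paths.
#'
#' @param cohort A [gait_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "gait_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", length(cohort$sessions))
  for (i in seq_along(cohort$sessions)) {
    s <- cohort$sessions[[i]]
    sess_dir <- sprintf("session_%04d", i)
    dir.create(file.path(out_dir, sess_dir), showWarnings = FALSE)
    files <- character(length(s$cycles))
    for (k in seq_along(s$cycles)) {
      files[k] <- file.path(sess_dir, sprintf("cycle_%04d.csv", k))
      write_cycle_csv(s$cycles[[k]], file.path(out_dir, files[k]))
    }
    entries[[i]] <- list(
      patient_id = s$patient_id,
      session_datetime = fmt_dt(s$session_datetime),
      equipment = s$equipment,
      cycle_ids = vapply(s$cycles, attr, character(1), "cycle_id"),
      cycle_files = files
    )
  }
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(entries, manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort from a manifest
#'
#' Inverse of [write_cohort()]: rebuilds the cohort from its JSON manifest.
#' Cycle values round-trip to at least 6 decimal places and metadata exactly.
#' A cycle file with the wrong shape or header rejects the whole read with a
#' diagnostic naming the file.
#'
#' @param manifest_path Path to a `manifest.json` written by [write_cohort()].
#' @return A [gait_cohort()].
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("missing manifest: ", manifest_path, call. = FALSE)
  }
  entries <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  base <- dirname(manifest_path)
  sessions <- lapply(entries, function(e) {
    files <- unlist(e$cycle_files)
    ids <- unlist(e$cycle_ids)
    cycles <- lapply(seq_along(files), function(k) {
      read_cycle_csv(file.path(base, files[k]), cycle_id = ids[k])
    })
    gait_session(e$patient_id, e$session_datetime, e$equipment, cycles)
  })
  gait_cohort(sessions)
}
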