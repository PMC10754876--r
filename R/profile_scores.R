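#' Construct a normative reference
#'
#' The per-angle mean curves of a reference (typically developing) population:
#' the baseline every deviation score is measured against.
#'
#' @param ref_values Numeric 101 x 9 matrix of degrees, columns in
#'   [angle_names()] order.
#' @param provenance Free-text label describing where the reference comes from.
#' @return An object of class `normative_reference`.
#' @export
normative_reference <- function(ref_values, provenance = "unspecified") {
  ref_values <- as.matrix(ref_values)
  if (nrow(ref_values) != 101L || ncol(ref_values) != 9L || !all(is.finite(ref_values))) {
    stop("normative reference must be a finite 101 x 9 matrix", call. = FALSE)
  }
  dimnames(ref_values) <- list(NULL, angle_names())
  structure(list(ref_values = ref_values, provenance = as.character(provenance)),
            class = "normative_reference")
}

#' @export
print.normative_reference <- function(x, ...) {
  cat("<normative_reference> 101 x 9 degrees (", x$provenance, ")\n", sep = "")
  invisible(x)
}

#' Write / read a normative reference as CSV
#'
#' Same CSV dialect as a cycle file: header = the nine canonical angle names,
#' 101 data rows, degrees.
#'
#' @param ref A [normative_reference()].
#' @param path CSV file path.
#' @return `write_reference` invisibly returns `path`; `read_reference`
#'   returns a [normative_reference()].
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "normative_reference"))
  utils::write.csv(as.data.frame(ref$ref_values), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df), angle_names()) || nrow(df) != 101L) {
    stop("malformed reference file ", path, call. = FALSE)
  }
  normative_reference(as.matrix(df), provenance = basename(path))
}

#' Gait Variable Score of one angle
#'
#' Root-mean-square deviation of one joint-angle curve from its normative
#' reference over the 101-point cycle:
#' `GVS_n = sqrt( (1/T) * sum_t (c[t,n] - ref[t,n])^2 )` with `T = 101`.
#'
#' @param cycle A [gait_cycle()].
#' @param ref A [normative_reference()].
#' @param n Angle index, 0-based 0..8 in [angle_names()] order.
#' @return Non-negative deviation in degrees.
#' @export
gvs <- function(cycle, ref, n) {
  stopifnot(is_gait_cycle(cycle), inherits(ref, "normative_reference"))
  if (length(n) != 1L || n < 0L || n > 8L || n != floor(n)) {
    stop("angle index n must be a single integer in 0..8", call. = FALSE)
  }
  d <- unclass(cycle)[, n + 1L] - ref$ref_values[, n + 1L]
  sqrt(sum(d * d) / 101)
}

#' Gait Profile Score of a cycle
#'
#' Single gait-quality index in degrees: the root-mean-square of the nine
#' Gait Variable Scores, `GPS = sqrt( (1/N) * sum_n GVS_n^2 )` with `N = 9`.
#'
#' @inheritParams gvs
#' @return Non-negative GPS in degrees.
#' @export
gps <- function(cycle, ref) {
  stopifnot(is_gait_cycle(cycle), inherits(ref, "normative_reference"))
  d <- unclass(cycle) - ref$ref_values
  # column means of squared deviations are the GVS^2; their mean is GPS^2
  sqrt(mean(colMeans(d * d)))
}

#' Movement Analysis Profile
#'
#' The nine GVS values plus the GPS, presented together.
#'
#' @inheritParams gvs
#' @return A list of class `movement_analysis_profile` with elements `gvs`
#'   (named numeric vector, length 9, degrees) and `gps` (degrees). The GPS is
#'   the RMS of the nine GVS entries by construction.
#' @export
map_profile <- function(cycle, ref) {
  stopifnot(is_gait_cycle(cycle), inherits(ref, "normative_reference"))
  d <- unclass(cycle) - ref$ref_values
  gvs_vec <- sqrt(colMeans(d * d))
  names(gvs_vec) <- angle_names()
  structure(list(gvs = gvs_vec, gps = sqrt(mean(gvs_vec^2))),
            class = "movement_analysis_profile")
}

#' @export
print.movement_analysis_profile <- function(x, digits = 2, ...) {
  cat("<movement_analysis_profile> GPS =", round(x$gps, digits), "deg\n")
  print(round(x$gvs, digits))
  invisible(x)
}

#' Average GPS of a session
#'
#' Arithmetic mean of the per-cycle GPS over all cycles of one gait session.
#'
#' @param session A [gait_session()].
#' @param ref A [normative_reference()].
#' @return Mean GPS in degrees.
#' @export
session_avg_gps <- function(session, ref) {
  stopifnot(inherits(session, "gait_session"))
  if (length(session$cycles) == 0L) stop("empty session", call. = FALSE)
  mean(vapply(session$cycles, gps, numeric(1), ref = ref))
}

#' Per-cycle GPS/GVS table for a cohort
#'
#' Scores every cycle of every session against the reference.
#'
#' @param cohort A [gait_cohort()].
#' @param ref A [normative_reference()].
#' @return A data.frame with columns `patient_id`, `session_datetime`,
#'   `cycle_id`, `gvs_1` .. `gvs_9` (degrees) and `gps` (degrees).
#' @export
score_cohort <- function(cohort, ref) {
  stopifnot(inherits(cohort, "gait_cohort"))
  rows <- list()
  for (s in cohort$sessions) {
    for (cy in s$cycles) {
      prof <- map_profile(cy, ref)
      row <- data.frame(patient_id = s$patient_id,
                        session_datetime = fmt_dt(s$session_datetime),
                        cycle_id = attr(cy, "cycle_id"),
                        stringsAsFactors = FALSE)
      for (n in 1:9) row[[paste0("gvs_", n)]] <- prof$gvs[[n]]
      row$gps <- prof$gps
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) {
    out <- data.frame(patient_id = character(), session_datetime = character(),
                      cycle_id = character(), stringsAsFactors = FALSE)
    for (n in 1:9) out[[paste0("gvs_", n)]] <- numeric()
    out$gps <- numeric()
    return(out)
  }
  do.call(rbind, rows)
}
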