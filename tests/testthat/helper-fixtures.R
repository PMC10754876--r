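# Shared fixtures: all built in code at test time.

# deterministic pseudo-random cycle (valid angle range)
rand_cycle <- function(seed, scale = 30, id = paste0("c", seed)) {
  rng <- local_rng(seed)
  gait_cycle(matrix(rng$rnorm(101 * 9, 0, scale / 3), 101, 9), cycle_id = id)
}

test_reference <- function(seed = 424) {
  generate_reference(seed)
}

# cycle whose GPS against ref is exactly g: ref + g * unit-GPS deviation shape
cycle_with_gps <- function(ref, g, seed, id = paste0("g", seed)) {
  rng <- local_rng(seed)
  shape <- matrix(rng$rnorm(101 * 9), 101, 9)
  shape <- shape / sqrt(mean(colMeans(shape^2)))
  gait_cycle(ref$ref_values + g * shape, cycle_id = id)
}

# session of cycles with prescribed GPS values
session_with_gps <- function(ref, gps_values, patient = "P1",
                             datetime = "2015-03-01 09:00:00",
                             equipment = "none", seed = 1) {
  cycles <- lapply(seq_along(gps_values), function(i) {
    cycle_with_gps(ref, gps_values[i], seed = seed * 1000 + i,
                   id = sprintf("%s_%s_c%d", patient, datetime, i))
  })
  gait_session(patient, datetime, equipment, cycles)
}

# brute-force GVS/GPS oracle: explicit summation loops
oracle_gvs <- function(cycle, ref, n) {
  cm <- unname(unclass(cycle))
  rm <- unname(ref$ref_values)
  acc <- 0
  for (t in 1:101) {
    d <- cm[t, n + 1] - rm[t, n + 1]
    acc <- acc + d * d
  }
  sqrt(acc / 101)
}

oracle_gps <- function(cycle, ref) {
  acc <- 0
  for (n in 0:8) acc <- acc + oracle_gvs(cycle, ref, n)^2
  sqrt(acc / 9)
}

# naive 2D DFT oracle: matrix form of the double summation over t and n
oracle_dft2 <- function(m) {
  Tt <- nrow(m); N <- ncol(m)
  Et <- exp(-2i * pi * outer(0:(Tt - 1), 0:(Tt - 1)) / Tt)
  En <- exp(-2i * pi * outer(0:(N - 1), 0:(N - 1)) / N)
  (Et %*% m %*% t(En)) / (Tt * N)
}
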