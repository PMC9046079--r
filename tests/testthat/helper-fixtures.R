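# Shared fixtures: all built in code, no stored data.

# A minimal well table: one plate, a handful of wells, all three assays.
toyWellTable <- function() {
  grid <- expand.grid(well_row = 1:2, well_col = 1:3,
                      assay = screenAssays(), stringsAsFactors = FALSE)
  grid$role <- ifelse(grid$well_col == 3L, "NO_CELL",
                      ifelse(grid$well_col == 2L, "VEHICLE_A", "COMPOUND"))
  data.frame(screen_id = "toy", donor = "m1", plate = "P1",
             well_row = grid$well_row, well_col = grid$well_col,
             role = grid$role,
             treatment_id = ifelse(grid$role == "COMPOUND", "cmpdX", ""),
             target_annotation = ifelse(grid$role == "COMPOUND", "tgtX", ""),
             dose_uM = ifelse(grid$role == "COMPOUND", 10, NA_real_),
             assay = grid$assay,
             raw_value = 1000 + 10 * grid$well_row + grid$well_col,
             stringsAsFactors = FALSE)
}

# Small but complete synthetic screen config for fast end-to-end tests.
smallConfig <- function(seed = 1, ...) {
  simulationConfig(seed = seed, donors = 3L, platesPerDonor = 1L,
                   nCompounds = 40L, nTargets = 20L, ...)
}

# Config with every nuisance term switched off: effects are exact (the
# effect scale is pinned at 0.1 log10 so spiked effects survive the
# noise-free limit).
cleanConfig <- function(seed = 1, ...) {
  defaults <- list(seed = seed, donors = 3L, platesPerDonor = 1L,
                   nCompounds = 20L, nTargets = 10L,
                   noiseSdLog10 = c(ATP = 1e-9, LYZ.NS = 1e-9, LYZ.S = 1e-9),
                   effectSdLog10 = c(ATP = 0.1, LYZ.NS = 0.1, LYZ.S = 0.1),
                   plateSdLog10 = 0, spatialAmplitudeLog10 = 0,
                   backgroundEffectSd = 0,
                   hitSpec = data.frame(), toxicitySpec = data.frame())
  dots <- list(...)
  defaults[names(dots)] <- dots
  do.call(simulationConfig, defaults)
}

# Build a ScreenDataset for one plate directly from a matrix of log10 values
# (roles all COMPOUND unless overridden), for normalization unit tests.
plateFromMatrix <- function(m, role = "COMPOUND", assay = "LYZ.NS",
                            donor = "m1", plate = "P1") {
  idx <- which(!is.na(m), arr.ind = TRUE)
  is_cmp <- role == "COMPOUND"
  w <- data.frame(screen_id = "fix", donor = donor, plate = plate,
                  well_row = idx[, 1L], well_col = idx[, 2L],
                  role = role,
                  treatment_id = if (is_cmp) sprintf("t%04d",
                                                     seq_len(nrow(idx)))
                                 else "",
                  target_annotation = "",
                  dose_uM = if (is_cmp) 1 else NA_real_,
                  assay = assay, raw_value = 10^m[idx],
                  stringsAsFactors = FALSE)
  ScreenDataset(w, geometry = dim(m))
}

# Independent Monte-Carlo oracle for the noncentral t CDF:
# P(T <= x) = E[ pnorm(x * sqrt(V/df) - ncp) ], V ~ chi-square(df).
mcNoncentralTCDF <- function(x, df, ncp, draws) {
  vals <- pnorm(x * sqrt(draws / df) - ncp)
  c(est = mean(vals), se = sd(vals) / sqrt(length(vals)))
}
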