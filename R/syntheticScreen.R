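#' Configuration for the synthetic screen generator
#'
#' Describes a multiplexed organoid screen to simulate: plate geometry and
#' counts, the compound library, the four-dose design, control-well layout,
#' log10-scale signal levels and noise, the smooth spatial plate artifact,
#' and the spiked treatment effects with their Hill dose--response. Defaults
#' reproduce the primary-screen design: 433 compounds against 184 annotated
#' targets at doses 0.08, 0.4, 2 and 10 uM, randomly distributed across 5
#' plates of a 384-well layout with interspersed vehicle and no-cell wells,
#' replicated over 3 biological donors.
#'
#' @param seed Integer seed; the generator draws from a single stream in a
#'   fixed documented order (placement, latent background effects, then per
#'   plate and assay: spatial surface, plate offset, well noise), so
#'   identical configs are byte-identical.
#' @param donors Number of biological replicates (donor organoid lines).
#' @param platesPerDonor Plates holding the library for one donor.
#' @param geometry Integer \code{c(rows, cols)}.
#' @param nCompounds,nTargets Library size and number of unique annotated
#'   targets (targets are assigned round-robin).
#' @param dosesUM Dose series in micromolar.
#' @param vehiclePerRole Vehicle (DMSO) wells per plate for each of the four
#'   stimulation-order roles A--D.
#' @param noCellPerPlate Background (no-cell) wells per plate.
#' @param baselineLog10 Named log10 signal baselines per assay for cell-laden
#'   wells.
#' @param backgroundLog10 Named log10 background levels per assay for no-cell
#'   wells.
#' @param stimEffectLog10 Log10 increment of lysozyme signal in a stimulated
#'   assay phase (applies to vehicle roles stimulated in that phase and to
#'   compound wells in the LYZ.S phase, which follow the role-A scheme).
#' @param noiseSdLog10 Named per-assay log10 well noise SD.
#' @param effectSdLog10 Named per-assay log10 scale converting a true SSMD
#'   \code{beta} into a log10 signal shift (\code{effect = beta *
#'   effectSdLog10[assay] * Hill(dose)}). Defaults to \code{noiseSdLog10},
#'   which makes the designed SSMD the effect in units of well noise; set it
#'   independently to probe the noise-free limit with non-vanishing effects.
#' @param plateSdLog10 SD of the random per-plate x assay offset.
#' @param spatialAmplitudeLog10 Amplitude of the smooth row/column/edge
#'   artifact added to every plate x assay (0 disables it).
#' @param spatialEdgeWeight Relative weight of the edge-row/column offset
#'   within the spatial artifact (0 = purely smooth polynomial ramp;
#'   default 0.5 mixes in the sharp edge effects plate readers show).
#' @param backgroundEffectSd SD (in SSMD units) of the per-treatment latent
#'   background effect: a target-selective inhibitor library is broadly
#'   bioactive, so every compound draws a latent effect \code{eta ~ Normal(0,
#'   backgroundEffectSd)} applied identically to both LYZ assays (abundance
#'   type, correlation 1) and coupled into ATP at \code{atpCoupling * eta},
#'   all following the default Hill dose--response. This term carries the
#'   donor-to-donor replicate correlation of group fold changes into the
#'   band reported for the screen (about 0.5--0.75 at the default 1.5); set
#'   it to 0 for a library of exact nulls plus the spiked hits.
#' @param atpCoupling Fraction of the latent LYZ effect coupled into ATP
#'   (hits tend to raise viability); default 0.5.
#' @param hitSpec \code{data.frame(treatment_id, assay, beta, ec50_uM, hill)}
#'   of spiked effects: \code{beta} is the true SSMD at full Hill occupancy,
#'   converted to a log10 shift via \code{beta * effectSdLog10[assay]}.
#'   Treatments listed for both LYZ assays share the same deterministic
#'   latent effect (abundance-type hits, correlation 1); listing only
#'   \code{LYZ.S} gives a secretion-only hit. \code{NULL} = [defaultHitSpec()]
#'   scaled to the library; use \code{data.frame()} for no hits.
#' @param toxicitySpec \code{data.frame(treatment_id, dose_threshold_uM,
#'   atp_drop_log10)}: ATP drops by the stated amount at doses at or above
#'   the threshold. \code{NULL} = [defaultToxicitySpec()]; \code{data.frame()}
#'   for none.
#' @param plateReplicates,wellsPerDosePerPlate Validation-screen layout: the
#'   number of plate replicates and wells per treatment-dose on each plate
#'   (replicate SSMD n = product, default 4 x 2 = 8).
#' @param validationVehiclePerRole Vehicle wells per role on a validation
#'   plate (default 25, i.e. 100 vehicle wells for ATP normalization).
#' @return A list of class \code{"simulationConfig"}.
#' @seealso [simulatePrimaryScreen()], [simulateValidationScreen()]
#' @export
simulationConfig <- function(seed = 1L,
                             donors = 3L,
                             platesPerDonor = 5L,
                             geometry = c(16L, 24L),
                             nCompounds = 433L,
                             nTargets = 184L,
                             dosesUM = c(0.08, 0.4, 2, 10),
                             vehiclePerRole = 6L,
                             noCellPerPlate = 8L,
                             baselineLog10 = c(ATP = 5.0, LYZ.NS = 3.0,
                                               LYZ.S = 3.1),
                             backgroundLog10 = c(ATP = 3.5, LYZ.NS = 2.2,
                                                 LYZ.S = 2.2),
                             stimEffectLog10 = 0.15,
                             noiseSdLog10 = c(ATP = 0.08, LYZ.NS = 0.10,
                                              LYZ.S = 0.10),
                             effectSdLog10 = noiseSdLog10,
                             plateSdLog10 = 0.05,
                             spatialAmplitudeLog10 = 0.05,
                             spatialEdgeWeight = 0.5,
                             backgroundEffectSd = 1.5,
                             atpCoupling = 0.5,
                             hitSpec = NULL,
                             toxicitySpec = NULL,
                             plateReplicates = 4L,
                             wellsPerDosePerPlate = 2L,
                             validationVehiclePerRole = 25L) {
  if (any(noiseSdLog10 <= 0)) stopf("noiseSdLog10 must be positive")
  if (is.null(hitSpec)) hitSpec <- defaultHitSpec(nCompounds)
  if (is.null(toxicitySpec)) toxicitySpec <- defaultToxicitySpec(nCompounds)
  if (nrow(hitSpec) && anyDuplicated(hitSpec[c("treatment_id", "assay")]))
    stopf("hitSpec has duplicate (treatment_id, assay) rows")
  cfg <- list(seed = as.integer(seed), donors = as.integer(donors),
              platesPerDonor = as.integer(platesPerDonor),
              geometry = as.integer(geometry),
              nCompounds = as.integer(nCompounds),
              nTargets = as.integer(nTargets),
              dosesUM = as.numeric(dosesUM),
              vehiclePerRole = as.integer(vehiclePerRole),
              noCellPerPlate = as.integer(noCellPerPlate),
              baselineLog10 = baselineLog10,
              backgroundLog10 = backgroundLog10,
              stimEffectLog10 = stimEffectLog10,
              noiseSdLog10 = noiseSdLog10,
              effectSdLog10 = effectSdLog10,
              plateSdLog10 = plateSdLog10,
              spatialAmplitudeLog10 = spatialAmplitudeLog10,
              spatialEdgeWeight = spatialEdgeWeight,
              backgroundEffectSd = backgroundEffectSd,
              atpCoupling = atpCoupling,
              hitSpec = hitSpec, toxicitySpec = toxicitySpec,
              plateReplicates = as.integer(plateReplicates),
              wellsPerDosePerPlate = as.integer(wellsPerDosePerPlate),
              validationVehiclePerRole = as.integer(validationVehiclePerRole))
  class(cfg) <- "simulationConfig"
  cfg
}

#' Default spiked-hit specification
#'
#' A realistic mixture scaled to the library size: strong abundance hits
#' (true SSMD 3 in both LYZ assays, shared latent effect), weak hits (SSMD 1
#' in both), and secretion-only hits (SSMD 3 in LYZ.S alone), all with a Hill
#' dose--response (EC50 0.5 uM, slope 1.5) so the two upper doses carry
#' near-full effect.
#'
#' @param nCompounds Library size; hit counts scale as roughly 2/1/1 percent.
#' @return \code{data.frame(treatment_id, assay, beta, ec50_uM, hill)}.
#' @export
defaultHitSpec <- function(nCompounds = 433L) {
  nStrong <- max(1L, round(nCompounds * 0.02))
  nWeak <- max(1L, round(nCompounds * 0.01))
  nSecr <- max(1L, round(nCompounds * 0.01))
  ids <- sprintf("cmpd%04d", seq_len(nStrong + nWeak + nSecr))
  strong <- ids[seq_len(nStrong)]
  weak <- ids[nStrong + seq_len(nWeak)]
  secr <- ids[nStrong + nWeak + seq_len(nSecr)]
  rbind(
    data.frame(treatment_id = rep(strong, each = 2L),
               assay = rep(c("LYZ.NS", "LYZ.S"), nStrong),
               beta = 3, ec50_uM = 0.5, hill = 1.5,
               stringsAsFactors = FALSE),
    data.frame(treatment_id = rep(weak, each = 2L),
               assay = rep(c("LYZ.NS", "LYZ.S"), nWeak),
               beta = 1, ec50_uM = 0.5, hill = 1.5,
               stringsAsFactors = FALSE),
    data.frame(treatment_id = secr, assay = "LYZ.S",
               beta = 3, ec50_uM = 0.5, hill = 1.5,
               stringsAsFactors = FALSE)
  )
}

#' Default toxicity specification
#'
#' About one percent of the library loses ATP signal (0.5 log10) at the two
#' highest doses, reproducing the low-value ATP tails of toxic compounds.
#'
#' @param nCompounds Library size.
#' @return \code{data.frame(treatment_id, dose_threshold_uM, atp_drop_log10)}.
#' @export
defaultToxicitySpec <- function(nCompounds = 433L) {
  nTox <- max(1L, round(nCompounds * 0.01))
  first <- max(1L, round(nCompounds * 0.9))
  data.frame(treatment_id = sprintf("cmpd%04d", first - 1L + seq_len(nTox)),
             dose_threshold_uM = 2, atp_drop_log10 = 0.5,
             stringsAsFactors = FALSE)
}

# Hill fractional occupancy; dose 0 -> 0, dose >> ec50 -> 1.
hillFraction <- function(dose, ec50, hill) {
  dose^hill / (dose^hill + ec50^hill)
}

# Smooth spatial artifact for one plate: low-order polynomial ramp plus an
# edge-row/column offset, centred to mean zero, scaled so its SD equals the
# configured amplitude. Coefficients are drawn from the active RNG stream.
.spatialSurface <- function(nr, nc, amplitude, edgeWeight = 0.5) {
  if (amplitude <= 0) return(matrix(0, nr, nc))
  co <- stats::runif(4L, -1, 1)
  r <- (seq_len(nr) - (nr + 1) / 2) / nr
  cc <- (seq_len(nc) - (nc + 1) / 2) / nc
  surf <- outer(r, cc, function(x, y) co[1L] * x + co[2L] * y + co[3L] * x * y)
  edge <- matrix(0, nr, nc)
  edge[c(1L, nr), ] <- 1
  edge[, c(1L, nc)] <- 1
  surf <- surf + co[4L] * edgeWeight * edge
  surf <- surf - mean(surf)
  s <- stats::sd(as.vector(surf))
  if (s > 0) surf <- surf * (amplitude / s)
  surf
}

# Look-up of spiked log10 effects: returns effect in log10 units for each
# (treatment, dose, assay) row triple.
.spikedEffect <- function(treatment, dose, assay, hitSpec, noiseSd) {
  eff <- numeric(length(treatment))
  if (!nrow(hitSpec)) return(eff)
  key <- paste(treatment, assay, sep = "\r")
  hkey <- paste(hitSpec$treatment_id, hitSpec$assay, sep = "\r")
  m <- match(key, hkey)
  has <- !is.na(m)
  if (any(has)) {
    hs <- hitSpec[m[has], , drop = FALSE]
    eff[has] <- hs$beta * noiseSd[assay[has]] *
      hillFraction(dose[has], hs$ec50_uM, hs$hill)
  }
  eff
}

# Latent background effect (log10) for each (treatment, dose, assay) triple.
# eta is a named per-treatment draw on the SSMD scale; both LYZ assays share
# it (abundance-type), ATP receives atpCoupling * eta. Default Hill curve.
.backgroundEffect <- function(treatment, dose, assay, eta, cfg) {
  eff <- numeric(length(treatment))
  if (!length(eta)) return(eff)
  m <- match(treatment, names(eta))
  has <- !is.na(m)
  if (!any(has)) return(eff)
  scale <- ifelse(assay[has] == "ATP", cfg$atpCoupling, 1)
  eff[has] <- eta[m[has]] * scale * cfg$effectSdLog10[assay[has]] *
    hillFraction(dose[has], 0.5, 1.5)
  eff
}

.toxEffect <- function(treatment, dose, assay, toxicitySpec) {
  eff <- numeric(length(treatment))
  if (!nrow(toxicitySpec)) return(eff)
  m <- match(treatment, toxicitySpec$treatment_id)
  has <- !is.na(m) & assay == "ATP"
  if (any(has)) {
    ts <- toxicitySpec[m[has], , drop = FALSE]
    eff[has] <- -ts$atp_drop_log10 * (dose[has] >= ts$dose_threshold_uM)
  }
  eff
}

# Build the well records for one physical plate given a layout data.frame
# (well_row, well_col, role, treatment_id, dose_uM) and per-assay surfaces.
.emitPlate <- function(layout, cfg, screenId, donor, plateId,
                       eta = numeric(), truthOffsets = FALSE) {
  assays <- screenAssays()
  nwell <- nrow(layout)
  recs <- vector("list", length(assays))
  offs <- if (truthOffsets) vector("list", length(assays)) else NULL
  for (ai in seq_along(assays)) {
    assay <- assays[ai]
    surf <- .spatialSurface(cfg$geometry[1L], cfg$geometry[2L],
                            cfg$spatialAmplitudeLog10, cfg$spatialEdgeWeight)
    plate_off <- stats::rnorm(1L, 0, cfg$plateSdLog10)
    spatial <- surf[cbind(layout$well_row, layout$well_col)]
    is_nc <- layout$role == "NO_CELL"
    base <- ifelse(is_nc, cfg$backgroundLog10[assay],
                   cfg$baselineLog10[assay])
    stim <- numeric(nwell)
    if (assay == "LYZ.NS") {
      stim[layout$role %in% stimulatedRoles("NS")] <- cfg$stimEffectLog10
    } else if (assay == "LYZ.S") {
      stim[layout$role %in% c(stimulatedRoles("S"), "COMPOUND")] <-
        cfg$stimEffectLog10
    }
    dose <- ifelse(is.na(layout$dose_uM), 0, layout$dose_uM)
    eff <- .spikedEffect(layout$treatment_id, dose, rep(assay, nwell),
                         cfg$hitSpec, cfg$effectSdLog10) +
      .backgroundEffect(layout$treatment_id, dose, rep(assay, nwell),
                        eta, cfg) +
      .toxEffect(layout$treatment_id, dose, rep(assay, nwell),
                 cfg$toxicitySpec)
    eff[layout$role != "COMPOUND"] <- 0
    noise <- stats::rnorm(nwell, 0, cfg$noiseSdLog10[assay])
    log10v <- base + plate_off + spatial + stim + eff + noise
    recs[[ai]] <- data.frame(
      screen_id = screenId, donor = donor, plate = plateId,
      well_row = layout$well_row, well_col = layout$well_col,
      role = layout$role, treatment_id = layout$treatment_id,
      target_annotation = layout$target_annotation,
      dose_uM = layout$dose_uM, assay = assay,
      raw_value = 10^log10v, stringsAsFactors = FALSE)
    if (truthOffsets)
      offs[[ai]] <- data.frame(plate = plateId, assay = assay,
                               well_row = layout$well_row,
                               well_col = layout$well_col,
                               spatial_offset_log10 = spatial,
                               stringsAsFactors = FALSE)
  }
  list(records = do.call(rbind, recs),
       offsets = if (truthOffsets) do.call(rbind, offs) else NULL)
}

.truthEffects <- function(treatments, doses, cfg, eta = numeric()) {
  grid <- expand.grid(treatment_id = treatments, dose_uM = doses,
                      assay = screenAssays(), stringsAsFactors = FALSE)
  grid$true_effect_log10 <-
    .spikedEffect(grid$treatment_id, grid$dose_uM, grid$assay, cfg$hitSpec,
                  cfg$effectSdLog10) +
    .backgroundEffect(grid$treatment_id, grid$dose_uM, grid$assay, eta, cfg) +
    .toxEffect(grid$treatment_id, grid$dose_uM, grid$assay, cfg$toxicitySpec)
  grid$true_ssmd <- grid$true_effect_log10 / cfg$noiseSdLog10[grid$assay]
  grid[order(grid$treatment_id, grid$dose_uM, grid$assay), , drop = FALSE]
}

#' Simulate a primary screen with known ground truth
#'
#' Generates the full well table of a primary screen: each compound-dose
#' combination placed once per donor replicate set (library layout shared
#' across donors, randomized by seed), vehicle wells in the four
#' stimulation-order roles, and no-cell background wells. Per well and assay
#' the raw value is \code{10^(baseline + plate offset + smooth spatial
#' surface + treatment effect * Hill(dose) + toxicity + stimulation +
#' Normal(0, noise))}. Deterministic given the config seed.
#'
#' @param config A [simulationConfig()].
#' @return List with \code{dataset} (a \linkS4class{ScreenDataset}) and
#'   \code{truth}: \code{effects} (\code{treatment_id, dose_uM, assay,
#'   true_effect_log10, true_ssmd}) and \code{wellOffsets} (the spatial
#'   offset applied to every well).
#' @examples
#' cfg <- simulationConfig(seed = 7, donors = 2, platesPerDonor = 1,
#'                         nCompounds = 40, nTargets = 20)
#' sim <- simulatePrimaryScreen(cfg)
#' sim$dataset
#' @export
simulatePrimaryScreen <- function(config) {
  stopifnot(inherits(config, "simulationConfig"))
  cfg <- config
  nwellPlate <- prod(cfg$geometry)
  nControls <- 4L * cfg$vehiclePerRole + cfg$noCellPerPlate
  capacity <- cfg$platesPerDonor * (nwellPlate - nControls)
  combos <- expand.grid(treatment_id = sprintf("cmpd%04d",
                                               seq_len(cfg$nCompounds)),
                        dose_uM = cfg$dosesUM, stringsAsFactors = FALSE)
  if (nrow(combos) > capacity)
    stopf("plate capacity exceeded: %d compound wells > %d available",
          nrow(combos), capacity)
  targets <- sprintf("target%03d",
                     rep_len(seq_len(cfg$nTargets), cfg$nCompounds))
  names(targets) <- sprintf("cmpd%04d", seq_len(cfg$nCompounds))

  withSeed(cfg$seed, {
    ## 1) placement: shuffle combos, deal across plates, shuffle positions
    combos <- combos[sample.int(nrow(combos)), , drop = FALSE]
    perPlate <- nwellPlate - nControls
    plate_of <- rep(seq_len(cfg$platesPerDonor), each = perPlate,
                    length.out = nrow(combos))
    layouts <- vector("list", cfg$platesPerDonor)
    fillRoles <- rep_len(paste0("VEHICLE_", c("A", "B", "C", "D")),
                         nwellPlate)
    for (p in seq_len(cfg$platesPerDonor)) {
      cp <- combos[plate_of == p, , drop = FALSE]
      nFill <- nwellPlate - nrow(cp) - nControls
      roles <- c(rep("COMPOUND", nrow(cp)),
                 rep(paste0("VEHICLE_", c("A", "B", "C", "D")),
                     each = cfg$vehiclePerRole),
                 rep("NO_CELL", cfg$noCellPerPlate),
                 if (nFill > 0L) fillRoles[seq_len(nFill)])
      pos <- sample.int(nwellPlate)
      layouts[[p]] <- data.frame(
        well_row = ((pos - 1L) %% cfg$geometry[1L]) + 1L,
        well_col = ((pos - 1L) %/% cfg$geometry[1L]) + 1L,
        role = roles,
        treatment_id = c(cp$treatment_id,
                         rep("", nwellPlate - nrow(cp))),
        dose_uM = c(cp$dose_uM, rep(NA_real_, nwellPlate - nrow(cp))),
        stringsAsFactors = FALSE)
      layouts[[p]]$target_annotation <-
        ifelse(layouts[[p]]$role == "COMPOUND",
               targets[layouts[[p]]$treatment_id], "")
    }
    ## 2) latent per-treatment background effects
    eta <- stats::rnorm(cfg$nCompounds, 0, cfg$backgroundEffectSd)
    names(eta) <- sprintf("cmpd%04d", seq_len(cfg$nCompounds))
    ## 3-5) per physical plate: spatial surfaces, plate offsets, noise
    all_recs <- list()
    all_offs <- list()
    k <- 0L
    for (d in seq_len(cfg$donors)) {
      donor <- sprintf("m%d", d)
      for (p in seq_len(cfg$platesPerDonor)) {
        k <- k + 1L
        plateId <- sprintf("%s_P%d", donor, p)
        em <- .emitPlate(layouts[[p]], cfg, "primary", donor, plateId,
                         eta = eta, truthOffsets = TRUE)
        all_recs[[k]] <- em$records
        all_offs[[k]] <- em$offsets
      }
    }
    dataset <- ScreenDataset(
      do.call(rbind, all_recs), geometry = cfg$geometry,
      provenance = list(generator = "simulatePrimaryScreen",
                        seed = cfg$seed, config = unclass(cfg)))
    truth <- list(
      effects = .truthEffects(sprintf("cmpd%04d", seq_len(cfg$nCompounds)),
                              cfg$dosesUM, cfg, eta = eta),
      backgroundEta = eta,
      wellOffsets = do.call(rbind, all_offs))
    list(dataset = dataset, truth = truth)
  })
}

#' Simulate a validation (secondary) screen
#'
#' Emulates the confirmatory screen design: each primary hit tested at a
#' narrowed dose range around its optimal dose (\code{2x} above, the optimal,
#' \code{2x} and \code{4x} below), on \code{plateReplicates} plate replicates
#' with \code{wellsPerDosePerPlate} wells each (default 4 x 2 = 8 well
#' replicates per dose), against large vehicle blocks (default 25 wells per
#' stimulation role, so 100 vehicle wells for ATP). Treatments present in the
#' config's \code{hitSpec} carry their spiked effects; others are inactive.
#'
#' @param config A [simulationConfig()].
#' @param hits \code{data.frame(treatment_id, optimal_dose_uM)} of primary
#'   hits to retest; must be nonempty.
#' @return As [simulatePrimaryScreen()]: list with \code{dataset} and
#'   \code{truth}.
#' @export
simulateValidationScreen <- function(config, hits) {
  stopifnot(inherits(config, "simulationConfig"))
  cfg <- config
  if (!is.data.frame(hits) || nrow(hits) == 0L)
    stopf("hits must be a nonempty data.frame(treatment_id, optimal_dose_uM)")
  if (anyDuplicated(hits$treatment_id))
    stopf("duplicate treatment ids in hits")
  nwellPlate <- prod(cfg$geometry)
  doseTab <- do.call(rbind, lapply(seq_len(nrow(hits)), function(i) {
    data.frame(treatment_id = hits$treatment_id[i],
               dose_uM = hits$optimal_dose_uM[i] * c(2, 1, 0.5, 0.25),
               stringsAsFactors = FALSE)
  }))
  nCtl <- 4L * cfg$validationVehiclePerRole + cfg$noCellPerPlate
  nCompoundWells <- nrow(doseTab) * cfg$wellsPerDosePerPlate
  if (nCompoundWells + nCtl > nwellPlate)
    stopf("plate capacity exceeded: %d wells needed > %d",
          nCompoundWells + nCtl, nwellPlate)
  targets <- sprintf("target%03d",
                     rep_len(seq_len(cfg$nTargets), nrow(hits)))
  names(targets) <- hits$treatment_id

  withSeed(cfg$seed, {
    cp <- doseTab[rep(seq_len(nrow(doseTab)),
                      each = cfg$wellsPerDosePerPlate), , drop = FALSE]
    nFill <- nwellPlate - nrow(cp) - nCtl
    roles <- c(rep("COMPOUND", nrow(cp)),
               rep(paste0("VEHICLE_", c("A", "B", "C", "D")),
                   each = cfg$validationVehiclePerRole),
               rep("NO_CELL", cfg$noCellPerPlate),
               rep_len(paste0("VEHICLE_", c("A", "B", "C", "D")),
                       max(nFill, 0L)))
    pos <- sample.int(nwellPlate)
    layout <- data.frame(
      well_row = ((pos - 1L) %% cfg$geometry[1L]) + 1L,
      well_col = ((pos - 1L) %/% cfg$geometry[1L]) + 1L,
      role = roles,
      treatment_id = c(cp$treatment_id, rep("", nwellPlate - nrow(cp))),
      dose_uM = c(cp$dose_uM, rep(NA_real_, nwellPlate - nrow(cp))),
      stringsAsFactors = FALSE)
    layout$target_annotation <- ifelse(layout$role == "COMPOUND",
                                       targets[layout$treatment_id], "")
    eta <- stats::rnorm(nrow(hits), 0, cfg$backgroundEffectSd)
    names(eta) <- hits$treatment_id
    all_recs <- list()
    all_offs <- list()
    for (r in seq_len(cfg$plateReplicates)) {
      rep_id <- sprintf("r%d", r)
      em <- .emitPlate(layout, cfg, "validation", rep_id,
                       sprintf("%s_V1", rep_id), eta = eta,
                       truthOffsets = TRUE)
      all_recs[[r]] <- em$records
      all_offs[[r]] <- em$offsets
    }
    dataset <- ScreenDataset(
      do.call(rbind, all_recs), geometry = cfg$geometry,
      provenance = list(generator = "simulateValidationScreen",
                        seed = cfg$seed, config = unclass(cfg),
                        hits = hits))
    truth <- list(
      effects = .truthEffects(unique(doseTab$treatment_id),
                              sort(unique(doseTab$dose_uM)), cfg, eta = eta),
      backgroundEta = eta,
      wellOffsets = do.call(rbind, all_offs))
    list(dataset = dataset, truth = truth)
  })
}

#' Simulate multinomial cell-composition count tables
#'
#' Generates per-timepoint cell-type counts for a control and a treated
#' condition with designed (cell type vs rest) odds ratios, the ground truth
#' for the Fisher enrichment statistics. Treated fractions are derived from
#' the control fractions by multiplying each type's odds by its designed
#' odds ratio; if the resulting fractions do not sum to one (an inconsistent
#' OR design) they are renormalised, and the returned truth table reports the
#' odds ratios realised by the final fractions (equal to the designed values
#' whenever the design is consistent).
#'
#' @param seed Integer seed (multinomial sampling is deterministic given it).
#' @param timepoints Vector of stratum labels (e.g. days).
#' @param baseFractions Named numeric of control cell-type fractions; must
#'   sum to 1 within 1e-9.
#' @param designedOR \code{data.frame(cell_type, timepoint, or)}; pairs not
#'   listed default to OR 1. All ORs must be positive.
#' @param cellsPerSample Cells drawn per (condition, timepoint) sample.
#' @return List with \code{table} (\code{data.frame(sample_id, condition,
#'   timepoint, cell_type, n_cells)}) and \code{truth}
#'   (\code{data.frame(cell_type, timepoint, designed_or, true_or,
#'   control_fraction, treated_fraction)}).
#' @examples
#' cc <- simulateCompositionCounts(1, timepoints = "d6",
#'   baseFractions = c(paneth = 0.2, other = 0.8),
#'   designedOR = data.frame(cell_type = "paneth", timepoint = "d6", or = 2),
#'   cellsPerSample = 5000)
#' head(cc$table)
#' @export
simulateCompositionCounts <- function(seed, timepoints, baseFractions,
                                      designedOR = NULL,
                                      cellsPerSample = 10000L) {
  if (abs(sum(baseFractions) - 1) > 1e-9)
    stopf("baseFractions must sum to 1 (got %.12f)", sum(baseFractions))
  if (is.null(names(baseFractions)) || any(!nzchar(names(baseFractions))))
    stopf("baseFractions must be named by cell type")
  if (!is.null(designedOR) && nrow(designedOR) && any(designedOR$or <= 0))
    stopf("designed odds ratios must be > 0")
  types <- names(baseFractions)
  timepoints <- as.character(timepoints)
  orLookup <- function(type, tp) {
    if (is.null(designedOR) || !nrow(designedOR)) return(1)
    hit <- designedOR$cell_type == type & designedOR$timepoint == tp
    if (any(hit)) designedOR$or[hit][1L] else 1
  }
  withSeed(seed, {
    tabs <- list()
    truths <- list()
    for (tp in timepoints) {
      p <- baseFractions
      ors <- vapply(types, orLookup, numeric(1L), tp = tp)
      odds <- ors * p / (1 - p)
      q <- odds / (1 + odds)
      q <- q / sum(q)
      truths[[tp]] <- data.frame(
        cell_type = types, timepoint = tp, designed_or = unname(ors),
        true_or = unname((q / (1 - q)) / (p / (1 - p))),
        control_fraction = unname(p), treated_fraction = unname(q),
        stringsAsFactors = FALSE)
      nc <- as.vector(stats::rmultinom(1L, cellsPerSample, p))
      nt <- as.vector(stats::rmultinom(1L, cellsPerSample, q))
      tabs[[tp]] <- rbind(
        data.frame(sample_id = sprintf("control_%s", tp),
                   condition = "control", timepoint = tp, cell_type = types,
                   n_cells = nc, stringsAsFactors = FALSE),
        data.frame(sample_id = sprintf("treated_%s", tp),
                   condition = "treated", timepoint = tp, cell_type = types,
                   n_cells = nt, stringsAsFactors = FALSE))
    }
    list(table = do.call(rbind, c(tabs, list(make.row.names = FALSE))),
         truth = do.call(rbind, c(truths, list(make.row.names = FALSE))))
  })
}
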