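# Seeded generators that emulate the study's cohort structure -- feature
# tables, LC-MS cohorts, serum batches, growth curves and dose-response
# counts -- each paired with the ground truth needed for recovery tests.
# Every generator is a pure function of its config: same seed, same output.

#' Simulation configuration
#'
#' Collects every parameter of the synthetic-data generators, with defaults
#' mirroring the cohort the pipeline is built for: one healthy control and
#' four pancreatic-cancer subclones, six replicates per arm, spiked
#' internal standards (50 pmol C16 Cer-d7, 50 pmol C17 Cer, 100 pmol
#' S1P-d7), ~10\% intensity CV, 2\% retention-time jitter for genuine
#' lipids against 40\% for decoys, ~70\% between-batch serum variation,
#' a planted +1.1 log shift of the S1P/C16 Cer rheostat in the cancer
#' groups (S1P up, C16 Cer down), halving of S1P under SKI-II treatment,
#' the measured proliferation rates of each group (0.72-1.12 \%/h), and
#' per-group EC50 truths from the combined-dose reading of the cell-death
#' assay.
#'
#' @param seed Mandatory integer seed; every generator is deterministic
#'   given the config.
#' @param groups Group labels; the first is the healthy control.
#' @param replicates Biological replicates per group and arm.
#' @param nDbLipids Size of the toy reference database (>= 5: S1P, C16
#'   ceramide, C17 ceramide and the two deuterated standards are always
#'   included).
#' @param nNoisePeaks Untagged noise peaks per shotgun run.
#' @param nDecoys Decoy lipids with unstable retention times per cohort.
#' @param massBiasPpm Systematic relative mass error planted on observed
#'   m/z (ppm).
#' @param intensityCv Lognormal CV of AUC intensities.
#' @param rtJitterCv Retention-time CV of genuine lipids.
#' @param decoyRtCv Retention-time CV of decoy lipids.
#' @param batchCv Target median across-batch CV of serum lipid
#'   concentrations.
#' @param nBatches,nSerumLipids Serum-batch table dimensions.
#' @param s1pShift,c16Shift Log-scale shifts applied to S1P and C16 Cer
#'   amounts in every cancer group (defaults +0.55 / -0.55, i.e. a +1.1
#'   planted log-ratio shift).
#' @param skiIiEffect Multiplier on S1P under SKI-II treatment.
#' @param s1pBasePmol,c16BasePmol True control-group amounts of the two
#'   targeted sphingolipids.
#' @param noiseBaseline Instrument noise floor (intensity units).
#' @param rates Baseline proliferation rates per group (\% confluence/h).
#' @param growthDose50 Dose (uM) halving the growth rate.
#' @param growthDoses SKI-II doses for the proliferation assay (uM).
#' @param growthReplicates Replicate growth curves per condition.
#' @param growthTimes Sampling times in hours.
#' @param growthNoiseSd Additive confluence measurement noise (sd, \%).
#' @param ec50Truth True EC50 per group (uM).
#' @param hill,respMin,respMax 4PL shape parameters of the death curve.
#' @param doses Dose grid for the cell-death assay (uM).
#' @param nEvents Flow-cytometry events counted per dose.
#' @return A validated list with class \code{"SimConfig"}.
#' @export
simConfig <- function(seed,
                      groups = c("hT", "pA", "pB", "pC", "pD"),
                      replicates = 6L,
                      nDbLipids = 60L,
                      nNoisePeaks = 200L,
                      nDecoys = 10L,
                      massBiasPpm = 0,
                      intensityCv = 0.1,
                      rtJitterCv = 0.02,
                      decoyRtCv = 0.4,
                      batchCv = 0.7,
                      nBatches = 3L,
                      nSerumLipids = 800L,
                      s1pShift = 0.55,
                      c16Shift = -0.55,
                      skiIiEffect = 0.5,
                      s1pBasePmol = 30,
                      c16BasePmol = 80,
                      noiseBaseline = 1,
                      rates = c(hT = 0.72, pA = 1.08, pB = 1.12,
                                pC = 1.05, pD = 1.04),
                      growthDose50 = 15,
                      growthDoses = c(0, 4.3, 13, 39),
                      growthReplicates = 4L,
                      growthTimes = 0:110,
                      growthNoiseSd = 0.3,
                      ec50Truth = c(hT = 14, pA = 10, pB = 8,
                                    pC = 12, pD = 9),
                      hill = 2,
                      respMin = 0.05,
                      respMax = 0.95,
                      doses = c(0, 1, 2, 4, 8, 16, 32, 64),
                      nEvents = 10000L) {
  if (missing(seed)) stop("'seed' is mandatory")
  cfg <- as.list(environment())
  cvs <- c(cfg$intensityCv, cfg$rtJitterCv, cfg$decoyRtCv, cfg$batchCv)
  if (any(cvs < 0)) stop("CVs must be >= 0")
  if (cfg$skiIiEffect <= 0) stop("multipliers must be > 0")
  if (any(cfg$ec50Truth <= 0)) stop("'ec50Truth' must be > 0")
  if (cfg$replicates < 2L) stop("at least 2 replicates per group")
  structure(cfg, class = "SimConfig")
}

#' Internal-standard spike table
#'
#' The three spiked standards with their amounts (from 20 uL of 2.5 uM,
#' 2.5 uM and 5 uM stock respectively) and the analyte each quantifies.
#'
#' @return \code{data.frame} with \code{name}, \code{pmol},
#'   \code{target}.
#' @export
internalStandardTable <- function() {
  data.frame(
    name = c("C16Cer_d7", "C17Cer", "S1P_d7"),
    pmol = c(spikeAmount(20, 2.5), spikeAmount(20, 2.5), spikeAmount(20, 5)),
    target = c("C16Cer", "C16Cer", "S1P"),
    stringsAsFactors = FALSE
  )
}

# mass difference of one deuterium substitution
.D_SHIFT <- 7 * (2.01410177785 - 1.00782503207)

.mandatoryRecords <- function() {
  lipidDb(
    id = c("S1P", "C16Cer", "C17Cer", "S1P_d7", "C16Cer_d7"),
    name = c("sphingosine-1-phosphate", "Cer(d18:1/16:0)", "Cer(d18:1/17:0)",
             "S1P-d7", "Cer(d18:1-d7/16:0)"),
    category = rep("sphingolipids", 5),
    formula = c("C18H38NO5P", "C34H67NO3", "C35H69NO3", NA, NA),
    monoisotopic_mass = c(NA, NA, NA,
                          formulaMass("C18H38NO5P") + .D_SHIFT,
                          formulaMass("C34H67NO3") + .D_SHIFT),
    fragments = c("264.2686", "264.2686", "264.2686", "271.3125", "271.3125")
  )
}

#' Generate a toy lipid reference database
#'
#' Deterministic stand-in reference list spanning all eight lipid
#' categories, always containing the two targeted sphingolipids (S1P,
#' C16 ceramide), the odd-chain C17 ceramide and the two deuterated
#' internal standards. Remaining records get random masses inside the
#' acquisition windows, optionally rejection-sampled so that no two
#' records fall within \code{minSeparationPpm} of one another (an
#' unambiguous-matching fixture).
#'
#' @param n Number of records (>= 5).
#' @param seed Integer seed.
#' @param minSeparationPpm Optional minimum pairwise mass separation.
#' @return Validated database \code{DataFrame}.
#' @export
makeToyDb <- function(n = 60L, seed = 1L, minSeparationPpm = NULL) {
  mand <- .mandatoryRecords()
  if (n < nrow(mand)) {
    stop("n too small: the ", nrow(mand), " mandatory targets must fit")
  }
  extra <- n - nrow(mand)
  cats <- rep(lipidCategories(), length.out = max(extra, 0L))
  withSeed(subSeed(seed, 11L), {
    masses <- numeric(0)
    accepted <- mand$monoisotopic_mass
    for (i in seq_len(extra)) {
      repeat {
        m <- exp(stats::runif(1, log(150), log(1200)))
        ok <- is.null(minSeparationPpm) ||
          all(abs(1e6 * (m - accepted) / accepted) >= minSeparationPpm)
        if (ok) break
      }
      masses <- c(masses, m)
      accepted <- c(accepted, m)
    }
    if (extra > 0L) {
      ids <- sprintf("LIP%03d", seq_len(extra))
      extraDb <- lipidDb(
        id = ids, name = paste0("synthetic lipid ", ids), category = cats,
        monoisotopic_mass = masses,
        fragments = sprintf("%.4f", masses * 0.6)
      )
      db <- rbind(mand, extraDb)
    } else {
      db <- mand
    }
    db
  })
}

.WINDOWS <- data.frame(
  label = c("75-250", "250-400", "400-600", "600-800", "800-1800"),
  lo = c(75, 250, 400, 600, 800),
  hi = c(250, 400, 600, 800, 1800)
)

.assignWindow <- function(mz) {
  idx <- findInterval(mz, .WINDOWS$lo)
  idx[mz > max(.WINDOWS$hi) | mz < min(.WINDOWS$lo)] <- NA_integer_
  .WINDOWS$label[idx]
}

# lognormal multiplicative noise with the requested CV and unit mean on the
# log scale (exp(sd * z)); cv 0 gives exactly 1.
.lnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  exp(stats::rnorm(n, 0, sqrt(log(1 + cv^2))))
}

#' Simulate a direct-injection (shotgun) run
#'
#' Emits one feature table: every database lipid as a protonated peak with
#' lognormal intensity, spiked internal standards, uniform-m/z noise peaks
#' at the configured baseline, and a global multiplicative ppm mass bias.
#' Per acquisition window the five most intense ions carry the MS2 flag,
#' emulating top-5 fragmentation selection. Every emitted peak is tagged
#' in the ground truth; only explicitly tagged noise is unassigned.
#'
#' @param db Lipid database (e.g. [makeToyDb()]).
#' @param config [simConfig()].
#' @return List with \code{features} (sample_id, mz, intensity, rt,
#'   polarity, window, has_ms2), \code{groundTruth} (per-peak kind, lipid
#'   id, true m/z and amount) and \code{standards} (observed vs
#'   theoretical standard m/z for calibration).
#' @export
simulateShotgunRun <- function(db, config) {
  stopifnot(inherits(config, "SimConfig"))
  istd <- internalStandardTable()
  biasFactor <- 1 + config$massBiasPpm * 1e-6
  withSeed(subSeed(config$seed, 23L), {
    theo <- theoreticalMz(db$monoisotopic_mass, massShift = PROTON_MASS)
    isStd <- db$id %in% istd$name
    amount <- numeric(nrow(db))
    amount[!isStd] <- exp(stats::rnorm(sum(!isStd), log(100), 1)) *
      .lnoise(sum(!isStd), config$intensityCv)
    amount[isStd] <- istd$pmol[match(db$id[isStd], istd$name)] *
      .lnoise(sum(isStd), config$intensityCv)

    nz <- config$nNoisePeaks
    noiseMz <- stats::runif(nz, 75, 1800)
    noiseInt <- config$noiseBaseline * .lnoise(nz, 0.3)

    mz <- c(theo * biasFactor, noiseMz)
    intensity <- c(amount * 100, noiseInt)
    kind <- c(ifelse(isStd, "standard", "true"), rep("noise", nz))
    lipid <- c(db$id, rep(NA_character_, nz))

    feat <- data.frame(
      sample_id = "run1", mz = mz, intensity = intensity, rt = NA_real_,
      polarity = "positive", window = .assignWindow(mz),
      has_ms2 = FALSE, stringsAsFactors = FALSE
    )
    for (w in unique(stats::na.omit(feat$window))) {
      inw <- which(feat$window == w)
      top <- inw[order(-feat$intensity[inw])][seq_len(min(5L, length(inw)))]
      feat$has_ms2[top] <- TRUE
    }
    gt <- data.frame(feature = seq_len(nrow(feat)), kind = kind,
                     lipid_id = lipid,
                     true_mz = c(theo, rep(NA_real_, nz)),
                     true_amount = c(amount, rep(NA_real_, nz)),
                     stringsAsFactors = FALSE)
    std <- data.frame(lipid_id = db$id[isStd],
                      observed_mz = theo[isStd] * biasFactor,
                      theoretical_mz = theo[isStd],
                      stringsAsFactors = FALSE)
    list(features = feat, groundTruth = gt, standards = std)
  })
}

#' Simulate an LC-MS cohort with planted rheostat effects
#'
#' Generates the paired vehicle / SKI-II cohort: per group and replicate,
#' intracellular samples carrying every database lipid with lognormal
#' intensity noise, per-lipid reference retention times with small jitter,
#' decoy lipids with large RT scatter, spiked internal standards, and
#' blank-medium samples without cellular lipids. Cancer groups (all but
#' the first group label) receive the planted S1P/C16 Cer shifts;
#' treatment multiplies S1P by \code{skiIiEffect} on the same noise draws
#' as the matching vehicle sample, so an effect of 1 reproduces the
#' vehicle values exactly.
#'
#' @param db Lipid database containing the targeted sphingolipids.
#' @param config [simConfig()].
#' @return List with \code{observations} (long table: sample_id, group,
#'   treatment, replicate, compartment, lipid_id, auc, rt),
#'   \code{standards} (per-sample internal-standard AUC, snr and spiked
#'   pmol) and \code{groundTruth} (per-sample true pmol of S1P and C16
#'   Cer, planted log-ratio shift, decoy ids).
#' @export
simulateLcmsCohort <- function(db, config) {
  stopifnot(inherits(config, "SimConfig"))
  istd <- internalStandardTable()
  groups <- config$groups
  control <- groups[1]
  lipids <- setdiff(db$id, istd$name)
  decoys <- if (config$nDecoys > 0) sprintf("DECOY%02d", seq_len(config$nDecoys)) else character()

  withSeed(subSeed(config$seed, 37L), {
    baseAmt <- stats::setNames(exp(stats::rnorm(length(lipids), log(100), 1)), lipids)
    baseAmt["S1P"] <- config$s1pBasePmol
    baseAmt["C16Cer"] <- config$c16BasePmol
    refRt <- stats::setNames(stats::runif(length(lipids), 2, 20), lipids)
    decoyRt <- stats::setNames(stats::runif(length(decoys), 2, 20), decoys)
    decoyAmt <- stats::setNames(exp(stats::rnorm(length(decoys), log(50), 1)), decoys)
  })

  rtSd <- sqrt(log(1 + config$rtJitterCv^2))
  decoySd <- sqrt(log(1 + config$decoyRtCv^2))

  obs <- list(); stdRows <- list(); gtRows <- list()
  idx <- 0L
  for (g in groups) {
    s1pMult <- if (g == control) 1 else exp(config$s1pShift)
    c16Mult <- if (g == control) 1 else exp(config$c16Shift)
    for (r in seq_len(config$replicates)) {
      idx <- idx + 1L
      withSeed(subSeed(config$seed, 1000L + idx), {
        eps <- .lnoise(length(lipids), config$intensityCv)
        names(eps) <- lipids
        injection <- .lnoise(1, 0.05)
        rtObs <- refRt * exp(stats::rnorm(length(lipids), 0, rtSd))
        dAmt <- decoyAmt * .lnoise(length(decoys), config$intensityCv)
        dRt <- decoyRt * exp(stats::rnorm(length(decoys), 0, decoySd))
        isEps <- .lnoise(nrow(istd), config$intensityCv)
        isSnr <- stats::runif(nrow(istd), 50, 150)
        for (trt in c("vehicle", "SKI-II")) {
          amt <- baseAmt * eps
          amt["S1P"] <- amt["S1P"] * s1pMult
          amt["C16Cer"] <- amt["C16Cer"] * c16Mult
          if (trt == "SKI-II") amt["S1P"] <- amt["S1P"] * config$skiIiEffect
          sid <- sprintf("%s_%s_r%d", g, ifelse(trt == "vehicle", "veh", "ski"), r)
          obs[[length(obs) + 1L]] <- data.frame(
            sample_id = sid, group = g, treatment = trt, replicate = r,
            compartment = "intracellular",
            lipid_id = c(lipids, decoys),
            auc = c(amt, dAmt) * 100 * injection,
            rt = c(rtObs, dRt), stringsAsFactors = FALSE
          )
          stdRows[[length(stdRows) + 1L]] <- data.frame(
            sample_id = sid, name = istd$name, pmol = istd$pmol,
            target = istd$target,
            auc = istd$pmol * isEps * 100 * injection,
            snr = isSnr, stringsAsFactors = FALSE
          )
          gtRows[[length(gtRows) + 1L]] <- data.frame(
            sample_id = sid, group = g, treatment = trt, replicate = r,
            s1p_pmol = unname(amt["S1P"]), c16_pmol = unname(amt["C16Cer"]),
            stringsAsFactors = FALSE
          )
        }
      })
    }
  }
  # blank-medium samples: serum-derived lipids only, no cellular signal
  nBlank <- 3L
  mediumLipids <- lipids[seq_len(ceiling(length(lipids) * 0.3))]
  for (b in seq_len(nBlank)) {
    idx <- idx + 1L
    withSeed(subSeed(config$seed, 1000L + idx), {
      eps <- .lnoise(length(mediumLipids), config$intensityCv)
      rtObs <- refRt[mediumLipids] *
        exp(stats::rnorm(length(mediumLipids), 0, rtSd))
      sid <- sprintf("blank_r%d", b)
      obs[[length(obs) + 1L]] <- data.frame(
        sample_id = sid, group = "blank",
        treatment = "none", replicate = b, compartment = "blank",
        lipid_id = mediumLipids,
        auc = baseAmt[mediumLipids] * 0.2 * eps * 100,
        rt = rtObs, stringsAsFactors = FALSE
      )
      # standards are spiked into every sample, blanks included
      stdRows[[length(stdRows) + 1L]] <- data.frame(
        sample_id = sid, name = istd$name, pmol = istd$pmol,
        target = istd$target,
        auc = istd$pmol * .lnoise(nrow(istd), config$intensityCv) * 100,
        snr = stats::runif(nrow(istd), 50, 150), stringsAsFactors = FALSE
      )
    })
  }

  gt <- do.call(rbind, gtRows)
  list(
    observations = do.call(rbind, obs),
    standards = do.call(rbind, stdRows),
    groundTruth = list(
      samples = gt,
      trueLogRatioShift = config$s1pShift - config$c16Shift,
      decoys = decoys,
      referenceRt = refRt,
      baseAmounts = baseAmt
    )
  )
}

# Calibrate the lognormal sdlog so that the MEDIAN empirical across-batch
# CV (population sd / mean of nBatches draws) matches the target. The
# sample CV of a few lognormal draws sits well below the distribution CV,
# so the generator solves for sdlog numerically on a fixed internal draw.
.calibrateBatchSdlog <- function(targetCv, nBatches, m = 20000L) {
  if (targetCv == 0) return(0)
  z <- withSeed(777L + nBatches, matrix(stats::rnorm(m * nBatches), m, nBatches))
  medcv <- function(s) {
    x <- exp(s * z)
    mu <- rowMeans(x)
    sdp <- sqrt(rowMeans((x - mu)^2))
    stats::median(sdp / mu)
  }
  stats::uniroot(function(s) medcv(s) - targetCv, c(1e-3, 4), tol = 1e-5)$root
}

#' Simulate serum batches
#'
#' Batch-by-lipid concentration table with lognormal per-lipid batch
#' effects and no systematic shift between batches, calibrated so that
#' the median empirical across-batch CV matches \code{batchCv}.
#'
#' @param config [simConfig()].
#' @return List with \code{concentrations} (lipids x batches matrix) and
#'   \code{groundTruth} (base concentrations, calibrated sdlog).
#' @export
simulateSerumBatches <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  if (config$nBatches < 2L) stop("at least 2 batches are required")
  sdlog <- .calibrateBatchSdlog(config$batchCv, config$nBatches)
  withSeed(subSeed(config$seed, 53L), {
    base <- exp(stats::rnorm(config$nSerumLipids, log(10), 1.5))
    eff <- matrix(exp(stats::rnorm(config$nSerumLipids * config$nBatches, 0, sdlog)),
                  config$nSerumLipids, config$nBatches)
    conc <- base * eff
    dimnames(conc) <- list(sprintf("serum%03d", seq_len(config$nSerumLipids)),
                           sprintf("batch%d", seq_len(config$nBatches)))
    list(concentrations = conc,
         groundTruth = list(base = base, sdlog = sdlog))
  })
}

#' Simulate confluence growth curves
#'
#' Logistic growth curves (or exactly linear curves for the linear
#' regime) with additive measurement noise and a dose-dependent rate
#' reduction \code{rate / (1 + dose / growthDose50)}. The analytic
#' maximal slope of each logistic curve, \code{r K / 4}, is recorded as
#' ground truth.
#'
#' @param config [simConfig()].
#' @param shape \code{"logistic"} or \code{"linear"}.
#' @return List with \code{curves} (long table: group, dose_uM,
#'   replicate, time_h, confluence_pct) and \code{groundTruth} (true
#'   maximal slope per group and dose).
#' @export
simulateGrowth <- function(config, shape = c("logistic", "linear")) {
  shape <- match.arg(shape)
  stopifnot(inherits(config, "SimConfig"))
  K <- 100; c0 <- 15
  tt <- config$growthTimes
  rows <- list(); gtRows <- list()
  idx <- 0L
  for (g in config$groups) {
    for (d in config$growthDoses) {
      slope <- unname(config$rates[g]) / (1 + d / config$growthDose50)
      gtRows[[length(gtRows) + 1L]] <- data.frame(
        group = g, dose_uM = d, true_slope = slope)
      for (r in seq_len(config$growthReplicates)) {
        idx <- idx + 1L
        y <- if (shape == "logistic") {
          rr <- 4 * slope / K
          t0 <- log((K - c0) / c0) / rr
          K / (1 + exp(-rr * (tt - t0)))
        } else {
          c0 + slope * tt
        }
        if (config$growthNoiseSd > 0) {
          y <- y + withSeed(subSeed(config$seed, 5000L + idx),
                            stats::rnorm(length(tt), 0, config$growthNoiseSd))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, dose_uM = d, replicate = r, time_h = tt,
          confluence_pct = pmin(pmax(y, 0), 100), stringsAsFactors = FALSE)
      }
    }
  }
  list(curves = do.call(rbind, rows), groundTruth = do.call(rbind, gtRows))
}

#' Simulate flow-cytometry dose-response counts
#'
#' Binomial dead-cell counts at each dose from a four-parameter
#' log-logistic curve with the configured per-group EC50 and hill slope.
#'
#' @param config [simConfig()].
#' @return List with \code{counts} (group, dose_uM, n_events, n_dead,
#'   fraction_dead) and \code{groundTruth} (true EC50 per group, hill,
#'   asymptotes).
#' @export
simulateDoseResponse <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  rows <- list()
  idx <- 0L
  for (g in config$groups) {
    e50 <- unname(config$ec50Truth[g])
    p <- config$respMin + (config$respMax - config$respMin) *
      config$doses^config$hill / (config$doses^config$hill + e50^config$hill)
    idx <- idx + 1L
    nDead <- withSeed(subSeed(config$seed, 9000L + idx),
                      stats::rbinom(length(config$doses), config$nEvents, p))
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, dose_uM = config$doses, n_events = config$nEvents,
      n_dead = nDead, fraction_dead = nDead / config$nEvents,
      stringsAsFactors = FALSE)
  }
  list(counts = do.call(rbind, rows),
       groundTruth = list(ec50 = config$ec50Truth, hill = config$hill,
                          respMin = config$respMin, respMax = config$respMax))
}
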