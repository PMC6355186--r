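# Mass recalibration, noise filtering, ppm-tolerance matching and RT-CV
# verification: the annotation stage between raw feature tables and
# quantitation.

#' Signed relative mass error in parts per million
#'
#' \code{1e6 * (observed - theoretical) / theoretical}.
#'
#' @param observed Observed m/z (Da).
#' @param theoretical Theoretical m/z (Da), must be positive.
#' @return Signed ppm error, vectorized.
#' @examples
#' ppmError(500.025, 500)  # +50 ppm
#' @export
ppmError <- function(observed, theoretical) {
  if (any(!is.finite(theoretical) | theoretical <= 0)) {
    stop("theoretical m/z must be positive")
  }
  1e6 * (observed - theoretical) / theoretical
}

#' Annotation configuration
#'
#' Bundles the quality thresholds of the annotation pipeline. Defaults are
#' the acquisition conventions of the assay: a 50 ppm mass tolerance, an
#' inclusion cutoff at twice the instrumental noise baseline, a 25\%
#' retention-time CV ceiling, and evaluation of RT CVs only for lipids
#' observed in at least 80\% of samples.
#'
#' @param tolPpm Mass tolerance in ppm (> 0).
#' @param noiseFactor Multiple of the noise baseline a feature must reach.
#' @param rtCvMax Maximum retention-time CV (fraction, < 1).
#' @param minSampleFraction Minimum fraction of samples a lipid must be
#'   observed in before its RT CV is evaluated.
#' @return A list with class \code{"AnnotationConfig"}.
#' @export
annotationConfig <- function(tolPpm = 50, noiseFactor = 2, rtCvMax = 0.25,
                             minSampleFraction = 0.8) {
  if (tolPpm <= 0) stop("'tolPpm' must be > 0")
  if (noiseFactor <= 0) stop("'noiseFactor' must be > 0")
  if (rtCvMax <= 0 || rtCvMax >= 1) stop("'rtCvMax' must be in (0, 1)")
  if (minSampleFraction <= 0 || minSampleFraction > 1) {
    stop("'minSampleFraction' must be in (0, 1]")
  }
  structure(list(tolPpm = tolPpm, noiseFactor = noiseFactor,
                 rtCvMax = rtCvMax, minSampleFraction = minSampleFraction),
            class = "AnnotationConfig")
}

#' Fit a mass calibration against internal standards
#'
#' Least-squares line mapping observed standard m/z to their theoretical
#' m/z. With a single standard an offset-only model is fit (slope fixed at
#' 1); with two or more, ordinary least squares. Per-standard signed ppm
#' residuals after correction are stored on the model.
#'
#' @param observed Observed m/z of the spiked standards (Da, > 0).
#' @param theoretical Theoretical m/z of the same standards, same length.
#' @return A \linkS4class{MassCalibration}.
#' @examples
#' fitMassCalibration(c(500.010, 700.014), c(500, 700))
#' @export
fitMassCalibration <- function(observed, theoretical) {
  if (length(observed) == 0L) stop("at least one standard is required")
  if (length(observed) != length(theoretical)) {
    stop("'observed' and 'theoretical' must have equal length")
  }
  if (any(observed <= 0) || any(theoretical <= 0)) {
    stop("standard m/z must be positive")
  }
  if (length(observed) == 1L) {
    slope <- 1
    intercept <- theoretical - observed
  } else {
    fit <- stats::lm.fit(cbind(1, observed), theoretical)
    intercept <- unname(fit$coefficients[1])
    slope <- unname(fit$coefficients[2])
  }
  corrected <- slope * observed + intercept
  new("MassCalibration", slope = slope, intercept = intercept,
      nStandards = length(observed),
      residualPpm = ppmError(corrected, theoretical))
}

#' Apply a mass calibration to a feature table
#'
#' Replaces each feature's m/z by \code{slope * mz + intercept}. All other
#' columns (intensity, RT, ...) and the row order are untouched.
#'
#' @param features Feature table with an \code{mz} column.
#' @param model A \linkS4class{MassCalibration}.
#' @return The feature table with corrected \code{mz}.
#' @export
applyCalibration <- function(features, model) {
  stopifnot(is(model, "MassCalibration"))
  validObject(model)
  features$mz <- model@slope * features$mz + model@intercept
  features
}

#' Instrumental noise baseline of a run
#'
#' The baseline detection level across all spectra of a run, estimated as
#' the median of the lowest intensity decile. The decile median is robust
#' to the bulk of genuine peaks while tracking the floor the instrument
#' reports between them.
#'
#' @param features Feature table with an \code{intensity} column, or a
#'   numeric vector of intensities.
#' @param decile Fraction of lowest intensities summarized (default 0.1).
#' @return A single intensity value.
#' @examples
#' estimateNoiseBaseline(c(rep(1, 90), rep(1000, 10)))  # 1
#' @export
estimateNoiseBaseline <- function(features, decile = 0.1) {
  intensity <- if (is.numeric(features)) features else features$intensity
  if (length(intensity) == 0L) stop("empty feature list")
  cut <- stats::quantile(intensity, decile, names = FALSE, type = 7)
  stats::median(intensity[intensity <= cut])
}

#' Remove features below the noise threshold
#'
#' Keeps exactly the features whose intensity is at least
#' \code{noiseFactor} times the baseline; the boundary is inclusive
#' ("at least twice the level of the instrumental noise").
#'
#' @param features Feature table with an \code{intensity} column.
#' @param baseline Noise baseline (>= 0), e.g. from
#'   [estimateNoiseBaseline()].
#' @param noiseFactor Multiplier on the baseline (default 2).
#' @return The retained rows of \code{features}.
#' @export
filterNoise <- function(features, baseline, noiseFactor = 2) {
  if (!is.finite(baseline) || baseline < 0) stop("negative baseline")
  features[features$intensity >= noiseFactor * baseline, , drop = FALSE]
}

#' Annotate features against a lipid database
#'
#' For each (calibrated) feature every (record, adduct) pair whose
#' theoretical m/z lies within \code{tolPpm} is located. In \code{"best"}
#' mode the assignment with the smallest absolute ppm error is reported
#' (exact ties resolved by lexicographic lipid id) with all candidates
#' retained in an audit column; in \code{"all"} mode one row per candidate
#' is emitted. Features with no match are returned unannotated
#' (\code{lipid_id} \code{NA}). The result is, by construction, identical
#' to a brute-force all-pairs ppm scan.
#'
#' Adducts are only searched against features of matching polarity when
#' the feature table carries a \code{polarity} column.
#'
#' @param features Feature table with columns \code{mz} and optionally
#'   \code{sample_id}, \code{intensity}, \code{rt}, \code{polarity},
#'   \code{has_ms2}.
#' @param db Lipid database ([lipidDb()]).
#' @param adducts Adduct table ([defaultAdducts()]).
#' @param config [annotationConfig()].
#' @param mode \code{"best"} (one row per feature) or \code{"all"}.
#' @return \code{data.frame} with columns \code{feature}, \code{mz},
#'   \code{lipid_id}, \code{adduct}, \code{ppm_error},
#'   \code{fragment_support}, \code{n_candidates}, \code{candidates}, plus
#'   \code{sample_id}/\code{intensity}/\code{rt} when present in the input.
#' @export
matchFeatures <- function(features, db, adducts = defaultAdducts(),
                          config = annotationConfig(),
                          mode = c("best", "all")) {
  mode <- match.arg(mode)
  if (nrow(db) == 0L) stop("empty database")
  tol <- config$tolPpm

  grid <- do.call(rbind, lapply(seq_len(nrow(adducts)), function(a) {
    data.frame(lipid_id = db$id,
               adduct = adducts$name[a],
               polarity = adducts$polarity[a],
               theo = theoreticalMz(db$monoisotopic_mass,
                                    massShift = adducts$massShift[a],
                                    charge = adducts$charge[a]),
               hasFrag = !is.na(db$fragments) & nzchar(db$fragments),
               stringsAsFactors = FALSE)
  }))
  grid <- grid[order(grid$lipid_id, grid$adduct), , drop = FALSE]

  hasPol <- "polarity" %in% colnames(features)
  hasMs2 <- "has_ms2" %in% colnames(features)
  carry <- intersect(c("sample_id", "intensity", "rt"), colnames(features))

  rows <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    g <- grid
    if (hasPol) g <- g[g$polarity == features$polarity[i], , drop = FALSE]
    ppm <- ppmError(features$mz[i], g$theo)
    hit <- which(abs(ppm) <= tol)
    base <- cbind(
      data.frame(feature = i, mz = features$mz[i]),
      features[i, carry, drop = FALSE]
    )
    if (!length(hit)) {
      rows[[i]] <- cbind(base, data.frame(
        lipid_id = NA_character_, adduct = NA_character_,
        ppm_error = NA_real_, fragment_support = FALSE,
        n_candidates = 0L, candidates = ""))
      next
    }
    ord <- hit[order(abs(ppm[hit]), g$lipid_id[hit])]
    keep <- if (mode == "best") ord[1L] else ord
    support <- (if (hasMs2) isTRUE(features$has_ms2[i]) else FALSE) & g$hasFrag[keep]
    rows[[i]] <- cbind(
      base[rep(1L, length(keep)), , drop = FALSE],
      data.frame(lipid_id = g$lipid_id[keep], adduct = g$adduct[keep],
                 ppm_error = ppm[keep], fragment_support = support,
                 n_candidates = length(hit),
                 candidates = paste(unique(g$lipid_id[ord]), collapse = ";"),
                 stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Retention-time CV verification filter
#'
#' Computes the coefficient of variation (population sd / mean) of each
#' lipid's retention time across samples, keeps lipids with CV at or below
#' \code{rtCvMax}, and reports lipids observed in fewer than
#' \code{minSampleFraction} of the samples separately instead of imputing.
#'
#' @param annotations Long table with columns \code{lipid_id},
#'   \code{sample_id} and \code{rt} (one RT observation per lipid per
#'   sample; rows with missing RT are ignored).
#' @param config [annotationConfig()].
#' @param nSamples Total number of samples in the experiment; defaults to
#'   the number of distinct \code{sample_id}s in \code{annotations}.
#' @return A list with \code{kept} (lipid ids passing), \code{cvTable}
#'   (per-lipid n, mean RT, CV and status) and \code{insufficient}
#'   (lipids observed in too few samples).
#' @export
rtCvFilter <- function(annotations, config = annotationConfig(),
                       nSamples = length(unique(annotations$sample_id))) {
  ann <- annotations[!is.na(annotations$rt), , drop = FALSE]
  if (nrow(ann) == 0L) stop("all retention times missing")
  if (nSamples < 2L) stop("at least 2 samples are required")

  byLipid <- split(ann, ann$lipid_id)
  tab <- do.call(rbind, lapply(byLipid, function(d) {
    n <- length(unique(d$sample_id))
    mu <- mean(d$rt)
    if (mu <= 0) stop("non-positive mean RT for lipid ", d$lipid_id[1])
    data.frame(lipid_id = d$lipid_id[1], n = n, mean_rt = mu,
               cv = popSd(d$rt) / mu, stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  tab$status <- ifelse(tab$n < config$minSampleFraction * nSamples,
                       "insufficient",
                       ifelse(tab$cv <= config$rtCvMax, "kept", "removed"))
  list(kept = tab$lipid_id[tab$status == "kept"],
       cvTable = tab,
       insufficient = tab$lipid_id[tab$status == "insufficient"])
}
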