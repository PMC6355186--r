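# Total-signal normalization, internal-standard targeted quantitation and
# the sphingolipid-rheostat ratio.

#' Total-signal normalization
#'
#' Divides each sample's AUC values by that sample's total AUC over the
#' quantified lipids, so every sample sums to 1. Unannotated noise features
#' are expected to have been removed first: the denominator is the sum over
#' the species quantified in each sample. Normalization is idempotent.
#'
#' For a plain matrix rows are samples and columns lipids; for a
#' \linkS4class{LipidomicsExperiment} samples are columns and the result
#' gains a \code{"normalized"} assay next to \code{"raw"}.
#'
#' @param x Matrix of non-negative AUC values, or a
#'   \linkS4class{LipidomicsExperiment}.
#' @return Same shape as the input, normalized.
#' @examples
#' normalizeTotal(matrix(c(1, 1, 3, 1), nrow = 2))
#' @export
setGeneric("normalizeTotal", function(x) standardGeneric("normalizeTotal"))

#' @rdname normalizeTotal
#' @export
setMethod("normalizeTotal", "matrix", function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("AUC values must be non-negative")
  tot <- rowSums(x, na.rm = TRUE)
  if (any(tot <= 0)) {
    stop("sample(s) with zero total signal: ",
         paste(which(tot <= 0), collapse = ", "))
  }
  sweep(x, 1, tot, "/")
})

#' @rdname normalizeTotal
#' @export
setMethod("normalizeTotal", "LipidomicsExperiment", function(x) {
  raw <- SummarizedExperiment::assay(x, "raw")
  norm <- t(normalizeTotal(t(raw)))
  SummarizedExperiment::assay(x, "normalized") <- norm
  validObject(x)
  x
})

#' Spiked amount of an internal standard
#'
#' \code{volume (uL) x concentration (uM) = amount (pmol)}; the unit
#' product is exact, e.g. 20 uL of 2.5 uM C16 Cer-d7 is 50 pmol and
#' 20 uL of 5 uM S1P-d7 is 100 pmol.
#'
#' @param volumeUl Spiked volume in microlitres (>= 0).
#' @param concUm Stock concentration in micromolar (>= 0).
#' @return Amount in pmol.
#' @examples
#' spikeAmount(20, 2.5)  # 50 pmol
#' spikeAmount(20, 5)    # 100 pmol
#' @export
spikeAmount <- function(volumeUl, concUm) {
  if (any(volumeUl < 0) || any(concUm < 0)) stop("negative input")
  volumeUl * concUm
}

#' Single-point internal-standard quantitation
#'
#' The proportional form \code{pmol_analyte / AUC_analyte =
#' pmol_IS / AUC_IS}, i.e. the analyte amount is
#' \code{pmol_IS * AUC_analyte / AUC_IS}. Exactly linear in the analyte
#' AUC and inverse in the standard AUC; a zero analyte AUC yields 0 pmol.
#'
#' @param aucAnalyte Analyte AUC (>= 0).
#' @param aucIs Internal-standard AUC in the same run (> 0).
#' @param pmolIs Spiked amount of the standard in pmol (> 0).
#' @return Analyte amount in pmol, vectorized.
#' @examples
#' quantifyByIS(aucAnalyte = 2e5, aucIs = 1e5, pmolIs = 100)  # 200 pmol
#' @export
quantifyByIS <- function(aucAnalyte, aucIs, pmolIs) {
  if (any(aucIs <= 0)) stop("unusable internal standard: AUC must be > 0")
  if (any(pmolIs <= 0)) stop("'pmolIs' must be > 0")
  if (any(aucAnalyte < 0)) stop("'aucAnalyte' must be >= 0")
  pmolIs * aucAnalyte / aucIs
}

#' Choose the internal standard with the best signal-to-noise
#'
#' Among candidate standards detected in a sample, returns the one with
#' the highest signal-to-noise ratio (the convention used when either
#' C16 Cer-d7 or C17 Cer may normalize C16 Cer). Exact ties are broken by
#' lexicographic name, with a message.
#'
#' @param candidates \code{data.frame} with columns \code{name} and
#'   \code{snr}; rows with missing snr are treated as undetected.
#' @return The selected row of \code{candidates}.
#' @export
selectInternalStandard <- function(candidates) {
  cand <- candidates[is.finite(candidates$snr), , drop = FALSE]
  if (nrow(cand) == 0L) stop("no internal standard detected in sample")
  best <- cand[cand$snr == max(cand$snr), , drop = FALSE]
  if (nrow(best) > 1L) {
    best <- best[order(best$name), , drop = FALSE]
    message("snr tie between standards; choosing '", best$name[1], "'")
  }
  best[1L, , drop = FALSE]
}

#' Sphingolipid-rheostat ratio
#'
#' The balance of pro-survival S1P to pro-apoptotic C16 ceramide, as a
#' linear ratio \code{s1p / c16} or its natural log. Both amounts must be
#' on the same normalization (both total-normalized AUC fractions or both
#' pmol). Non-positive amounts leave the rheostat undefined for that
#' sample and yield \code{NA} with a warning.
#'
#' @param s1p S1P amount(s), > 0.
#' @param c16 C16 ceramide amount(s), > 0, same length or length 1.
#' @param log If \code{TRUE} return \code{ln(s1p / c16)}.
#' @return Numeric vector of ratios.
#' @examples
#' sphingolipidRatio(3, 1)               # 3
#' sphingolipidRatio(exp(1), 1, log = TRUE)  # 1
#' @export
sphingolipidRatio <- function(s1p, c16, log = FALSE) {
  bad <- !is.finite(s1p) | !is.finite(c16) | s1p <= 0 | c16 <= 0
  r <- s1p / c16
  if (any(bad)) {
    warning("rheostat undefined for ", sum(bad),
            " sample(s) with non-positive amounts")
    r[bad] <- NA_real_
  }
  if (log) base::log(r) else r
}

#' Assemble a quantitation matrix from annotations
#'
#' Pivots a long annotation table (one row per annotated feature) into a
#' lipids-by-samples \linkS4class{LipidomicsExperiment}, summing AUC over
#' features assigned to the same lipid in the same sample. Unannotated
#' rows are dropped.
#'
#' @param annotations Output of [matchFeatures()] (best mode), with
#'   \code{sample_id}, \code{lipid_id} and \code{intensity} columns.
#' @param colData Optional per-sample metadata, row names matching
#'   \code{sample_id}s.
#' @return A \linkS4class{LipidomicsExperiment} with a \code{"raw"} assay.
#' @export
quantFromAnnotations <- function(annotations, colData = NULL) {
  ann <- annotations[!is.na(annotations$lipid_id), , drop = FALSE]
  if (nrow(ann) == 0L) stop("no annotated features")
  lipids <- sort(unique(ann$lipid_id))
  samples <- unique(ann$sample_id)
  raw <- matrix(0, nrow = length(lipids), ncol = length(samples),
                dimnames = list(lipids, samples))
  agg <- stats::aggregate(intensity ~ lipid_id + sample_id, data = ann, FUN = sum)
  raw[cbind(agg$lipid_id, agg$sample_id)] <- agg$intensity
  if (!is.null(colData)) colData <- colData[samples, , drop = FALSE]
  LipidomicsExperiment(raw, colData = colData)
}
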