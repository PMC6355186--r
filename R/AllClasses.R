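#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Mass calibration model
#'
#' A linear recalibration of observed m/z against the theoretical m/z of
#' spiked internal standards: corrected = slope * observed + intercept.
#' With a single standard the slope is fixed at 1 (offset-only model); with
#' two or more standards the line is an ordinary least-squares fit.
#'
#' @slot slope Dimensionless slope of the calibration line.
#' @slot intercept Intercept in Da.
#' @slot nStandards Number of internal standards the model was fit to.
#' @slot residualPpm Signed ppm residual of each standard after correction.
#'
#' @seealso [fitMassCalibration()], [applyCalibration()]
#' @export
setClass("MassCalibration",
  representation(
    slope = "numeric",
    intercept = "numeric",
    nStandards = "integer",
    residualPpm = "numeric"
  )
)

setValidity("MassCalibration", function(object) {
  msg <- character()
  if (length(object@slope) != 1L || !is.finite(object@slope)) {
    msg <- c(msg, "'slope' must be a single finite number")
  }
  if (length(object@intercept) != 1L || !is.finite(object@intercept)) {
    msg <- c(msg, "'intercept' must be a single finite number")
  }
  if (length(object@nStandards) != 1L || object@nStandards < 1L) {
    msg <- c(msg, "model must be derived from at least one standard")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn MassCalibration Compact display.
#' @param object A \code{MassCalibration}.
#' @export
setMethod("show", "MassCalibration", function(object) {
  cat("MassCalibration model\n")
  cat(sprintf("  corrected = %.8f * observed %+.6f Da\n",
              object@slope, object@intercept))
  cat(sprintf("  standards: %d, median |residual|: %.3f ppm\n",
              object@nStandards, stats::median(abs(object@residualPpm))))
  invisible(NULL)
})

#' @rdname MassCalibration
#' @param x A \code{MassCalibration}.
#' @export
calibrationSlope <- function(x) x@slope

#' @rdname MassCalibration
#' @export
calibrationIntercept <- function(x) x@intercept

#' @rdname MassCalibration
#' @export
residualPpm <- function(x) x@residualPpm

#' Samples-by-lipids quantitation container
#'
#' A \linkS4class{SummarizedExperiment} holding annotated lipid abundances:
#' rows are lipids, columns are samples. The \code{"raw"} assay carries AUC
#' intensities; [normalizeTotal()] adds a \code{"normalized"} assay in which
#' every sample (column) sums to 1 over the quantified lipids. Sample
#' metadata (group, treatment, compartment, replicate, batch) lives in
#' \code{colData}.
#'
#' @seealso [LipidomicsExperiment()], [normalizeTotal()]
#' @export
setClass("LipidomicsExperiment", contains = "SummarizedExperiment")

setValidity("LipidomicsExperiment", function(object) {
  msg <- character()
  anames <- SummarizedExperiment::assayNames(object)
  if (!("raw" %in% anames)) {
    msg <- c(msg, "a 'raw' assay of AUC intensities is required")
  } else {
    raw <- SummarizedExperiment::assay(object, "raw")
    if (!is.numeric(raw)) msg <- c(msg, "'raw' assay must be numeric")
    else if (any(is.finite(raw) & raw < 0)) {
      msg <- c(msg, "'raw' AUC values must be non-negative")
    }
  }
  if ("normalized" %in% anames) {
    norm <- SummarizedExperiment::assay(object, "normalized")
    tots <- colSums(norm, na.rm = TRUE)
    if (any(abs(tots - 1) > 1e-6 & tots != 0)) {
      msg <- c(msg, "'normalized' columns must each sum to 1")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LipidomicsExperiment
#'
#' @param raw Numeric matrix of AUC intensities, lipids in rows and samples
#'   in columns. Dimnames are used as lipid ids and sample ids.
#' @param colData Optional \code{DataFrame}/\code{data.frame} of sample
#'   metadata, one row per column of \code{raw}.
#' @param rowData Optional per-lipid metadata.
#'
#' @return A \linkS4class{LipidomicsExperiment}.
#' @examples
#' raw <- matrix(c(10, 30, 20, 40), nrow = 2,
#'               dimnames = list(c("S1P", "C16Cer"), c("s1", "s2")))
#' le <- LipidomicsExperiment(raw)
#' normalizeTotal(le)
#' @export
LipidomicsExperiment <- function(raw, colData = NULL, rowData = NULL) {
  raw <- as.matrix(raw)
  if (is.null(colData)) {
    colData <- S4Vectors::DataFrame(row.names = colnames(raw))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(raw = raw), colData = colData
  )
  if (!is.null(rowData)) SummarizedExperiment::rowData(se) <- rowData
  new("LipidomicsExperiment", se)
}
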