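# Group-comparison statistics and profiling computations applied across the
# omic layers: t-tests, BH correction, Dunnett-vs-control, Tukey-Kramer,
# fold-change and evidence filters, SNP density, CV, SVD PCA and
# complete-linkage clustering.

#' Two-sample t-test
#'
#' Welch's unequal-variance statistic for unpaired data, paired-difference
#' t for paired data, both two-sided. By convention, groups with zero
#' variance and zero mean difference give p = 1 (and p = 0 for a nonzero
#' difference with zero variance).
#'
#' @param a,b Numeric vectors, n >= 2 each; equal lengths when paired.
#' @param paired Paired-difference test instead of Welch.
#' @return One-row \code{data.frame}: \code{comparison},
#'   \code{statistic}, \code{df}, \code{p}.
#' @export
twoSampleTTest <- function(a, b, paired = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("at least 2 values per group")
  if (paired && length(a) != length(b)) stop("paired test needs equal lengths")
  res <- tryCatch(
    stats::t.test(a, b, paired = paired, var.equal = FALSE),
    error = function(e) NULL
  )
  if (is.null(res) || is.nan(res$p.value)) {
    # degenerate: essentially constant data
    delta <- if (paired) mean(a - b) else mean(a) - mean(b)
    stat <- if (delta == 0) 0 else sign(delta) * Inf
    p <- if (delta == 0) 1 else 0
    return(data.frame(comparison = if (paired) "paired" else "welch",
                      statistic = stat, df = NA_real_, p = p))
  }
  data.frame(comparison = if (paired) "paired" else "welch",
             statistic = unname(res$statistic), df = unname(res$parameter),
             p = res$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1, in the input order.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bhAdjust <- function(p) {
  .assertProb(p, "p")
  stats::p.adjust(p, method = "BH")
}

# Monte Carlo sample of max_i |T_i| for the Dunnett many-to-one statistic:
# T ~ equicorrelated multivariate t with correlation
# R_ij = sqrt(n_i n_j / ((n_i + n0)(n_j + n0))), df error degrees of freedom.
.dunnettMaxT <- function(ns, n0, df, nDraws, seed) {
  k <- length(ns)
  lam <- sqrt(ns / (ns + n0))
  R <- outer(lam, lam)
  diag(R) <- 1
  withSeed(seed, {
    Z <- matrix(stats::rnorm(nDraws * k), nrow = k)
    if (k > 1L) Z <- t(chol(R)) %*% Z
    S <- sqrt(stats::rchisq(nDraws, df) / df)
    maxT <- apply(abs(Z), 2, max) / S
    maxT
  })
}

#' Dunnett many-to-one comparisons
#'
#' Compares every treatment group against a designated control with
#' family-wise error control over the k contrasts. Statistics use the
#' pooled error variance; adjusted p-values are tail probabilities of
#' \code{max_i |T_i|} under the equicorrelated multivariate t, estimated by
#' seeded Monte Carlo (50,000 draws by default), so results are
#' deterministic given \code{seed}. With k = 1 the adjusted p equals the
#' pooled two-sample t-test p up to Monte Carlo error.
#'
#' @param values Numeric measurements.
#' @param groups Group label per value.
#' @param control Label of the control group.
#' @param alpha Family-wise level used for the significance flag.
#' @param nDraws Monte Carlo draws.
#' @param seed RNG seed for the draws.
#' @return \code{data.frame}, one row per treatment-vs-control contrast:
#'   \code{comparison}, \code{estimate}, \code{statistic}, \code{df},
#'   \code{p} (unadjusted pooled-t), \code{p_adjusted}, \code{significant}.
#' @export
dunnettVsControl <- function(values, groups, control, alpha = 0.05,
                             nDraws = 50000, seed = 1) {
  groups <- as.character(groups)
  if (!control %in% groups) stop("control group '", control, "' not present")
  sp <- split(values, groups)
  if (any(lengths(sp) < 2L)) stop("at least 2 replicates per group")
  trt <- setdiff(names(sp), control)
  k <- length(trt)
  if (k == 0L) stop("no treatment groups to compare")

  ns <- lengths(sp)
  means <- vapply(sp, mean, numeric(1))
  df <- sum(ns) - length(sp)
  s2 <- sum(vapply(sp, function(x) sum((x - mean(x))^2), numeric(1))) / df

  est <- means[trt] - means[control]
  se <- sqrt(s2 * (1 / ns[trt] + 1 / ns[control]))
  tstat <- est / se

  maxT <- .dunnettMaxT(ns[trt], ns[control], df, nDraws, seed)
  pAdj <- vapply(abs(tstat), function(t0) mean(maxT >= t0), numeric(1))
  pRaw <- 2 * stats::pt(-abs(tstat), df)
  pAdj <- pmax(pAdj, pRaw)  # adjusted p can never undercut the raw p

  data.frame(comparison = paste(trt, "-", control), estimate = unname(est),
             statistic = unname(tstat), df = df, p = unname(pRaw),
             p_adjusted = unname(pAdj), significant = unname(pAdj < alpha),
             row.names = NULL)
}

#' Monte Carlo critical value for the Dunnett statistic
#'
#' The \code{1 - alpha} quantile of \code{max_i |T_i|} used by
#' [dunnettVsControl()]; exposed so calibration studies can reuse one set
#' of draws across many simulated datasets.
#'
#' @param ns Treatment group sizes.
#' @param n0 Control group size.
#' @param df Error degrees of freedom.
#' @param alpha Family-wise level.
#' @param nDraws,seed Monte Carlo draws and seed.
#' @return The critical value (single number).
#' @export
dunnettCritical <- function(ns, n0, df, alpha = 0.05, nDraws = 50000, seed = 1) {
  stats::quantile(.dunnettMaxT(ns, n0, df, nDraws, seed), 1 - alpha,
                  names = FALSE)
}

#' Tukey-Kramer all-pairs comparisons
#'
#' Studentized-range adjusted p-values for all pairwise group differences,
#' with Kramer's harmonic correction for unbalanced group sizes.
#'
#' @param values Numeric measurements.
#' @param groups Group label per value (>= 2 groups, >= 2 replicates each).
#' @param alpha Family-wise level for the significance flag.
#' @return \code{data.frame}, one row per pair: \code{comparison},
#'   \code{estimate}, \code{statistic} (q), \code{df}, \code{p}
#'   (unadjusted pooled-t), \code{p_adjusted}, \code{significant}.
#' @export
tukeyKramer <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  sp <- split(values, groups)
  if (length(sp) < 2L) stop("at least 2 groups are required")
  if (any(lengths(sp) < 2L)) stop("at least 2 replicates per group")

  ns <- lengths(sp)
  means <- vapply(sp, mean, numeric(1))
  k <- length(sp)
  df <- sum(ns) - k
  s2 <- sum(vapply(sp, function(x) sum((x - mean(x))^2), numeric(1))) / df

  pairs <- utils::combn(names(sp), 2)
  out <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    est <- means[i] - means[j]
    seQ <- sqrt(s2 / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- abs(est) / seQ
    seT <- sqrt(s2 * (1 / ns[i] + 1 / ns[j]))
    data.frame(comparison = paste(i, "-", j), estimate = unname(est),
               statistic = unname(q), df = df,
               p = 2 * stats::pt(-abs(est) / seT, df),
               p_adjusted = stats::ptukey(q, nmeans = k, df = df,
                                          lower.tail = FALSE))
  })
  out <- do.call(rbind, out)
  out$p_adjusted <- pmax(out$p_adjusted, out$p)
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  out
}

#' Fold-change direction
#'
#' Ratio above 1 is "up", below 1 is "down"; exactly 1 is "unchanged"
#' (the boundary the up/down dichotomy leaves open).
#'
#' @param groupMean Mean in the group of interest.
#' @param otherMean Reference mean, > 0.
#' @return Character vector in \{"up", "down", "unchanged"\}.
#' @export
foldChangeClassify <- function(groupMean, otherMean) {
  if (any(otherMean <= 0)) stop("non-positive denominator")
  fc <- groupMean / otherMean
  ifelse(fc > 1, "up", ifelse(fc < 1, "down", "unchanged"))
}

#' Peptide-evidence filter for protein quantitation
#'
#' Keeps proteins supported by at least 2 unique peptides at a false
#' discovery rate strictly below 1\%.
#'
#' @param records \code{data.frame} with columns \code{unique_peptides}
#'   and \code{fdr} (fraction).
#' @return The retained rows.
#' @export
proteinEvidenceFilter <- function(records) {
  need <- c("unique_peptides", "fdr")
  if (!all(need %in% colnames(records))) {
    stop("records need columns: ", paste(need, collapse = ", "))
  }
  records[records$unique_peptides >= 2 & records$fdr < 0.01, , drop = FALSE]
}

#' Variant density per kilobase
#'
#' Number of non-synonymous coding SNPs normalized to transcript length.
#' Because a percentage convention (density x 100) also circulates, both
#' are returned.
#'
#' @param nSnps Variant count (>= 0).
#' @param lengthKb Transcript length in kb (> 0).
#' @return \code{data.frame} with \code{per_kb} and \code{percent}.
#' @export
snpDensity <- function(nSnps, lengthKb) {
  if (any(lengthKb <= 0)) stop("non-positive transcript length")
  if (any(nSnps < 0)) stop("negative count")
  perKb <- nSnps / lengthKb
  data.frame(per_kb = perKb, percent = perKb * 100)
}

#' Coefficient of variation
#'
#' Population standard deviation over the mean (descriptive convention
#' used for RT and batch-variability summaries).
#'
#' @param x Numeric vector, n >= 2.
#' @return CV as a fraction.
#' @export
coefficientOfVariation <- function(x) {
  if (length(x) < 2L) stop("at least 2 values are required")
  mu <- mean(x)
  if (mu <= 0) stop("mean must be positive")
  popSd(x) / mu
}

#' Principal component analysis by SVD
#'
#' Column-centered singular value decomposition of a samples-by-variables
#' matrix. Missing entries are imputed by variable means before
#' decomposition ("SVD with imputation"); an iterative low-rank
#' refinement of the imputed values is available behind
#' \code{impute = "iterative"}.
#'
#' @param x Numeric matrix, samples in rows (>= 2 complete samples).
#' @param center Center columns (default TRUE).
#' @param impute Missing-value strategy: variable-mean fill, or mean fill
#'   refined by iterating a rank-\code{rank} SVD reconstruction.
#' @param rank Rank of the iterative reconstruction.
#' @return List with \code{scores} (samples x components),
#'   \code{loadings} (variables x components), \code{varianceExplained}
#'   (fractions summing to 1) and \code{d} (singular values).
#' @export
pcaSvd <- function(x, center = TRUE, impute = c("mean", "iterative"),
                   rank = 2) {
  impute <- match.arg(impute)
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("at least 2 samples are required")
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2]]
    if (impute == "iterative") {
      for (it in seq_len(100)) {
        ctr <- colMeans(x)
        sv <- svd(sweep(x, 2, ctr))
        r <- min(rank, length(sv$d))
        rec <- sv$u[, seq_len(r), drop = FALSE] %*%
          (sv$d[seq_len(r)] * t(sv$v[, seq_len(r), drop = FALSE]))
        rec <- sweep(rec, 2, ctr, "+")
        new <- rec[idx]
        if (max(abs(new - x[idx])) < 1e-8) break
        x[idx] <- new
      }
    }
  }
  if (center) x <- sweep(x, 2, colMeans(x))
  sv <- svd(x)
  d2 <- sv$d^2
  list(scores = sv$u %*% diag(sv$d, nrow = length(sv$d)),
       loadings = sv$v,
       varianceExplained = if (sum(d2) > 0) d2 / sum(d2) else d2,
       d = sv$d)
}

#' Complete-linkage Euclidean clustering
#'
#' Agglomerative hierarchical clustering of the rows of a matrix using
#' Euclidean distance and complete linkage; deterministic given the input
#' order.
#'
#' @param x Numeric matrix with >= 2 rows.
#' @return An \code{hclust} tree (merge heights are non-decreasing).
#' @export
hclustCompleteEuclidean <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("at least 2 rows are required")
  stats::hclust(stats::dist(x, method = "euclidean"), method = "complete")
}

#' Serum-batch stability tests
#'
#' For each pair of serum batches, a paired t-test across lipids (pairing
#' each lipid's concentration in one batch with the same lipid in the
#' other, on the log scale) asks whether the batches differ systematically;
#' p-values are BH-adjusted over the batch pairs. Large per-lipid
#' batch-to-batch scatter with no systematic shift leaves all comparisons
#' non-significant.
#'
#' @param mat Lipids-by-batches matrix of positive concentrations.
#' @param alpha FDR level for the significance flag.
#' @param logScale Test log concentrations (default TRUE).
#' @return \code{data.frame}, one row per batch pair, with \code{p},
#'   \code{p_adjusted} and \code{significant}.
#' @export
serumBatchPairedTests <- function(mat, alpha = 0.05, logScale = TRUE) {
  if (ncol(mat) < 2L) stop("at least 2 batches are required")
  if (logScale) {
    if (any(mat <= 0)) stop("concentrations must be positive on the log scale")
    mat <- log(mat)
  }
  pairs <- utils::combn(colnames(mat) %||% seq_len(ncol(mat)), 2)
  res <- apply(pairs, 2, function(pr) {
    tt <- twoSampleTTest(mat[, pr[1]], mat[, pr[2]], paired = TRUE)
    data.frame(comparison = paste(pr[1], "-", pr[2]),
               statistic = tt$statistic, p = tt$p)
  })
  res <- do.call(rbind, res)
  res$p_adjusted <- bhAdjust(res$p)
  res$significant <- res$p_adjusted < alpha
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
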