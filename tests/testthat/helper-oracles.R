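# Independent oracles used to cross-check the package implementations.
# These are deliberately naive (explicit loops, textbook formulas) and share
# no code with the functions they verify.

# Brute-force all-pairs ppm annotation: for one feature, scan every
# (record, adduct) pair, keep those within tol, pick smallest |ppm| with
# lexicographic lipid-id tie-break.
oracleBestMatch <- function(mz, db, adducts, tol) {
  best <- NULL
  for (r in seq_len(nrow(db))) {
    for (a in seq_len(nrow(adducts))) {
      theo <- (db$monoisotopic_mass[r] + adducts$massShift[a]) /
        abs(adducts$charge[a])
      ppm <- 1e6 * (mz - theo) / theo
      if (abs(ppm) <= tol) {
        cand <- list(lipid_id = db$id[r], adduct = adducts$name[a], ppm = ppm)
        if (is.null(best) ||
            abs(ppm) < abs(best$ppm) - 1e-300 ||
            (abs(ppm) == abs(best$ppm) && cand$lipid_id < best$lipid_id)) {
          best <- cand
        }
      }
    }
  }
  best
}

# Textbook Welch statistic and two-sided p.
oracleWelch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t0 <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = t0, p = 2 * pt(-abs(t0), df))
}

# Same brute-force all-pairs scan, written as one big outer ppm matrix so
# larger randomized instances stay fast; still independent of the package's
# per-feature implementation.
oracleMatchAll <- function(mz, db, adducts, tol) {
  theo <- numeric(0); ids <- character(0)
  for (a in seq_len(nrow(adducts))) {
    theo <- c(theo, (db$monoisotopic_mass + adducts$massShift[a]) /
                abs(adducts$charge[a]))
    ids <- c(ids, db$id)
  }
  ppm <- outer(mz, theo, function(f, t) 1e6 * (f - t) / t)
  lapply(seq_along(mz), function(i) {
    hit <- which(abs(ppm[i, ]) <= tol)
    if (!length(hit)) return(NULL)
    best <- hit[order(abs(ppm[i, hit]), ids[hit])][1]
    list(lipid_id = ids[best], ppm = ppm[i, best], n = length(hit))
  })
}

# Random feature/database instance for oracle-equivalence checks.
randomMatchInstance <- function(nFeat, nDb, seed) {
  set.seed(seed)
  masses <- sort(runif(nDb, 100, 1200))
  db <- lipidDb(id = sprintf("R%04d", sample.int(9999, nDb)),
                name = paste0("lip", seq_len(nDb)),
                category = sample(lipidCategories(), nDb, replace = TRUE),
                monoisotopic_mass = masses)
  # features scattered near and far from true m/z values
  base <- sample(masses, nFeat, replace = TRUE) + 1.007276
  mz <- base * (1 + runif(nFeat, -120, 120) * 1e-6)
  features <- data.frame(sample_id = "s1", mz = mz,
                         intensity = rlnorm(nFeat, 3, 1),
                         polarity = "positive")
  list(features = features, db = db)
}
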