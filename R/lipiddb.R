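# Lipid reference-database model and adduct m/z arithmetic.

#' The eight LIPID MAPS top-level categories
#'
#' @return Character vector of the eight category names every database
#'   record must belong to.
#' @export
lipidCategories <- function() {
  c("fatty acids", "glycerolipids", "glycerophospholipids", "sphingolipids",
    "sterols", "prenols", "saccharolipids", "polyketides")
}

# Proton mass (Da) used for charge carriers in m/z arithmetic.
PROTON_MASS <- 1.007276

# Monoisotopic masses of the elements the formula parser supports. The
# lipid classes in scope are covered by CHNOPS; other elements are rejected.
.ELEMENT_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163,
  S = 31.97207100
)

#' Monoisotopic mass from an elemental formula
#'
#' Parses formulas over C, H, N, O, P and S (e.g. \code{"C34H67NO3"} for
#' Cer(d18:1/16:0)) and sums standard monoisotopic element masses.
#'
#' @param formula Character vector of elemental formulas.
#' @return Numeric vector of monoisotopic masses in Da.
#' @examples
#' formulaMass("C34H67NO3")  # neutral C16 ceramide
#' @export
formulaMass <- function(formula) {
  vapply(as.character(formula), function(f) {
    if (is.na(f) || !nzchar(f)) stop("empty or missing formula")
    toks <- regmatches(f, gregexpr("[A-Z][a-z]?[0-9]*", f))[[1]]
    if (!length(toks) || sum(nchar(toks)) != nchar(f)) {
      stop(sprintf("unparsable formula '%s'", f))
    }
    total <- 0
    for (tok in toks) {
      el <- sub("[0-9]*$", "", tok)
      cnt <- sub("^[A-Za-z]+", "", tok)
      n <- if (nzchar(cnt)) as.numeric(cnt) else 1
      if (!el %in% names(.ELEMENT_MASS)) {
        stop(sprintf("unsupported element '%s' in formula '%s'", el, f))
      }
      total <- total + .ELEMENT_MASS[[el]] * n
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

#' Adduct specification
#'
#' Describes how a neutral lipid is ionized: a signed mass shift in Da and
#' an integer charge whose sign must match the polarity.
#'
#' @param name Adduct label, e.g. \code{"protonated"}.
#' @param massShift Signed mass shift in Da added to the neutral mass.
#' @param charge Non-zero integer charge.
#' @param polarity \code{"positive"} or \code{"negative"}.
#' @return One-row \code{data.frame} with the four fields.
#' @examples
#' adductSpec("protonated", 1.007276, 1L, "positive")
#' @export
adductSpec <- function(name, massShift, charge, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  charge <- as.integer(charge)
  if (charge == 0L) stop("adduct charge must be non-zero")
  if ((polarity == "positive") != (charge > 0L)) {
    stop("charge sign inconsistent with polarity")
  }
  data.frame(name = name, massShift = massShift, charge = charge,
             polarity = polarity, stringsAsFactors = FALSE)
}

#' Default adduct list
#'
#' The adduct set searched per polarity is configurable rather than fixed;
#' defaults are the protonated and ammoniated forms in positive mode (the
#' ammonium-acetate extraction additive promotes ammoniated ions) and the
#' deprotonated form in negative mode.
#'
#' @param polarity Restrict to one polarity, or \code{"both"} (default).
#' @return \code{data.frame} of adduct rows as built by [adductSpec()].
#' @export
defaultAdducts <- function(polarity = c("both", "positive", "negative")) {
  polarity <- match.arg(polarity)
  adds <- rbind(
    adductSpec("protonated", PROTON_MASS, 1L, "positive"),
    adductSpec("ammoniated", 18.033823, 1L, "positive"),
    adductSpec("deprotonated", -PROTON_MASS, -1L, "negative")
  )
  if (polarity != "both") adds <- adds[adds$polarity == polarity, , drop = FALSE]
  adds
}

#' Theoretical m/z of a lipid under an adduct
#'
#' \code{(monoisotopic mass + mass shift) / |charge|}. The first argument
#' may be a numeric vector of neutral masses or a lipid database (a
#' \code{DataFrame} with a \code{monoisotopic_mass} column).
#'
#' @param mass Neutral monoisotopic mass(es) in Da, or a lipid database.
#' @param adduct Optional one-row adduct as built by [adductSpec()];
#'   overrides \code{massShift}/\code{charge} when supplied.
#' @param massShift Signed mass shift in Da (default 0).
#' @param charge Integer charge (default +1); its absolute value divides.
#' @return Numeric vector of m/z values.
#' @examples
#' theoreticalMz(500)                               # identity adduct
#' theoreticalMz(formulaMass("C34H67NO3"),
#'               adductSpec("protonated", 1.007276, 1L, "positive"))
#' @export
theoreticalMz <- function(mass, adduct = NULL, massShift = 0, charge = 1L) {
  if (is(mass, "DataFrame") || is.data.frame(mass)) {
    mass <- mass$monoisotopic_mass
  }
  if (!is.null(adduct)) {
    massShift <- adduct$massShift
    charge <- adduct$charge
  }
  if (any(charge == 0L)) stop("zero charge")
  if (any(!is.finite(mass) | mass <= 0)) stop("masses must be positive")
  (mass + massShift) / abs(charge)
}

# Validate a candidate lipid database; returns the (possibly repaired)
# DataFrame or stops with row-numbered errors. When both formula and mass
# are present and disagree by >1 ppm the explicit mass wins with a warning.
.validateLipidDb <- function(db) {
  required <- c("id", "name", "category")
  missing <- setdiff(required, colnames(db))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (!"monoisotopic_mass" %in% colnames(db)) db$monoisotopic_mass <- NA_real_
  if (!"formula" %in% colnames(db)) db$formula <- NA_character_
  if (!"fragments" %in% colnames(db)) db$fragments <- NA_character_
  db$monoisotopic_mass <- suppressWarnings(as.numeric(db$monoisotopic_mass))

  errs <- character()
  n <- nrow(db)
  for (i in seq_len(n)) {
    hasMass <- is.finite(db$monoisotopic_mass[i])
    hasFormula <- !is.na(db$formula[i]) && nzchar(db$formula[i])
    if (!hasMass && !hasFormula) {
      errs <- c(errs, sprintf("row %d (%s): neither mass nor formula", i, db$id[i]))
      next
    }
    fMass <- if (hasFormula) {
      tryCatch(formulaMass(db$formula[i]), error = function(e) {
        errs <<- c(errs, sprintf("row %d (%s): %s", i, db$id[i], conditionMessage(e)))
        NA_real_
      })
    } else NA_real_
    if (!hasMass) {
      db$monoisotopic_mass[i] <- fMass
    } else if (is.finite(fMass)) {
      if (abs(1e6 * (db$monoisotopic_mass[i] - fMass) / fMass) > 1) {
        warning(sprintf(
          "row %d (%s): formula mass %.6f disagrees with stated mass %.6f by >1 ppm; using stated mass",
          i, db$id[i], fMass, db$monoisotopic_mass[i]))
      }
    }
    if (is.finite(db$monoisotopic_mass[i]) && db$monoisotopic_mass[i] <= 0) {
      errs <- c(errs, sprintf("row %d (%s): monoisotopic mass must be > 0", i, db$id[i]))
    }
    if (!db$category[i] %in% lipidCategories()) {
      errs <- c(errs, sprintf("row %d (%s): unknown category '%s'", i, db$id[i], db$category[i]))
    }
  }
  dup <- db$id[duplicated(db$id)]
  if (length(dup)) {
    errs <- c(errs, paste("duplicate id(s):", paste(unique(dup), collapse = ", ")))
  }
  if (length(errs)) stop("invalid lipid database:\n  ", paste(errs, collapse = "\n  "))
  db
}

#' Build a lipid reference database
#'
#' @param id Unique record ids.
#' @param name Lipid names.
#' @param category One of the eight categories in [lipidCategories()].
#' @param formula Optional elemental formulas (CHNOPS); used to fill in a
#'   missing \code{monoisotopic_mass}.
#' @param monoisotopic_mass Optional neutral monoisotopic masses (Da > 0).
#' @param fragments Optional diagnostic fragment m/z, semicolon-separated.
#' @return \code{DataFrame} with one validated record per row.
#' @examples
#' lipidDb(id = "LR1", name = "Cer(d18:1/16:0)", category = "sphingolipids",
#'         formula = "C34H67NO3")
#' @export
lipidDb <- function(id, name, category, formula = NA_character_,
                    monoisotopic_mass = NA_real_, fragments = NA_character_) {
  n <- length(id)
  db <- S4Vectors::DataFrame(
    id = as.character(id),
    name = rep_len(as.character(name), n),
    category = rep_len(as.character(category), n),
    formula = rep_len(as.character(formula), n),
    monoisotopic_mass = rep_len(as.numeric(monoisotopic_mass), n),
    fragments = rep_len(as.character(fragments), n)
  )
  .validateLipidDb(db)
}

#' Read a lipid database from TSV or JSON
#'
#' TSV dialect: tab-delimited with header; columns \code{id}, \code{name},
#' \code{category}, and \code{formula} and/or \code{monoisotopic_mass};
#' optional \code{fragments} as semicolon-separated m/z. A JSON array of
#' objects with the same fields is accepted for \code{.json} paths.
#'
#' @param path Path to the file.
#' @return Validated \code{DataFrame} of records (possibly zero rows).
#' @seealso [writeLipidDb()]
#' @examples
#' readLipidDb(system.file("extdata", "example_lipid_db.tsv",
#'                         package = "LipidRheostat"))
#' @export
readLipidDb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path)
    db <- S4Vectors::DataFrame(as.data.frame(raw, stringsAsFactors = FALSE))
  } else {
    raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                             colClasses = "character")
    db <- S4Vectors::DataFrame(raw)
  }
  if (nrow(db) == 0L) {
    return(lipidDb(id = character(), name = character(), category = character()))
  }
  .validateLipidDb(db)
}

#' Write a lipid database as TSV
#'
#' Round-trips with [readLipidDb()]: every field is preserved.
#'
#' @param db Database from [lipidDb()] / [readLipidDb()] / [makeToyDb()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeLipidDb <- function(db, path) {
  out <- as.data.frame(db)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

# Parse a semicolon-separated fragment field into numeric m/z (possibly empty).
.parseFragments <- function(x) {
  if (is.na(x) || !nzchar(x)) return(numeric())
  as.numeric(strsplit(x, ";", fixed = TRUE)[[1]])
}
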