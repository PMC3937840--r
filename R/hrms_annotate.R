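# Monoisotopic atomic masses (Da), IUPAC/CODATA values.
MONOISOTOPIC_MASS <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Na = 22.9897692809,
  K  = 38.96370668,
  Cl = 34.96885268
)

# mass change of each supported adduct, applied to the neutral molecule
ADDUCT_DELTA <- list(
  "none" = 0,
  "+H" = unname(MONOISOTOPIC_MASS["H"]),
  "-H" = -unname(MONOISOTOPIC_MASS["H"]),
  "+K" = unname(MONOISOTOPIC_MASS["K"]),
  "+Na" = unname(MONOISOTOPIC_MASS["Na"])
)

#' Parse an elemental formula in Hill notation
#'
#' @param formula character string such as `"C6H12O6"`.
#' @return named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula)) return(formula)
  stopifnot(is.character(formula), length(formula) == 1L)
  f <- trimws(formula)
  if (!nzchar(f)) return(stats::setNames(integer(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
  toks <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
  if (sum(nchar(toks)) != nchar(f))
    stop("cannot parse formula: ", formula)
  el <- sub("[0-9]*$", "", toks)
  ct <- as.integer(ifelse(grepl("[0-9]+$", toks), sub("^[A-Za-z]+", "", toks), "1"))
  counts <- tapply(ct, el, sum)
  stats::setNames(as.integer(counts), names(counts))
}

#' Monoisotopic mass of an elemental formula
#'
#' @param formula Hill-notation string or named count vector; an empty
#'   formula has mass 0.
#' @return monoisotopic mass (Da).
#' @examples
#' formula_mass("H2O")     # 18.010565
#' formula_mass("C6H12O6") # 180.063388
#' @export
formula_mass <- function(formula) {
  counts <- parse_formula(formula)
  if (length(counts) == 0L) return(0)
  unknown <- setdiff(names(counts), names(MONOISOTOPIC_MASS))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  sum(counts * MONOISOTOPIC_MASS[names(counts)])
}

#' Theoretical m/z of a singly charged ion species
#'
#' The neutral monoisotopic mass adjusted by the adduct (`-H` subtracts one
#' hydrogen, `+K` adds one potassium, ...). The electron mass is
#' deliberately NOT included: for the sparse fragment annotation this
#' package performs, the hydrogen-transfer convention (m/z = M +/- H etc.)
#' is the one under which observed ion-trap and Orbitrap fragment lists
#' match theory most tightly, and it keeps the +H/-H adducts exactly
#' symmetric about the neutral mass.
#'
#' @param formula neutral elemental formula (string or counts).
#' @param adduct one of `"none"`, `"+H"`, `"-H"`, `"+K"`, `"+Na"`.
#' @param nominal when `TRUE`, round the result to the nearest integer
#'   (nominal-mass arithmetic for low-resolution data, e.g. 828 + K -> 867).
#' @return theoretical m/z (Th).
#' @examples
#' ion_mz("C6H12O6", "-H")  # deprotonated glucose
#' @export
ion_mz <- function(formula, adduct = "none", nominal = FALSE) {
  if (!adduct %in% names(ADDUCT_DELTA))
    stop("unsupported adduct: ", adduct)
  m <- formula_mass(formula) + ADDUCT_DELTA[[adduct]]
  if (nominal) round(m) else m
}

#' Signed mass error in parts per million
#'
#' @param theoretical theoretical m/z (> 0).
#' @param observed observed m/z.
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppm_error <- function(theoretical, observed) {
  stopifnot(all(theoretical > 0))
  1e6 * (observed - theoretical) / theoretical
}

#' Annotate observed fragments against candidate ion species
#'
#' Every observed peak is compared with every candidate; matches within
#' `tol_ppm` (absolute ppm error) are reported sorted by |ppm error|.
#'
#' @param spectrum centroid peak matrix.
#' @param candidates data.frame with columns `label`, `formula` (neutral,
#'   Hill notation), `adduct`.
#' @param tol_ppm match tolerance in ppm (e.g. 8).
#' @return data.frame `observed_mz`, `intensity`, `label`, `formula`,
#'   `adduct`, `theoretical_mz`, `ppm_error` (zero rows when nothing
#'   matches).
#' @export
annotate_fragments <- function(spectrum, candidates, tol_ppm) {
  p <- as_peaks(spectrum)
  stopifnot(all(c("label", "formula", "adduct") %in% names(candidates)))
  theo <- vapply(seq_len(nrow(candidates)), function(i)
    ion_mz(candidates$formula[i], candidates$adduct[i]), numeric(1))
  out <- list()
  for (i in seq_len(nrow(p))) {
    err <- ppm_error(theo, p[i, "mz"])
    hit <- which(abs(err) <= tol_ppm)
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(
        observed_mz = unname(p[i, "mz"]), intensity = unname(p[i, "intensity"]),
        label = candidates$label[hit], formula = candidates$formula[hit],
        adduct = candidates$adduct[hit], theoretical_mz = theo[hit],
        ppm_error = err[hit])
  }
  if (length(out) == 0L)
    return(data.frame(observed_mz = numeric(0), intensity = numeric(0),
                      label = character(0), formula = character(0),
                      adduct = character(0), theoretical_mz = numeric(0),
                      ppm_error = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[order(abs(res$ppm_error)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Detect neutral-loss series in a fragment spectrum
#'
#' Starting from the precursor, follows maximal chains of peaks separated
#' by the given loss (e.g. 162, hexose - H2O) within the tolerance:
#' `p0 > p1 > ...` with `p_i - p_(i+1)` within `tol` of `loss`.
#'
#' @param peaks peak matrix (fragments).
#' @param precursor_mz anchor m/z of the series.
#' @param loss neutral loss (Da, > 0).
#' @param tol step tolerance.
#' @return list of numeric chains (each starting at `precursor_mz`);
#'   empty list when no fragment sits one loss below the precursor.
#' @export
neutral_loss_series <- function(peaks, precursor_mz, loss, tol) {
  stopifnot(loss > 0)
  p <- as_peaks(peaks)
  mz <- p[, "mz"]
  extend <- function(chain) {
    target <- chain[length(chain)] - loss
    nxt <- mz[abs(mz - target) <= half_window(tol, pmin(mz, target))]
    if (length(nxt) == 0L) return(list(chain))
    unlist(lapply(nxt, function(x) extend(c(chain, x))), recursive = FALSE)
  }
  chains <- extend(precursor_mz)
  chains[vapply(chains, length, integer(1)) > 1L]
}

#' Candidate fragment ions of PI(16:0,18:3)
#'
#' The five diagnostic fragment compositions of deprotonated
#' phosphatidylinositol PI(16:0,18:3): the two acyl carboxylate anions,
#' the dehydrated inositol-phosphate and glycerophosphate ions, and the
#' ion after loss of the sn2 fatty acid and inositol. Compositions are
#' this package's own derivation from the standard glycerophospholipid
#' fragmentation nomenclature (a synthetic reference list, not a vendor
#' database export), shipped for the worked high-resolution annotation
#' example.
#'
#' @return data.frame with `label`, `formula` (neutral), `adduct`.
#' @export
pi_16_0_18_3_fragments <- function() {
  data.frame(
    label = c("sn1 RCOO- (16:0)",
              "sn2 RCOO- (18:3)",
              "inositol phosphate - H2O",
              "glycerol-3-phosphate - H2O",
              "[M-H - sn2 RCOOH - inositol]"),
    formula = c("C16H32O2", "C18H30O2", "C6H11O8P", "C3H7O5P", "C19H37O6P"),
    adduct = rep("-H", 5L))
}
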