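#' Peak lists
#'
#' Peaks are stored as a two-column numeric matrix (`mz`, `intensity`),
#' sorted ascending by m/z, the same layout `mzR::peaks()` returns. All
#' m/z values are in Th and must be positive; intensities are arbitrary
#' units and must be non-negative.
#'
#' @param mz numeric vector of m/z values (Th).
#' @param intensity numeric vector of intensities, same length.
#' @return peak matrix sorted by m/z.
#' @examples
#' new_peaks(c(341.1, 179.05), c(100, 40))
#' @export
new_peaks <- function(mz = numeric(0), intensity = numeric(0)) {
  stopifnot(length(mz) == length(intensity))
  if (any(!is.finite(mz)) || any(!is.finite(intensity)))
    stop("non-finite m/z or intensity")
  if (any(mz <= 0)) stop("m/z values must be > 0")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  o <- order(mz)
  cbind(mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]))
}

as_peaks <- function(x) {
  if (is.matrix(x) && ncol(x) == 2L) return(new_peaks(x[, 1L], x[, 2L]))
  if (is.data.frame(x) && all(c("mz", "intensity") %in% names(x)))
    return(new_peaks(x$mz, x$intensity))
  if (inherits(x, "norm_spectrum")) return(x$peaks)
  stop("cannot interpret input as a peak list (need mz/intensity columns)")
}

#' Select the n most intense peaks
#'
#' Intensity ties are broken in favour of the lower m/z. The result is
#' re-sorted ascending by m/z. Fewer than `n` peaks are returned unchanged.
#'
#' @param peaks peak matrix (or data.frame with mz/intensity).
#' @param n number of peaks to keep (>= 1).
#' @return peak matrix with at most `n` rows.
#' @export
select_top_n <- function(peaks, n) {
  stopifnot(n >= 1)
  p <- as_peaks(peaks)
  if (nrow(p) == 0L) return(p)
  o <- order(-p[, "intensity"], p[, "mz"])
  keep <- sort(o[seq_len(min(n, nrow(p)))])
  p[keep, , drop = FALSE]
}

#' Normalize a spectrum for comparison
#'
#' Keeps the `top_n` most intense peaks and scales their intensities either
#' by the base peak (most intense ion, giving a maximum of exactly 1) or by
#' the sum over the selected ions (intensities then sum to 1). The result is
#' the standard input to [distms2()].
#'
#' @param peaks peak matrix.
#' @param mode `"sum"` or `"base_peak"`.
#' @param top_n number of most intense ions to keep (default 5).
#' @param source_chain optional precursor chain of origin, recorded as-is.
#' @return object of class `norm_spectrum` with elements `peaks`,
#'   `norm_mode`, `top_n`, `source_chain`.
#' @export
normalize_spectrum <- function(peaks, mode = c("sum", "base_peak"), top_n = 5,
                               source_chain = NULL) {
  mode <- match.arg(mode)
  p <- as_peaks(peaks)
  if (nrow(p) == 0L || all(p[, "intensity"] == 0))
    stop("degenerate spectrum: no peak with positive intensity")
  p <- select_top_n(p, top_n)
  denom <- switch(mode,
    base_peak = max(p[, "intensity"]),
    sum = sum(p[, "intensity"]))
  p[, "intensity"] <- p[, "intensity"] / denom
  structure(list(peaks = p, norm_mode = mode, top_n = top_n,
                 source_chain = source_chain),
            class = "norm_spectrum")
}

#' @export
print.norm_spectrum <- function(x, ...) {
  cat(sprintf("<norm_spectrum> %d peaks, %s-normalized (top_n = %d)\n",
              nrow(x$peaks), x$norm_mode, x$top_n))
  invisible(x)
}

#' Merge peaks within a mass tolerance
#'
#' Greedy single-linkage binning on the m/z-sorted list: consecutive peaks
#' whose gap does not exceed the half-window (evaluated at the lower m/z of
#' the pair) join one bin. Each bin emits a single peak at the median of the
#' member m/z values with intensity aggregated by the maximum or the 95%
#' quantile (linear-interpolation definition). Used both for consensus
#' spectra over many scans and for centroiding profile data.
#'
#' The operation is idempotent: output peaks are pairwise separated by more
#' than the half-window, so re-merging changes nothing.
#'
#' @param peaks peak matrix, possibly concatenated from many scans.
#' @param tol tolerance ([tol_da()]/[tol_ppm()]).
#' @param agg intensity aggregation within a bin: `"max"` or `"q95"`.
#' @return merged peak matrix.
#' @export
merge_peaks <- function(peaks, tol, agg = c("max", "q95")) {
  agg <- match.arg(agg)
  p <- as_peaks(peaks)
  if (nrow(p) <= 1L) return(p)
  tol <- as_mz_tol(tol)
  mz <- p[, "mz"]
  gaps <- diff(mz)
  hw <- half_window(tol, mz[-length(mz)])  # lower mz of each consecutive pair
  bin <- cumsum(c(1, as.integer(gaps > hw)))
  afun <- if (agg == "max") max else function(x) unname(stats::quantile(x, 0.95, type = 7))
  mzs <- vapply(split(mz, bin), stats::median, numeric(1))
  ints <- vapply(split(p[, "intensity"], bin), afun, numeric(1))
  new_peaks(mzs, ints)
}

#' Centroid a profile-mode scan
#'
#' Drops zero-intensity profile points and reduces the point cloud with
#' [merge_peaks()] so that each ion species is represented by one centroid
#' peak. Errors on a scan that is already centroided.
#'
#' @param scan an [msn_scan()] with `peak_mode = "profile"`.
#' @param tol tolerance (e.g. `tol_ppm(20)` for Orbitrap MS2 data).
#' @param agg intensity aggregation, `"max"` (default) or `"q95"`.
#' @return a centroid-mode copy of the scan.
#' @export
centroid_profile <- function(scan, tol, agg = c("max", "q95")) {
  agg <- match.arg(agg)
  stopifnot(inherits(scan, "msn_scan"))
  if (!identical(scan$peak_mode, "profile"))
    stop("scan is not profile mode: nothing to centroid")
  p <- scan$peaks
  p <- p[p[, "intensity"] > 0, , drop = FALSE]
  scan$peaks <- merge_peaks(p, tol, agg)
  scan$peak_mode <- "centroid"
  scan
}
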