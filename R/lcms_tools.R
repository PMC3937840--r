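#' Extracted ion chromatogram (XIC)
#'
#' For each MS^1 scan the intensity at the target m/z is the sum of peak
#' intensities within `mz` +/- the half-window (0 when no peak falls in
#' the window). Points are ordered by retention time.
#'
#' @param scans list of MS^1 centroid [msn_scan()] objects with RT.
#' @param mz target m/z (Th).
#' @param tol window tolerance.
#' @return object of class `xic`: `mz_center`, `tol`, `rt`, `intensity`.
#' @export
extract_xic <- function(scans, mz, tol) {
  stopifnot(length(scans) > 0L)
  for (s in scans) {
    if (s$ms_level != 1L)
      stop(sprintf("scan '%s' is MS%d, not MS1", s$scan_id, s$ms_level))
    if (is.na(s$rt))
      stop(sprintf("scan '%s' has no retention time", s$scan_id))
  }
  rt <- vapply(scans, `[[`, numeric(1), "rt")
  o <- order(rt)
  inten <- vapply(scans[o], function(s) {
    p <- s$peaks
    if (nrow(p) == 0L) return(0)
    sum(p[mz_within(p[, "mz"], mz, tol), "intensity"])
  }, numeric(1))
  structure(list(mz_center = mz, tol = as_mz_tol(tol),
                 rt = rt[o], intensity = inten),
            class = "xic")
}

#' @export
print.xic <- function(x, ...) {
  cat(sprintf("<xic> m/z %g, %d points, RT %.1f-%.1f s\n",
              x$mz_center, length(x$rt), min(x$rt), max(x$rt)))
  invisible(x)
}

#' Detect chromatographic peaks in an XIC
#'
#' Moving-average smoothing of the stated width followed by local-maximum
#' picking: smoothed points strictly greater than both neighbours and at
#' least `min_height` high become apexes; each peak's bounds extend to the
#' nearest valley (local minimum of the smoothed trace) or trace end.
#' Peaks are returned in RT order.
#'
#' @param xic an [extract_xic()] result.
#' @param min_height minimum apex intensity.
#' @param smooth_width moving-average window in points (odd; default 5).
#' @return data.frame with `apex_rt`, `rt_lo`, `rt_hi`, `height`
#'   (possibly zero rows).
#' @export
detect_peaks <- function(xic, min_height = 0, smooth_width = 5) {
  stopifnot(inherits(xic, "xic"), length(xic$rt) > 0L)
  y <- xic$intensity
  n <- length(y)
  w <- max(1L, as.integer(smooth_width))
  if (w %% 2L == 0L) w <- w + 1L
  s <- if (w > 1L && n >= w)
    as.numeric(stats::filter(y, rep(1 / w, w), sides = 2)) else y
  # moving average is NA at the ends; fall back to the raw trace there
  s[is.na(s)] <- y[is.na(s)]
  if (n < 3L) return(empty_chrom_peaks())
  apex <- which(s[2:(n - 1L)] > s[1:(n - 2L)] & s[2:(n - 1L)] >= s[3:n]) + 1L
  apex <- apex[s[apex] >= min_height & s[apex] > 0]
  if (length(apex) == 0L) return(empty_chrom_peaks())
  out <- lapply(apex, function(a) {
    lo <- a
    while (lo > 1L && s[lo - 1L] <= s[lo]) lo <- lo - 1L
    hi <- a
    while (hi < n && s[hi + 1L] <= s[hi]) hi <- hi + 1L
    data.frame(apex_rt = xic$rt[a], rt_lo = xic$rt[lo], rt_hi = xic$rt[hi],
               height = y[a])
  })
  res <- do.call(rbind, out)
  res[order(res$apex_rt), , drop = FALSE]
}

empty_chrom_peaks <- function()
  data.frame(apex_rt = numeric(0), rt_lo = numeric(0), rt_hi = numeric(0),
             height = numeric(0))

#' Retention-time statistics of a set of apexes
#'
#' Summarises apex retention times across samples the way LC peaks are
#' reported: median RT with the `[min, max]` range, plus the relative
#' standard deviation RSD% = 100 * sd / mean (sample standard deviation,
#' n - 1). A single apex yields RSD 0 by convention, flagged by the
#' `single_value` column.
#'
#' @param apex_rts numeric vector of apex retention times (seconds).
#' @return one-row data.frame: `median_rt`, `rt_min`, `rt_max`,
#'   `rsd_percent`, `n`, `single_value`.
#' @export
rt_stats <- function(apex_rts) {
  stopifnot(length(apex_rts) > 0L, all(is.finite(apex_rts)))
  n <- length(apex_rts)
  rsd <- if (n == 1L) 0 else 100 * stats::sd(apex_rts) / mean(apex_rts)
  data.frame(median_rt = stats::median(apex_rts),
             rt_min = min(apex_rts), rt_max = max(apex_rts),
             rsd_percent = rsd, n = n, single_value = n == 1L)
}

#' Assign MS^2 scans to chromatographic peaks
#'
#' Each scan maps to the peak whose `[rt_lo, rt_hi]` window contains its
#' retention time; when windows overlap the peak with the nearest apex
#' wins; scans outside every window stay unassigned (`NA`).
#'
#' @param ms2_scans list of MS^2 [msn_scan()] objects with RT.
#' @param peaks data.frame from [detect_peaks()].
#' @return integer vector (row index into `peaks`, or `NA`), one entry per
#'   scan, named by scan id.
#' @export
assign_ms2_to_peaks <- function(ms2_scans, peaks) {
  out <- vapply(ms2_scans, function(s) {
    if (is.na(s$rt)) stop(sprintf("scan '%s' has no retention time", s$scan_id))
    inside <- which(peaks$rt_lo <= s$rt & s$rt <= peaks$rt_hi)
    if (length(inside) == 0L) return(NA_integer_)
    inside[which.min(abs(peaks$apex_rt[inside] - s$rt))]
  }, integer(1))
  names(out) <- vapply(ms2_scans, `[[`, "", "scan_id")
  out
}

#' Write an XIC or peak table as TSV
#'
#' @param x an `xic` or the data.frame from [detect_peaks()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_xic_tsv <- function(x, path) {
  df <- if (inherits(x, "xic")) data.frame(rt = x$rt, intensity = x$intensity) else x
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
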