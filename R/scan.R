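#' A single MS^n scan
#'
#' One acquired spectrum together with the information the tree builder
#' needs: the ms level, the ordered chain of precursor ions that led to it
#' (MS^1 first; empty for an MS^1 scan), and sample/retention-time metadata.
#' Retention time may be `NA` for direct-infusion data; RT-dependent
#' operations reject such scans explicitly.
#'
#' @param scan_id scan identifier (character).
#' @param sample_id sample identifier (character).
#' @param ms_level integer n >= 1.
#' @param precursor_chain numeric vector of length `ms_level - 1`, MS^1 first.
#' @param peaks peak matrix (see [new_peaks()]).
#' @param rt retention time in seconds, or `NA` for DIMS.
#' @param polarity `"positive"` or `"negative"`.
#' @param peak_mode `"centroid"` or `"profile"`.
#' @param collision_energy relative collision energy (percent), or `NA`.
#' @return object of class `msn_scan`.
#' @examples
#' msn_scan("s1", "A", 3, c(867, 705), new_peaks(c(543, 381), c(150, 50)))
#' @export
msn_scan <- function(scan_id, sample_id, ms_level, precursor_chain = numeric(0),
                     peaks = new_peaks(), rt = NA_real_,
                     polarity = c("positive", "negative"),
                     peak_mode = c("centroid", "profile"),
                     collision_energy = NA_real_) {
  polarity <- match.arg(polarity)
  peak_mode <- match.arg(peak_mode)
  ms_level <- as.integer(ms_level)
  stopifnot(ms_level >= 1L)
  precursor_chain <- as.numeric(precursor_chain)
  if (length(precursor_chain) != ms_level - 1L)
    stop(sprintf("scan '%s': precursor chain has %d entries, expected %d for MS%d",
                 scan_id, length(precursor_chain), ms_level - 1L, ms_level))
  if (length(precursor_chain) && any(precursor_chain <= 0))
    stop("precursor chain m/z values must be > 0")
  p <- as_peaks(peaks)
  if (anyDuplicated(p[, "mz"]))
    stop(sprintf("scan '%s': duplicate m/z values in peak list", scan_id))
  structure(list(scan_id = as.character(scan_id),
                 sample_id = as.character(sample_id),
                 ms_level = ms_level,
                 precursor_chain = precursor_chain,
                 rt = as.numeric(rt),
                 polarity = polarity,
                 peaks = p,
                 peak_mode = peak_mode,
                 collision_energy = as.numeric(collision_energy)),
            class = "msn_scan")
}

#' @export
print.msn_scan <- function(x, ...) {
  chain <- if (length(x$precursor_chain))
    paste(sprintf("%.4f", x$precursor_chain), collapse = " > ") else "-"
  cat(sprintf("<msn_scan %s> MS%d sample=%s chain=[%s] %d peaks rt=%s %s/%s\n",
              x$scan_id, x$ms_level, x$sample_id, chain, nrow(x$peaks),
              ifelse(is.na(x$rt), "NA", sprintf("%.1fs", x$rt)),
              x$polarity, x$peak_mode))
  invisible(x)
}

#' Base-peak intensity of a scan
#'
#' @param scan an [msn_scan()].
#' @return maximum peak intensity, or 0 for an empty peak list.
#' @export
base_peak_intensity <- function(scan) {
  if (nrow(scan$peaks) == 0L) 0 else max(scan$peaks[, "intensity"])
}
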