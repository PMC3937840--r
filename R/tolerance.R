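#' Mass tolerances
#'
#' A tolerance describes the half-window used whenever two m/z values are
#' compared: absolute (Th) for nominal-mass ion-trap data, or relative (ppm)
#' for high-resolution data. The half-window at mass `m` is `value` for an
#' absolute tolerance and `m * value * 1e-6` for a relative one.
#'
#' @param value positive tolerance value (Th for `tol_da`, ppm for `tol_ppm`).
#' @return An object of class `mz_tol`.
#' @examples
#' tol_da(0.5)   # +/- 0.5 Th, nominal-mass default
#' tol_ppm(20)   # +/- 20 ppm, high-resolution default
#' @export
tol_da <- function(value) new_mz_tol(value, "absolute")

#' @rdname tol_da
#' @export
tol_ppm <- function(value) new_mz_tol(value, "relative")

new_mz_tol <- function(value, kind) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  if (value <= 0) stop("tolerance value must be > 0")
  structure(list(value = value, kind = kind), class = "mz_tol")
}

#' @export
print.mz_tol <- function(x, ...) {
  unit <- if (x$kind == "absolute") "Th" else "ppm"
  cat(sprintf("<mz_tol> +/- %g %s\n", x$value, unit))
  invisible(x)
}

as_mz_tol <- function(tol) {
  if (inherits(tol, "mz_tol")) return(tol)
  if (is.numeric(tol) && length(tol) == 1L) return(tol_da(tol))
  stop("`tol` must be an mz_tol object (see tol_da()/tol_ppm()) or a single Th value")
}

#' Half-window of a tolerance at a given mass
#'
#' @param tol an [tol_da()]/[tol_ppm()] tolerance.
#' @param mz m/z value(s) at which to evaluate the window (needed for ppm).
#' @return numeric vector of half-window widths in Th.
#' @export
half_window <- function(tol, mz) {
  tol <- as_mz_tol(tol)
  if (tol$kind == "absolute") rep_len(tol$value, length(mz)) else mz * tol$value * 1e-6
}

#' Do two m/z values agree within a tolerance?
#'
#' The half-window is evaluated at the smaller of the two masses, so the
#' predicate is symmetric.
#'
#' @param mz1,mz2 m/z values (vectorised).
#' @param tol tolerance.
#' @return logical vector.
#' @export
mz_within <- function(mz1, mz2, tol) {
  abs(mz1 - mz2) <= half_window(tol, pmin(mz1, mz2))
}
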