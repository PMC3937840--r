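#' Greedy one-to-one ion matching between two spectra
#'
#' Candidate pairs are all peak pairs whose m/z values agree within the
#' half-window (evaluated at the smaller m/z). Pairs are considered in
#' order of increasing |delta m/z|, ties broken by the higher product of
#' intensities, then by the lower m/z; a pair is accepted when both of its
#' peaks are still unmatched. For the sparse spectra this package targets
#' (a handful of ions) the greedy assignment is near-optimal and
#' deterministic, and is checked against brute-force enumeration in the
#' test suite.
#'
#' @param s1,s2 [normalize_spectrum()] results (or plain peak matrices).
#' @param tol match tolerance.
#' @return object of class `ion_matching`: `matched` (data.frame with
#'   `mz1, i1, mz2, i2`), `unmatched_1`, `unmatched_2` (peak matrices),
#'   `tol`.
#' @export
match_ions <- function(s1, s2, tol) {
  p1 <- as_peaks(s1); p2 <- as_peaks(s2)
  tol <- as_mz_tol(tol)
  n1 <- nrow(p1); n2 <- nrow(p2)
  cand <- NULL
  if (n1 > 0L && n2 > 0L) {
    idx <- expand.grid(i = seq_len(n1), j = seq_len(n2))
    mz1 <- p1[idx$i, "mz"]; mz2 <- p2[idx$j, "mz"]
    ok <- mz_within(mz1, mz2, tol)
    cand <- idx[ok, , drop = FALSE]
  }
  matched <- data.frame(mz1 = numeric(0), i1 = numeric(0),
                        mz2 = numeric(0), i2 = numeric(0))
  used1 <- logical(n1); used2 <- logical(n2)
  if (!is.null(cand) && nrow(cand) > 0L) {
    dmz <- abs(p1[cand$i, "mz"] - p2[cand$j, "mz"])
    prod_int <- p1[cand$i, "intensity"] * p2[cand$j, "intensity"]
    ord <- order(dmz, -prod_int, pmin(p1[cand$i, "mz"], p2[cand$j, "mz"]))
    for (k in ord) {
      i <- cand$i[k]; j <- cand$j[k]
      if (used1[i] || used2[j]) next
      used1[i] <- TRUE; used2[j] <- TRUE
      matched[nrow(matched) + 1L, ] <- c(p1[i, "mz"], p1[i, "intensity"],
                                         p2[j, "mz"], p2[j, "intensity"])
    }
  }
  structure(list(matched = matched,
                 unmatched_1 = p1[!used1, , drop = FALSE],
                 unmatched_2 = p2[!used2, , drop = FALSE],
                 tol = tol),
            class = "ion_matching")
}

#' @export
print.ion_matching <- function(x, ...) {
  cat(sprintf("<ion_matching> %d matched, %d + %d unmatched\n",
              nrow(x$matched), nrow(x$unmatched_1), nrow(x$unmatched_2)))
  invisible(x)
}

#' distMS2: sparse MS^2 spectral distance
#'
#' The distance between two MS^2 spectra is the sum of the Manhattan
#' distance between the matched ions and the normalized intensities of all
#' unmatched ions (summed over both spectra). Each spectrum is first
#' reduced to its `top_n` most intense ions and normalized against either
#' the base peak or the sum of the selected ions. The score satisfies
#' non-negativity, symmetry and the identity d(S, S) = 0, but not the
#' triangle inequality: it is a quasi-metric. Under sum normalization the
#' score is bounded by 2, with equality for spectra sharing no ions.
#'
#' @param s1,s2 peak matrices (raw intensities).
#' @param top_n number of most intense ions compared (default 5).
#' @param norm_mode `"sum"` (default; bounds the score in `[0, 2]`) or
#'   `"base_peak"`.
#' @param tol ion match tolerance (0.5 Th nominal, `tol_ppm(20)` for
#'   high-resolution spectra).
#' @return non-negative distance score.
#' @examples
#' s1 <- new_peaks(c(100, 150), c(1000, 500))
#' s2 <- new_peaks(c(100, 160), c(600, 240))
#' distms2(s1, s2, norm_mode = "base_peak")  # 0.9
#' @export
distms2 <- function(s1, s2, top_n = 5, norm_mode = c("sum", "base_peak"),
                    tol = tol_da(0.5)) {
  norm_mode <- match.arg(norm_mode)
  n1 <- normalize_spectrum(s1, norm_mode, top_n)
  n2 <- normalize_spectrum(s2, norm_mode, top_n)
  m <- match_ions(n1, n2, tol)
  sum(abs(m$matched$i1 - m$matched$i2)) +
    sum(m$unmatched_1[, "intensity"]) + sum(m$unmatched_2[, "intensity"])
}

#' Correlation-based spectral distance (1 - r)
#'
#' The baseline metric distMS2 is compared against: the two spectra are
#' aligned on the union of their ions (matched ions pair up; an ion absent
#' from the other spectrum gets intensity 0 there) and the distance is one
#' minus Pearson's correlation coefficient over the aligned intensity
#' vectors, in `[0, 2]`.
#'
#' @param s1,s2 peak matrices.
#' @param tol ion match tolerance.
#' @param top_n most intense ions kept per spectrum before alignment.
#' @return 1 - r.
#' @export
corr_distance <- function(s1, s2, tol = tol_da(0.5), top_n = 5) {
  p1 <- select_top_n(as_peaks(s1), top_n)
  p2 <- select_top_n(as_peaks(s2), top_n)
  m <- match_ions(p1, p2, tol)
  v1 <- c(m$matched$i1, m$unmatched_1[, "intensity"],
          rep(0, nrow(m$unmatched_2)))
  v2 <- c(m$matched$i2, rep(0, nrow(m$unmatched_1)),
          m$unmatched_2[, "intensity"])
  if (length(v1) < 2L || stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("correlation undefined: constant aligned intensity vector")
  1 - stats::cor(v1, v2)
}

#' Pairwise distance matrix over a list of spectra
#'
#' @param spectra named list of peak matrices.
#' @param metric `"distms2"` or `"corr"`.
#' @param top_n,norm_mode,tol passed to the metric ( `norm_mode` is ignored
#'   for `"corr"`).
#' @return symmetric numeric matrix with zero diagonal, dimnames from
#'   `names(spectra)`.
#' @export
distance_matrix <- function(spectra, metric = c("distms2", "corr"),
                            top_n = 5, norm_mode = c("sum", "base_peak"),
                            tol = tol_da(0.5)) {
  metric <- match.arg(metric)
  norm_mode <- match.arg(norm_mode)
  n <- length(spectra)
  stopifnot(n >= 2L)
  ids <- names(spectra)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  # pre-normalize once per spectrum; the pairwise step reuses the result
  prepped <- if (metric == "distms2")
    lapply(spectra, function(s) normalize_spectrum(s, norm_mode, top_n)$peaks)
  else
    lapply(spectra, function(s) select_top_n(as_peaks(s), top_n))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      val <- tryCatch({
        m <- match_ions(prepped[[i]], prepped[[j]], tol)
        if (metric == "distms2") {
          sum(abs(m$matched$i1 - m$matched$i2)) +
            sum(m$unmatched_1[, "intensity"]) + sum(m$unmatched_2[, "intensity"])
        } else {
          v1 <- c(m$matched$i1, m$unmatched_1[, "intensity"],
                  rep(0, nrow(m$unmatched_2)))
          v2 <- c(m$matched$i2, rep(0, nrow(m$unmatched_1)),
                  m$unmatched_2[, "intensity"])
          if (length(v1) < 2L || stats::sd(v1) == 0 || stats::sd(v2) == 0)
            stop("constant aligned intensity vector")
          1 - stats::cor(v1, v2)
        }
      }, error = function(e)
        stop(sprintf("distance failed for pair (%s, %s): %s",
                     ids[i], ids[j], conditionMessage(e)), call. = FALSE))
      D[i, j] <- D[j, i] <- val
    }
  }
  D
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Classical (Torgerson) scaling: double-centering of the squared-distance
#' matrix and projection on the top-k eigenpairs, with coordinates scaled
#' by the square roots of the eigenvalues. Negative eigenvalues (possible
#' for a quasi-metric such as distMS2) are truncated at zero; when fewer
#' than `k` positive eigenvalues exist the remaining coordinates are
#' zero-padded with a warning.
#'
#' @param d symmetric distance matrix (e.g. from [distance_matrix()]).
#' @param k number of embedding dimensions.
#' @return numeric matrix (items x k) with rownames from `d`.
#' @export
mds_embed <- function(d, k = 2) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), k >= 1, k < nrow(d))
  if (all(d == 0)) {
    out <- matrix(0, nrow(d), k, dimnames = list(rownames(d), NULL))
    return(out)
  }
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE))
  pts <- fit$points
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 1L)
  if (ncol(pts) < k) pts <- cbind(pts, matrix(0, nrow(pts), k - ncol(pts)))
  n_pos <- sum(fit$eig > max(fit$eig) * 1e-12)
  if (k > n_pos) {
    warning(sprintf("only %d positive eigenvalue(s); padding %d dimension(s) with zeros",
                    n_pos, k - n_pos))
    pts[, seq.int(n_pos + 1L, k)] <- 0
  }
  rownames(pts) <- rownames(d)
  pts
}

#' Write a distance matrix or embedding as TSV
#'
#' Distance matrices get an id header row and column; embeddings get
#' columns `id, dim1..dimk`.
#'
#' @param x matrix from [distance_matrix()] or [mds_embed()].
#' @param path output file.
#' @param what `"matrix"` or `"embedding"`.
#' @return `path`, invisibly.
#' @export
write_dist_tsv <- function(x, path, what = c("matrix", "embedding")) {
  what <- match.arg(what)
  if (what == "matrix") {
    df <- data.frame(id = rownames(x), x, check.names = FALSE)
  } else {
    df <- data.frame(id = rownames(x), x)
    names(df) <- c("id", paste0("dim", seq_len(ncol(x))))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
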