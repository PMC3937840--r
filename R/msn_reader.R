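#' Read MS^n scans from mzML, mzXML or a scan table
#'
#' For mzML/mzXML the file is read through mzR. The precursor chain of an
#' MS^n scan is taken from a filter-string attribute when one is present and
#' parses (Thermo style, e.g. `"ms3 867.00@cid35.00 705.00@cid35.00"`);
#' otherwise it is reconstructed by walking the precursor-scan references
#' up to MS^1, collecting each ancestor's precursor m/z. Scans whose ms
#' level is missing, or whose chain cannot be completed, are rejected with
#' a warning.
#'
#' The scantable format is this package's plain-text fixture format: a TSV
#' with one scan per row and columns `scan_id`, `sample_id`, `ms_level`,
#' `precursor_chain` (semicolon-separated, MS^1 first, empty for MS^1),
#' `rt` (seconds, `NA` for DIMS), `polarity`, `peak_mode`,
#' `collision_energy`, `peaks` (space-separated `mz:intensity` pairs).
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"mzml"`, `"mzxml"` or
#'   `"scantable"`.
#' @param sample_id sample identifier to assign; defaults to the file name
#'   without extension (mzML/mzXML only; the scantable carries its own).
#' @return list of [msn_scan()] objects.
#' @export
read_scans <- function(path, format = c("auto", "mzml", "mzxml", "scantable"),
                       sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mzml = "mzml", mzxml = "mzxml", "scantable")
  }
  if (format == "scantable") read_scantable(path) else read_mzr(path, sample_id)
}

#' Write scans to the scantable text format
#'
#' @param scans list of [msn_scan()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scantable <- function(scans, path) {
  fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.10g", x))
  rows <- vapply(scans, function(s) {
    paste(s$scan_id, s$sample_id, s$ms_level,
          paste(fmt_num(s$precursor_chain), collapse = ";"),
          fmt_num(s$rt), s$polarity, s$peak_mode, fmt_num(s$collision_energy),
          paste(sprintf("%.10g:%.10g", s$peaks[, "mz"], s$peaks[, "intensity"]),
                collapse = " "),
          sep = "\t")
  }, character(1))
  header <- paste("scan_id", "sample_id", "ms_level", "precursor_chain", "rt",
                  "polarity", "peak_mode", "collision_energy", "peaks",
                  sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

read_scantable <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character", na.strings = NULL)
  need <- c("scan_id", "sample_id", "ms_level", "precursor_chain", "rt",
            "polarity", "peak_mode", "collision_energy", "peaks")
  if (!all(need %in% names(tab)))
    stop("scantable is missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  parse_num <- function(x) suppressWarnings(as.numeric(x))
  lapply(seq_len(nrow(tab)), function(i) {
    chain <- if (nzchar(tab$precursor_chain[i]))
      parse_num(strsplit(tab$precursor_chain[i], ";", fixed = TRUE)[[1]])
    else numeric(0)
    pk <- if (nzchar(tab$peaks[i])) {
      pairs <- strsplit(strsplit(tab$peaks[i], " ", fixed = TRUE)[[1]], ":",
                        fixed = TRUE)
      new_peaks(parse_num(vapply(pairs, `[`, "", 1L)),
                parse_num(vapply(pairs, `[`, "", 2L)))
    } else new_peaks()
    msn_scan(tab$scan_id[i], tab$sample_id[i], as.integer(tab$ms_level[i]),
             chain, pk, rt = parse_num(tab$rt[i]),
             polarity = tab$polarity[i], peak_mode = tab$peak_mode[i],
             collision_energy = parse_num(tab$collision_energy[i]))
  })
}

# Thermo-style filter string -> precursor chain, or NULL when it does not
# carry one ("ms3 867.00@cid35.00 705.00@cid35.00" gives c(867, 705)).
parse_filter_chain <- function(filter, ms_level) {
  if (is.null(filter) || is.na(filter) || !nzchar(filter)) return(NULL)
  m <- regmatches(filter, gregexpr("[0-9]+\\.?[0-9]*(?=@)", filter, perl = TRUE))[[1]]
  if (length(m) != ms_level - 1L) return(NULL)
  as.numeric(m)
}

read_mzr <- function(path, sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- tools::file_path_sans_ext(basename(path))
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms), add = TRUE)
  n <- length(ms)
  if (n == 0L) return(list())
  h <- mzR::header(ms)
  pk <- mzR::peaks(ms)
  if (n == 1L) pk <- list(pk)
  acq_row <- seq_len(n)
  names(acq_row) <- as.character(h$acquisitionNum)

  chain_of <- function(i, depth = 0L) {
    lev <- h$msLevel[i]
    if (depth > 10L) return(NULL)  # cyclic references
    if (is.na(lev)) return(NULL)
    if (lev == 1L) return(numeric(0))
    own <- h$precursorMZ[i]
    if (is.na(own) || own <= 0) return(NULL)
    if (lev == 2L) return(own)
    parent <- h$precursorScanNum[i]
    if (is.na(parent) || parent <= 0) return(NULL)
    j <- acq_row[as.character(parent)]
    if (is.na(j)) return(NULL)
    up <- chain_of(j, depth + 1L)
    if (is.null(up) || length(up) != lev - 2L) return(NULL)
    c(up, own)
  }

  out <- vector("list", n)
  kept <- 0L
  filt <- if ("filterString" %in% names(h)) h$filterString else rep(NA_character_, n)
  for (i in seq_len(n)) {
    lev <- h$msLevel[i]
    if (is.na(lev)) {
      warning(sprintf("scan %d of %s: missing ms level, rejected", i, basename(path)))
      next
    }
    chain <- parse_filter_chain(filt[i], lev)
    if (is.null(chain)) chain <- chain_of(i)
    if (is.null(chain) || length(chain) != lev - 1L) {
      warning(sprintf("scan %d of %s: precursor chain inconsistent with MS%d, rejected",
                      i, basename(path), lev))
      next
    }
    p <- pk[[i]]
    # collapse occasional exact duplicate m/z rows (some writers emit them)
    if (nrow(p) && anyDuplicated(p[, 1L])) {
      ints <- tapply(p[, 2L], p[, 1L], max)
      p <- cbind(as.numeric(names(ints)), as.numeric(ints))
    }
    kept <- kept + 1L
    out[[kept]] <- msn_scan(
      scan_id = sprintf("%s.%d", sample_id, h$acquisitionNum[i]),
      sample_id = sample_id, ms_level = lev, precursor_chain = chain,
      peaks = if (nrow(p)) new_peaks(p[, 1L], p[, 2L]) else new_peaks(),
      rt = if (is.na(h$retentionTime[i])) NA_real_ else h$retentionTime[i],
      polarity = if (!is.na(h$polarity[i]) && h$polarity[i] == 0) "negative" else "positive",
      peak_mode = if (!is.na(h$centroided[i]) && !h$centroided[i]) "profile" else "centroid",
      collision_energy = h$collisionEnergy[i])
  }
  out[seq_len(kept)]
}

# 1-D single-linkage bin ids over a numeric vector: values whose sorted gap
# is <= the half-window (at the lower value) share a bin. Order-independent.
linkage_bins <- function(x, tol) {
  o <- order(x)
  xs <- x[o]
  if (length(xs) <= 1L) return(rep(1L, length(x)))
  gaps <- diff(xs)
  hw <- half_window(tol, xs[-length(xs)])
  bin_sorted <- cumsum(c(1L, as.integer(gaps > hw)))
  bin <- integer(length(x))
  bin[o] <- bin_sorted
  bin
}

#' Group scans by precursor chain
#'
#' Partitions scans so that two scans share a group iff they have the same
#' ms level and every entry of their precursor chains agrees within the
#' half-window. Each chain coordinate is binned by greedy single-linkage on
#' its sorted values, which makes the grouping independent of input order.
#' The group's `chain_center` is the entrywise median of member chains.
#'
#' @param scans list of [msn_scan()] objects (one polarity).
#' @param tol grouping tolerance (0.5 Th nominal, 20 ppm high-resolution).
#' @return list of `scan_group` objects (`chain_center`, `scans`, `ms_level`).
#' @export
group_by_chain <- function(scans, tol) {
  stopifnot(length(scans) > 0L)
  pol <- unique(vapply(scans, `[[`, "", "polarity"))
  if (length(pol) > 1L) stop("scans mix polarities; group each polarity separately")
  levels <- vapply(scans, `[[`, integer(1), "ms_level")
  groups <- list()
  for (lev in sort(unique(levels))) {
    idx <- which(levels == lev)
    if (lev == 1L) {
      key <- rep("1", length(idx))
    } else {
      chains <- do.call(rbind, lapply(scans[idx], `[[`, "precursor_chain"))
      bins <- apply(chains, 2L, linkage_bins, tol = tol)
      bins <- matrix(bins, nrow = length(idx))
      key <- apply(bins, 1L, paste, collapse = ".")
    }
    for (k in unique(key)) {
      members <- idx[key == k]
      chains <- lapply(scans[members], `[[`, "precursor_chain")
      center <- if (lev == 1L) numeric(0)
        else apply(do.call(rbind, chains), 2L, stats::median)
      groups[[length(groups) + 1L]] <- structure(
        list(chain_center = center, scans = scans[members], ms_level = lev),
        class = "scan_group")
    }
  }
  # deterministic order: ms level, then chain center
  ord <- order(vapply(groups, `[[`, integer(1), "ms_level"),
               vapply(groups, function(g) if (length(g$chain_center)) g$chain_center[1] else 0, numeric(1)),
               vapply(groups, function(g) if (length(g$chain_center) > 1) g$chain_center[2] else 0, numeric(1)))
  groups[ord]
}

#' @export
print.scan_group <- function(x, ...) {
  chain <- if (length(x$chain_center))
    paste(sprintf("%.4f", x$chain_center), collapse = " > ") else "-"
  cat(sprintf("<scan_group> MS%d chain=[%s] %d scans\n",
              x$ms_level, chain, length(x$scans)))
  invisible(x)
}
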