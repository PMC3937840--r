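# Run code under a fixed, fully specified RNG (Mersenne-Twister /
# Inversion / Rejection), restoring the caller's RNG state afterwards.
# Pinning all three kinds makes generated fixtures identical across
# platforms and R sessions.
with_rng <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

#' Template spectrum: generator ground truth
#'
#' @param chain precursor chain (MS^1 first); its length fixes the ms level
#'   of scans generated from the template (`length(chain) + 1`).
#' @param mz,intensity template peak list.
#' @param label class/isomer label carried through to generated scans.
#' @return object of class `template_spectrum`.
#' @export
template_spectrum <- function(chain, mz, intensity, label = "t") {
  structure(list(chain = as.numeric(chain),
                 peaks = new_peaks(mz, intensity),
                 label = as.character(label)),
            class = "template_spectrum")
}

#' Scan-to-scan noise model
#'
#' Multiplicative lognormal intensity noise with the stated coefficient of
#' variation (mean 1, so template intensities are unbiased), uniform m/z
#' jitter within the stated tolerance, and per-peak dropout. Fragmentation
#' spectra show substantial scan-to-scan intensity variation and weak
#' precursors often fail to yield higher-stage scans; these two terms
#' emulate exactly that.
#'
#' @param intensity_cv relative scan-to-scan coefficient of variation
#'   (default 0.3).
#' @param mz_jitter tolerance object bounding the m/z jitter
#'   (default +/- 0.05 Th).
#' @param dropout_prob probability a template peak is absent from a scan.
#' @param seed integer seed; every generator call is reproducible under it.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(intensity_cv = 0.3, mz_jitter = tol_da(0.05),
                        dropout_prob = 0, seed = 1L) {
  stopifnot(intensity_cv >= 0, dropout_prob >= 0, dropout_prob < 1)
  structure(list(intensity_cv = intensity_cv, mz_jitter = as_mz_tol(mz_jitter),
                 dropout_prob = dropout_prob, seed = as.integer(seed)),
            class = "noise_model")
}

perturb_peaks <- function(template_peaks, noise) {
  p <- template_peaks
  keep <- stats::runif(nrow(p)) >= noise$dropout_prob
  p <- p[keep, , drop = FALSE]
  if (nrow(p) == 0L) return(new_peaks())
  hw <- half_window(noise$mz_jitter, p[, "mz"])
  mz <- p[, "mz"] + stats::runif(nrow(p), -hw, hw)
  ints <- p[, "intensity"]
  if (noise$intensity_cv > 0) {
    sdlog <- sqrt(log(1 + noise$intensity_cv^2))
    ints <- ints * stats::rlnorm(nrow(p), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  new_peaks(mz, ints)
}

#' Generate noisy MS^n scans from template spectra
#'
#' Each emitted scan perturbs its template with the noise model:
#' multiplicative lognormal intensity noise, bounded m/z jitter, and peak
#' dropout. Chains are copied from the templates. Output is byte-identical
#' across runs under a fixed `noise$seed`.
#'
#' @param templates list of [template_spectrum()] objects.
#' @param n_scans_per_template scans generated per template and sample.
#' @param noise a [noise_model()].
#' @param samples character vector of sample ids (default `"S1"`).
#' @param polarity polarity assigned to all scans.
#' @return list of [msn_scan()] objects; each carries its template label in
#'   attribute `"label"`.
#' @export
make_msn_scans <- function(templates, n_scans_per_template, noise,
                           samples = "S1", polarity = "positive") {
  with_rng(noise$seed, {
    out <- list()
    for (sid in samples) {
      for (tpl in templates) {
        for (k in seq_len(n_scans_per_template)) {
          pk <- perturb_peaks(tpl$peaks, noise)
          sc <- msn_scan(
            scan_id = sprintf("%s.%s.%03d", sid, tpl$label, k),
            sample_id = sid, ms_level = length(tpl$chain) + 1L,
            precursor_chain = tpl$chain, peaks = pk, polarity = polarity)
          attr(sc, "label") <- tpl$label
          out[[length(out) + 1L]] <- sc
        }
      }
    }
    out
  })
}

#' Generate a synthetic LC run with co-eluting isomers
#'
#' Emulates the LC low-resolution scenario this package's clustering tools
#' target: one precursor m/z shared by several isomers that elute as
#' separate chromatographic peaks. MS^1 scans on a regular grid carry a
#' Gaussian XIC peak per isomer (apexes jittered per sample to give
#' realistic across-sample RT spread); MS^2 scans are emitted near each
#' apex from the corresponding isomer's template, their intensity scaled
#' by the chromatogram height. Ground-truth labels ride along as scan
#' attributes and in the returned `labels` vector.
#'
#' @param isomer_templates list of MS^2 [template_spectrum()] objects
#'   sharing the precursor m/z (chain of length 1).
#' @param apex_rts ordered apex retention times (s), separated by more
#'   than `4 * rt_sd`.
#' @param rt_sd across-sample apex standard deviation (s).
#' @param n_samples number of samples.
#' @param noise a [noise_model()] for the MS^2 spectra.
#' @param peak_sigma chromatographic peak sigma (s, default 8).
#' @param scan_interval MS^1 scan spacing (s, default 2).
#' @param ms2_per_peak MS^2 scans per isomer peak and sample (default 4).
#' @param ms1_height apex height of each XIC peak (default 5000).
#' @param polarity scan polarity (default negative, as for oligosaccharide
#'   LC runs).
#' @return list with `scans` (MS^1 + MS^2), `labels` (isomer label per
#'   MS^2 scan, in scan order), `apex_truth` (data.frame sample, label,
#'   apex_rt).
#' @export
make_lc_run <- function(isomer_templates, apex_rts, rt_sd = 4, n_samples = 5,
                        noise = noise_model(), peak_sigma = 8,
                        scan_interval = 2, ms2_per_peak = 4,
                        ms1_height = 5000, polarity = "negative") {
  stopifnot(length(isomer_templates) == length(apex_rts))
  if (is.unsorted(apex_rts, strictly = TRUE))
    stop("apex_rts must be strictly increasing")
  if (length(apex_rts) > 1L && min(diff(apex_rts)) <= 4 * rt_sd)
    stop("apex RTs must be separated by more than 4 * rt_sd")
  prec <- vapply(isomer_templates, function(t) t$chain[1], numeric(1))
  if (max(prec) - min(prec) > 1e-6)
    stop("isomer templates must share the precursor m/z")
  labels <- vapply(isomer_templates, `[[`, "", "label")
  with_rng(noise$seed, {
    scans <- list(); lab_out <- character(0)
    truth <- list()
    rt_grid <- seq(max(0, min(apex_rts) - 6 * peak_sigma),
                   max(apex_rts) + 6 * peak_sigma, by = scan_interval)
    for (s in seq_len(n_samples)) {
      sid <- sprintf("S%02d", s)
      apex_s <- apex_rts + stats::rnorm(length(apex_rts), 0, rt_sd)
      truth[[s]] <- data.frame(sample = sid, label = labels, apex_rt = apex_s)
      # MS1 scans: superposed Gaussian XIC peaks at the target m/z
      for (i in seq_along(rt_grid)) {
        h <- sum(ms1_height * exp(-(rt_grid[i] - apex_s)^2 / (2 * peak_sigma^2)))
        pk <- if (h > 1) new_peaks(prec[1], h) else new_peaks()
        scans[[length(scans) + 1L]] <- msn_scan(
          sprintf("%s.ms1.%04d", sid, i), sid, 1L, numeric(0), pk,
          rt = rt_grid[i], polarity = polarity)
      }
      # MS2 scans near each apex, from the matching isomer template
      for (j in seq_along(isomer_templates)) {
        rts <- apex_s[j] + stats::runif(ms2_per_peak, -peak_sigma, peak_sigma)
        for (k in seq_len(ms2_per_peak)) {
          scale <- exp(-(rts[k] - apex_s[j])^2 / (2 * peak_sigma^2))
          tpl <- isomer_templates[[j]]
          pk <- perturb_peaks(tpl$peaks, noise)
          pk[, "intensity"] <- pk[, "intensity"] * scale
          sc <- msn_scan(
            sprintf("%s.%s.ms2.%02d", sid, tpl$label, k), sid, 2L,
            tpl$chain[1], pk, rt = rts[k], polarity = polarity)
          attr(sc, "label") <- tpl$label
          scans[[length(scans) + 1L]] <- sc
          lab_out <- c(lab_out, tpl$label)
        }
      }
    }
    list(scans = scans, labels = lab_out, apex_truth = do.call(rbind, truth))
  })
}

#' Write scans to a fixture file
#'
#' Writes scans in the scantable text format or as mzML (through mzR).
#' Either file reads back with [read_scans()] losslessly up to float
#' round-off; the mzML writer stores the full precursor chain both as a
#' filter string (`"ms3 867.000000@cid35.00 705.000000@cid35.00"`) and,
#' where a parent scan exists in the file, as a precursor-scan reference.
#'
#' @param scans list of [msn_scan()] objects.
#' @param path output file.
#' @param format `"scantable"` or `"mzml"`.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(scans, path, format = c("scantable", "mzml")) {
  format <- match.arg(format)
  if (format == "scantable") return(write_scantable(scans, path))
  write_mzml(scans, path)
}

write_mzml <- function(scans, path) {
  n <- length(scans)
  mk_filter <- function(s) {
    if (s$ms_level == 1L) return(NA_character_)
    ce <- if (is.na(s$collision_energy)) 35 else s$collision_energy
    sprintf("ms%d %s", s$ms_level,
            paste(sprintf("%.6f@cid%.2f", s$precursor_chain, ce), collapse = " "))
  }
  lev <- vapply(scans, `[[`, integer(1), "ms_level")
  # best-effort parent link: most recent earlier scan one level up whose
  # chain is the prefix of this scan's chain
  parent_of <- integer(n)
  for (i in seq_len(n)) {
    parent_of[i] <- 0L
    if (lev[i] <= 1L) next
    want <- scans[[i]]$precursor_chain
    for (j in rev(seq_len(i - 1L))) {
      if (lev[j] != lev[i] - 1L) next
      pc <- scans[[j]]$precursor_chain
      if (length(want) == 1L ||
          all(abs(pc - want[-length(want)]) <= 1e-6)) { parent_of[i] <- j; break }
    }
  }
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = lev,
    polarity = vapply(scans, function(s) if (s$polarity == "negative") 0L else 1L, integer(1)),
    peaksCount = vapply(scans, function(s) nrow(s$peaks), integer(1)),
    totIonCurrent = vapply(scans, function(s) sum(s$peaks[, "intensity"]), numeric(1)),
    retentionTime = vapply(scans, function(s) if (is.na(s$rt)) 0 else s$rt, numeric(1)),
    basePeakMZ = vapply(scans, function(s)
      if (nrow(s$peaks)) s$peaks[which.max(s$peaks[, "intensity"]), "mz"] else 0, numeric(1)),
    basePeakIntensity = vapply(scans, base_peak_intensity, numeric(1)),
    collisionEnergy = vapply(scans, function(s)
      if (s$ms_level > 1L && is.na(s$collision_energy)) 35 else s$collision_energy, numeric(1)),
    ionisationEnergy = rep(0, n),
    lowMZ = vapply(scans, function(s) if (nrow(s$peaks)) min(s$peaks[, "mz"]) else 0, numeric(1)),
    highMZ = vapply(scans, function(s) if (nrow(s$peaks)) max(s$peaks[, "mz"]) else 0, numeric(1)),
    precursorScanNum = parent_of,
    precursorMZ = vapply(scans, function(s)
      if (s$ms_level > 1L) s$precursor_chain[s$ms_level - 1L] else 0, numeric(1)),
    precursorCharge = as.integer(ifelse(lev > 1L, 1L, 0L)),
    precursorIntensity = as.numeric(ifelse(lev > 1L, 100, 0)),
    mergedScan = rep(0L, n), mergedResultScanNum = rep(0L, n),
    mergedResultStartScanNum = rep(0L, n), mergedResultEndScanNum = rep(0L, n),
    injectionTime = rep(0, n),
    filterString = vapply(scans, mk_filter, character(1)),
    spectrumId = sprintf("scan=%d", seq_len(n)),
    centroided = vapply(scans, function(s) s$peak_mode == "centroid", logical(1)),
    ionMobilityDriftTime = rep(NA_real_, n),
    isolationWindowTargetMZ = vapply(scans, function(s)
      if (s$ms_level > 1L) s$precursor_chain[s$ms_level - 1L] else NA_real_, numeric(1)),
    isolationWindowLowerOffset = as.numeric(ifelse(lev > 1L, 1, NA_real_)),
    isolationWindowUpperOffset = as.numeric(ifelse(lev > 1L, 1, NA_real_)),
    scanWindowLowerLimit = rep(NA_real_, n), scanWindowUpperLimit = rep(NA_real_, n),
    stringsAsFactors = FALSE)
  pk <- lapply(scans, function(s)
    cbind(mz = s$peaks[, "mz"], intensity = s$peaks[, "intensity"]))
  mzR::writeMSData(object = pk, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Write a fixture manifest
#'
#' JSON record of the templates, labels and seed a fixture was generated
#' from, so a fixture file can always be traced back to (and regenerated
#' from) its generator call.
#'
#' @param templates list of [template_spectrum()] objects.
#' @param noise the [noise_model()] used.
#' @param path output JSON file.
#' @param extra optional named list of additional parameters to record.
#' @return `path`, invisibly.
#' @export
write_fixture_manifest <- function(templates, noise, path, extra = list()) {
  obj <- c(list(
    seed = noise$seed,
    noise = list(intensity_cv = noise$intensity_cv,
                 mz_jitter = list(value = noise$mz_jitter$value,
                                  kind = noise$mz_jitter$kind),
                 dropout_prob = noise$dropout_prob),
    templates = lapply(templates, function(t)
      list(label = t$label, chain = t$chain,
           mz = t$peaks[, "mz"], intensity = t$peaks[, "intensity"]))),
    extra)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Built-in template sets for the worked examples
#'
#' `templates_tree867()` reproduces the topology of the oligosaccharide
#' ion tree rooted at nominal m/z 867 (a penta-hexoside potassium adduct):
#' one MS^2 template with product ions 705/543/525 and three MS^3
#' templates for the chains 867-525, 867-543 and 867-705, showing the
#' repeated neutral loss of 162 (hexose - H2O).
#' `templates_trihexoside_isomers()` gives four MS^2 templates of isomeric
#' trihexosides ([M-H]- at nominal m/z 503) that share most fragment ions
#' (341, 323, 221, 179, ...) but differ in their ratios, the situation in
#' which intensity-aware spectral distances earn their keep.
#'
#' @return list of [template_spectrum()] objects.
#' @export
templates_tree867 <- function() {
  list(
    template_spectrum(867, c(705, 543, 525), c(8000, 3000, 1500), "ms2_867"),
    template_spectrum(c(867, 705), c(543, 381), c(2500, 900), "ms3_705"),
    template_spectrum(c(867, 543), c(381, 219), c(1200, 500), "ms3_543"),
    template_spectrum(c(867, 525), c(363, 345), c(800, 300), "ms3_525"))
}

#' @rdname templates_tree867
#' @export
templates_trihexoside_isomers <- function() {
  list(
    template_spectrum(503, c(179, 221, 263, 323, 341),
                      c(300, 100, 350, 200, 1000), "iso1"),
    template_spectrum(503, c(179, 221, 263, 323, 341),
                      c(450, 150, 100, 550, 1000), "iso2"),
    template_spectrum(503, c(161, 179, 221, 323, 341),
                      c(300, 200, 1000, 250, 600), "iso3"),
    template_spectrum(503, c(161, 221, 281, 323, 341),
                      c(500, 250, 400, 1000, 300), "iso4"))
}
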