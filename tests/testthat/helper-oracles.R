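# Independent oracles and small generators used across the suite.

# random peak list: n peaks, m/z in [lo, hi], intensities in [10, 1000]
random_peaks <- function(n, lo = 50, hi = 1000) {
  new_peaks(sort(runif(n, lo, hi)), runif(n, 10, 1000))
}

# Brute-force minimal distMS2-style score over ALL one-to-one matchings of
# two already-normalized peak lists (independent of the greedy path):
# enumerate every assignment of peaks of p1 to tolerance-compatible,
# unused peaks of p2 (or to "unmatched") and take the minimum of
# sum |i1 - i2| over matched + sum of unmatched intensities.
bf_min_score <- function(p1, p2, tol) {
  n1 <- nrow(p1); n2 <- nrow(p2)
  allowed <- lapply(seq_len(max(n1, 0)), function(i) {
    if (n2 == 0L) integer(0)
    else which(abs(p1[i, "mz"] - p2[, "mz"]) <=
                 half_window(tol, pmin(p1[i, "mz"], p2[, "mz"])))
  })
  best <- Inf
  rec <- function(i, used2, acc) {
    if (i > n1) {
      tot <- acc + sum(p2[!used2, "intensity"])
      if (tot < best) best <<- tot
      return(invisible())
    }
    # option: leave p1 peak i unmatched
    rec(i + 1L, used2, acc + p1[i, "intensity"])
    for (j in allowed[[i]]) {
      if (used2[j]) next
      u <- used2; u[j] <- TRUE
      rec(i + 1L, u, acc + abs(p1[i, "intensity"] - p2[j, "intensity"]))
    }
  }
  rec(1L, rep(FALSE, n2), 0)
  unname(best)
}

# greedy distMS2 score evaluated on pre-normalized peak lists (mirrors the
# arithmetic of distms2() after normalization, via the public matcher)
greedy_score <- function(p1, p2, tol) {
  m <- match_ions(p1, p2, tol)
  sum(abs(m$matched$i1 - m$matched$i2)) +
    sum(m$unmatched_1[, "intensity"]) + sum(m$unmatched_2[, "intensity"])
}

# mean silhouette width of given labels on a distance matrix / embedding
mean_silhouette <- function(d, labels) {
  sil <- cluster::silhouette(as.integer(factor(labels)), d)
  mean(sil[, 3])
}

# the four-isomer LC fixture used by the clustering checks (the study
# conditions: 13 samples x 4 MS2 scans per isomer peak = 52 per isomer,
# scan-to-scan intensity cv 0.3)
isomer_lc_fixture <- function(seed = 42) {
  make_lc_run(templates_trihexoside_isomers(), c(300, 336, 378, 402),
              rt_sd = 4, n_samples = 13,
              noise = noise_model(intensity_cv = 0.3, seed = seed),
              ms2_per_peak = 4)
}
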