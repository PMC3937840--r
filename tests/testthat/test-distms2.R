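test_that("ion matching is greedy one-to-one by closest m/z", {
  m <- match_ions(new_peaks(c(100, 150), c(1, 1)),
                  new_peaks(c(100, 160), c(1, 1)), tol_da(0.5))
  expect_equal(nrow(m$matched), 1L)
  expect_equal(m$matched$mz1, 100)
  expect_equal(unname(m$unmatched_1[, "mz"]), 150)
  expect_equal(unname(m$unmatched_2[, "mz"]), 160)
  # the closer of two in-window candidates wins
  m2 <- match_ions(new_peaks(100.0, 1),
                   new_peaks(c(100.2, 100.4), c(1, 1)), tol_da(0.5))
  expect_equal(m2$matched$mz2, 100.2)
  expect_equal(unname(m2$unmatched_2[, "mz"]), 100.4)
  s <- random_peaks(5)
  m3 <- match_ions(s, s, tol_da(0.5))
  expect_equal(nrow(m3$matched), 5L)
  expect_equal(nrow(m3$unmatched_1) + nrow(m3$unmatched_2), 0L)
})

test_that("distMS2 reproduces the hand-computed worked pairs", {
  s1 <- new_peaks(c(100, 150), c(1000, 500))
  s2 <- new_peaks(c(100, 160), c(600, 240))
  # base peak: |1 - 1| + 0.5 + 0.4
  expect_equal(distms2(s1, s2, norm_mode = "base_peak"), 0.9, tolerance = 1e-12)
  # sum: |2/3 - 5/7| + 1/3 + 2/7 = 2/3
  expect_equal(distms2(s1, s2, norm_mode = "sum"), 2 / 3, tolerance = 1e-12)
  # no shared ions under sum normalization -> the maximal score 2
  expect_identical(distms2(new_peaks(c(100, 120), c(5, 5)),
                           new_peaks(c(300, 320), c(7, 7)), norm_mode = "sum"), 2)
  expect_error(distms2(new_peaks(c(100), 0), s2), "degenerate")
})

test_that("distMS2 is a quasi-metric: identity and symmetry exact, non-negative", {
  set.seed(101)
  for (i in 1:100) {
    a <- random_peaks(sample(3:8, 1))
    b <- random_peaks(sample(3:8, 1))
    for (nm in c("sum", "base_peak")) {
      d_ab <- distms2(a, b, norm_mode = nm)
      expect_gte(d_ab, 0)
      expect_identical(d_ab, distms2(b, a, norm_mode = nm))
    }
    expect_identical(distms2(a, a), 0)
    expect_lte(distms2(a, b, norm_mode = "sum"), 2 + 1e-12)
  }
})

test_that("distMS2 violates the triangle inequality (documented triple)", {
  # tolerance chaining: A matches B and B matches C, but A and C are more
  # than the half-window apart, so d(A,C) = 2 while d(A,B) = d(B,C) = 0
  A <- new_peaks(100.0, 1); B <- new_peaks(100.4, 1); C <- new_peaks(100.8, 1)
  expect_identical(distms2(A, B), 0)
  expect_identical(distms2(B, C), 0)
  expect_identical(distms2(A, C), 2)
  expect_gt(distms2(A, C), distms2(A, B) + distms2(B, C))
})

test_that("base-peak normalization is bounded by the summed peak counts", {
  # worst case: every ion at base-peak intensity, nothing matches
  a <- new_peaks(c(100, 110, 120), c(7, 7, 7))
  b <- new_peaks(c(300, 310), c(9, 9))
  expect_identical(distms2(a, b, norm_mode = "base_peak"), 5)  # 3 + 2
})

test_that("greedy matching is optimal on sparse spectra, documented gap when dense", {
  # realistic sparse regime (4 ions over m/z 50-1000, 0.5 Th window):
  # enumeration confirms the greedy pairing is exact
  set.seed(103)
  for (i in 1:200) {
    a <- normalize_spectrum(random_peaks(4), "sum")$peaks
    b <- normalize_spectrum(random_peaks(4), "sum")$peaks
    g <- greedy_score(a, b, tol_da(0.5))
    o <- bf_min_score(a, b, tol_da(0.5))
    expect_equal(g, o, tolerance = 1e-12)
  }
  # known greedy/optimal gap when candidate windows overlap heavily: this
  # recorded instance (4 ions crowded into 40 Th with a 2 Th window) scores
  # 1.191099 greedy vs 1.116865 optimal
  a <- new_peaks(c(105.8495, 113.4942, 132.5981, 134.1266),
                 c(0.4439205, 0.1145118, 0.1494465, 0.2921212))
  b <- new_peaks(c(132.4406, 132.8692, 134.5581, 138.9103),
                 c(0.11232914, 0.50103432, 0.32607621, 0.06056034))
  g <- greedy_score(a, b, tol_da(2))
  o <- bf_min_score(a, b, tol_da(2))
  expect_gt(g, o)              # greedy is suboptimal here...
  expect_gte(g, o - 1e-12)     # ...but never beats the optimum
  expect_equal(g, 1.191099, tolerance = 1e-6)
  expect_equal(o, 1.116865, tolerance = 1e-6)
})

test_that("1 - r distance aligns ion unions and is scale invariant", {
  s <- random_peaks(5)
  expect_equal(corr_distance(s, s), 0, tolerance = 1e-12)
  s2 <- s; s2[, "intensity"] <- s2[, "intensity"] * 2
  expect_equal(corr_distance(s, s2), 0, tolerance = 1e-12)
  # disjoint equal-intensity pairs align to [a,a,0,0] vs [0,0,a,a]: r = -1
  a <- new_peaks(c(100, 120), c(5, 5))
  b <- new_peaks(c(300, 320), c(5, 5))
  expect_equal(corr_distance(a, b), 2, tolerance = 1e-12)
  expect_error(corr_distance(new_peaks(100, 5), new_peaks(100.1, 7)),
               "constant|undefined")
})

test_that("distance matrices are symmetric with zero diagonal", {
  s <- random_peaks(5)
  same <- list(a = s, b = s, c = s)
  D <- distance_matrix(same, "distms2")
  expect_true(all(D == 0))
  two <- list(x = new_peaks(c(100, 150), c(1000, 500)),
              y = new_peaks(c(100, 160), c(600, 240)))
  D2 <- distance_matrix(two, "distms2", norm_mode = "base_peak")
  expect_equal(D2["x", "y"], 0.9)
  expect_identical(D2, t(D2))
  expect_equal(diag(D2), c(x = 0, y = 0))
})

test_that("within-template distances are smaller than between-template ones", {
  tpls <- templates_trihexoside_isomers()
  scans <- make_msn_scans(tpls, 8, noise_model(intensity_cv = 0.3, seed = 77),
                          polarity = "negative")
  spectra <- lapply(scans, `[[`, "peaks")
  names(spectra) <- sprintf("q%02d", seq_along(spectra))
  labs <- vapply(scans, function(s) attr(s, "label"), "")
  D <- distance_matrix(spectra, "distms2")
  same <- outer(labs, labs, "==") & upper.tri(D)
  diff <- outer(labs, labs, "!=") & upper.tri(D)
  expect_lt(mean(D[same]), mean(D[diff]))
})

test_that("classical MDS reproduces Euclidean configurations", {
  D <- as.matrix(dist(matrix(c(0, 1, 2), ncol = 1)))
  X <- mds_embed(D, 1)
  expect_equal(as.matrix(dist(X)), D, tolerance = 1e-8, ignore_attr = TRUE)
  Z <- mds_embed(matrix(0, 4, 4), 2)
  expect_true(all(Z == 0))
  # k beyond the positive eigenvalues pads with zeros and warns
  # (two coincident points leave a single positive eigenvalue)
  Dc <- as.matrix(dist(matrix(c(0, 0, 5), ncol = 1)))
  expect_warning(X2 <- mds_embed(Dc, 2), "padding")
  expect_true(all(X2[, 2] == 0))
})
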