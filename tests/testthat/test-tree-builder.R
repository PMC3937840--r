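mk_scan <- function(id, chain, mz, int, sample = "A")
  msn_scan(id, sample, length(chain) + 1L, chain, new_peaks(mz, int))

test_that("representative spectrum merges member scans (median m/z, max intensity)", {
  g <- group_by_chain(list(mk_scan("a", c(867), 705.0, 100),
                           mk_scan("b", c(867), 705.1, 300)), tol_da(0.5))
  r <- representative_spectrum(g[[1]], tol_da(0.5))
  expect_equal(r$peaks, new_peaks(705.05, 300))
  expect_equal(r$n_scans, 2L)
  single <- group_by_chain(list(mk_scan("a", c(867), c(543, 705), c(50, 100))),
                           tol_da(0.5))
  r1 <- representative_spectrum(single[[1]], tol_da(0.5))
  expect_equal(r1$peaks, new_peaks(c(543, 705), c(50, 100)))
  expect_equal(r1$n_scans, 1L)
})

test_that("noisy replicate scans recover the 5-peak template", {
  tpl <- template_spectrum(867, c(219, 363, 543, 705, 810),
                           c(900, 400, 2000, 5000, 150), "t")
  scans <- make_msn_scans(list(tpl), 15,
                          noise_model(intensity_cv = 0.25,
                                      mz_jitter = tol_da(0.05), seed = 31))
  g <- group_by_chain(scans, tol_da(0.5))
  r <- representative_spectrum(g[[1]], tol_da(0.5))
  expect_equal(nrow(r$peaks), 5L)
  expect_equal(r$n_scans, 15L)
  expect_true(all(abs(r$peaks[, "mz"] - tpl$peaks[, "mz"]) <= 0.05))
})

test_that("tree construction yields one MS2 node and one MS3 node per chain", {
  scans <- list(mk_scan("m2", 867, c(525, 543, 705), c(200, 300, 800)),
                mk_scan("m3a", c(867, 525), 363, 150),
                mk_scan("m3b", c(867, 543), 381, 250),
                mk_scan("m3c", c(867, 705), 543, 400))
  trees <- build_tree(scans, 867, tol_da(0.5))
  expect_length(trees, 1L)
  t <- trees[["A"]]
  expect_length(t$ms2_nodes, 1L)
  expect_equal(n_ms3(t), 3L)
  chains <- t(vapply(t$ms3_nodes, `[[`, numeric(2), "chain"))
  expect_setequal(chains[, 2], c(525, 543, 705))
  # MS2-only input
  t2 <- build_tree(scans[1], 867, tol_da(0.5))[["A"]]
  expect_equal(n_ms3(t2), 0L)
  # minimal two-level tree
  t3 <- build_tree(list(mk_scan("a", 248, c(206, 231), c(500, 200)),
                        mk_scan("b", c(248, 206), c(149, 175), c(80, 120))),
                   248, tol_da(0.5))[["A"]]
  expect_length(t3$ms2_nodes, 1L)
  expect_equal(n_ms3(t3), 1L)
})

test_that("QC removes scans below the base-peak intensity threshold", {
  weak <- mk_scan("w", 867, c(100, 200), c(40, 99))
  edge <- mk_scan("e", 867, c(100, 200), c(40, 100))
  empty <- msn_scan("z", "A", 2, 867, new_peaks())
  expect_length(qc_filter_spectra(list(weak, edge, empty)), 1L)
  expect_equal(qc_filter_spectra(list(weak, edge, empty))[[1]]$scan_id, "e")
  # counting: 10 scans, 4 below threshold
  set.seed(41)
  bps <- c(30, 50, 80, 99, 100, 150, 400, 1000, 2500, 101)
  scans <- lapply(seq_along(bps), function(i)
    mk_scan(sprintf("s%d", i), 867, c(100, 200), c(bps[i] / 2, bps[i])))
  expect_length(qc_filter_spectra(scans), 6L)
})

test_that("QC before building prunes exactly the weak-scan branches", {
  # the 867-525 branch is generated weak (template base peak 800 scaled by
  # noise), so a threshold between its scans and the others removes that
  # node and leaves the rest of the tree untouched
  strong <- list(mk_scan("m2", 867, c(525, 543, 705), c(1500, 3000, 8000)),
                 mk_scan("m3a", c(867, 705), c(381, 543), c(900, 2500)),
                 mk_scan("m3b", c(867, 543), c(219, 381), c(500, 1200)))
  weak <- list(mk_scan("m3c", c(867, 525), c(345, 363), c(30, 80)))
  all_scans <- c(strong, weak)
  full <- build_tree(all_scans, 867, tol_da(0.5))[["A"]]
  pruned <- build_tree(qc_filter_spectra(all_scans, 100), 867, tol_da(0.5))[["A"]]
  expect_equal(n_ms3(full), 3L)
  expect_equal(n_ms3(pruned), 2L)
  ch <- function(t) sort(vapply(t$ms3_nodes, function(n) n$chain[2], numeric(1)))
  expect_equal(ch(pruned), setdiff(ch(full), 525))
  # surviving nodes are bit-identical to the full build (weak scans touched
  # only the pruned branch)
  expect_equal(pruned$ms2_nodes[[1]]$peaks, full$ms2_nodes[[1]]$peaks)
})

test_that("the most-branched tree wins, ties broken by intensity then sample id", {
  t0 <- build_tree(list(mk_scan("a", 867, 705, 500, "s1")), 867, tol_da(0.5))[[1]]
  t2 <- build_tree(list(mk_scan("a", 867, 705, 500, "s2"),
                        mk_scan("b", c(867, 705), 543, 100, "s2"),
                        mk_scan("c", c(867, 525), 363, 100, "s2")),
                   867, tol_da(0.5))[[1]]
  t3 <- build_tree(list(mk_scan("a", 867, 705, 500, "s3"),
                        mk_scan("b", c(867, 705), 543, 100, "s3"),
                        mk_scan("c", c(867, 525), 363, 100, "s3"),
                        mk_scan("d", c(867, 543), 381, 100, "s3")),
                   867, tol_da(0.5))[[1]]
  pick <- select_most_branched(list(t0, t2, t3))
  expect_equal(pick$sample_id, "s3")
  expect_equal(n_ms3(pick), max(0L, 2L, 3L))
  expect_equal(select_most_branched(list(t2))$sample_id, "s2")
  # tie on n_ms3 -> larger MS2 base-peak sum
  lo <- build_tree(list(mk_scan("a", 867, 705, 500, "sA"),
                        mk_scan("b", c(867, 705), 543, 100, "sA")),
                   867, tol_da(0.5))[[1]]
  hi <- build_tree(list(mk_scan("a", 867, 705, 900, "sB"),
                        mk_scan("b", c(867, 705), 543, 100, "sB")),
                   867, tol_da(0.5))[[1]]
  expect_equal(select_most_branched(list(lo, hi))$sample_id, "sB")
})

test_that("tree text notation serializes and parses the published grammar", {
  scans <- list(mk_scan("m2", 248, c(206, 231), c(900, 300)),
                mk_scan("m3", c(248, 206), c(149, 175), c(200, 500)))
  tree <- build_tree(scans, 248, tol_da(0.5))[["A"]]
  expect_equal(tree_to_text(tree, top_k_ms3_ions = 2), "248-206 (175, 149), 231")
  # root-only rendering
  bare <- build_tree(list(msn_scan("m", "A", 2, 248, new_peaks())),
                     248, tol_da(0.5))[["A"]]
  expect_equal(tree_to_text(bare), "248")
  # parse the published example (en-dash accepted)
  p <- parse_text_tree("248–206 (175, 149), 231")
  expect_equal(p$root, 248)
  expect_equal(vapply(p$children, `[[`, numeric(1), "mz"), c(206, 231))
  expect_equal(p$children[[1]]$ms3, c(175, 149))
  expect_length(p$children[[2]]$ms3, 0L)
  p2 <- parse_text_tree("867-705 (543), 543, 525")
  expect_length(p2$children, 3L)
  expect_error(parse_text_tree(""), "position")
  expect_error(parse_text_tree("248-206 (175, 149"), "unbalanced")
  # serialize -> parse round trip reproduces the topology
  txt <- tree_to_text(tree, 2)
  back <- parse_text_tree(txt)
  expect_equal(back$root, 248)
  expect_setequal(vapply(back$children, `[[`, numeric(1), "mz"), c(206, 231))
})

test_that("trees round-trip through JSON with peaks and scan counts", {
  scans <- make_msn_scans(templates_tree867(), 4, noise_model(seed = 9))
  tree <- build_tree(qc_filter_spectra(scans), 867, tol_da(0.5))[[1]]
  back <- tree_from_json(tree_to_json(tree))
  expect_equal(back$root_mz, tree$root_mz)
  expect_equal(n_ms3(back), n_ms3(tree))
  expect_equal(back$ms2_nodes[[1]]$peaks, tree$ms2_nodes[[1]]$peaks)
  expect_equal(back$ms3_nodes[[2]]$chain, tree$ms3_nodes[[2]]$chain)
})

test_that("build_tree recovers the generated topology exactly", {
  scans <- make_msn_scans(templates_tree867(), 8,
                          noise_model(intensity_cv = 0.3, seed = 23))
  tree <- build_tree(scans, 867, tol_da(0.5))[[1]]
  expect_length(tree$ms2_nodes, 1L)
  expect_equal(n_ms3(tree), 3L)
  expect_setequal(round(vapply(tree$ms3_nodes, function(n) n$chain[2], numeric(1))),
                  c(525, 543, 705))
})
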