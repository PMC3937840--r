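build_867_tree <- function(seed = 3) {
  scans <- make_msn_scans(templates_tree867(), 5, noise_model(seed = seed))
  build_tree(qc_filter_spectra(scans), 867, tol_da(0.5))[[1]]
}

test_that("library creation is idempotent and persists records", {
  f <- withr::local_tempfile(fileext = ".db")
  db <- mzdb_init(f)
  expect_length(mzdb_query_mz(db, 867, tol_da(0.5)), 0L)
  mzdb_close(db)
  db <- mzdb_init(f)  # second init: unchanged, no error
  tree <- build_867_tree()
  id <- mzdb_insert_tree(db, list(experiment_id = "e1", species = "Lolium perenne",
                                  polarity = "positive"), tree)
  mzdb_close(db)
  db <- mzdb_open(f)  # reopen: record still visible
  recs <- mzdb_query_mz(db, 867, tol_da(0.5))
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$record_id, id)
  expect_length(recs[[1]]$ms3_spectra, 3L)
  # referential integrity: the mz row's experiment exists
  exps <- DBI::dbGetQuery(db, "SELECT experiment_id FROM experiment")
  expect_true(recs[[1]]$experiment_id %in% exps$experiment_id)
  mzdb_close(db)
})

test_that("a schema-version mismatch refuses to open, never migrates", {
  f <- withr::local_tempfile(fileext = ".db")
  db <- mzdb_init(f)
  DBI::dbExecute(db, "UPDATE schema_version SET version = 99")
  mzdb_close(db)
  expect_error(mzdb_open(f), "schema version")
})

test_that("stored spectra round-trip within 1e-6 relative", {
  f <- withr::local_tempfile(fileext = ".db")
  db <- mzdb_init(f); withr::defer(mzdb_close(db))
  tree <- build_867_tree()
  mzdb_insert_tree(db, list(experiment_id = "e1"), tree)
  rec <- mzdb_query_mz(db, 867, tol_da(0.5))[[1]]
  expect_equal(rec$ms2_spectrum, tree$ms2_nodes[[1]]$peaks, tolerance = 1e-6)
  got_chains <- lapply(rec$ms3_spectra, `[[`, "chain")
  want_chains <- lapply(tree$ms3_nodes, `[[`, "chain")
  expect_equal(got_chains, want_chains, tolerance = 1e-6)
  for (i in seq_along(rec$ms3_spectra))
    expect_equal(rec$ms3_spectra[[i]]$peaks, tree$ms3_nodes[[i]]$peaks,
                 tolerance = 1e-6)
})

test_that("duplicate deposits are rejected unless replacement is requested", {
  f <- withr::local_tempfile(fileext = ".db")
  db <- mzdb_init(f); withr::defer(mzdb_close(db))
  tree <- build_867_tree()
  mzdb_insert_tree(db, list(experiment_id = "e1"), tree)
  expect_error(mzdb_insert_tree(db, list(experiment_id = "e1"), tree), "replace")
  id2 <- mzdb_insert_tree(db, list(experiment_id = "e1"), tree, replace = TRUE)
  expect_length(mzdb_query_mz(db, 867, tol_da(0.5)), 1L)
  # unknown experiment auto-created from the supplied record
  id3 <- mzdb_insert_tree(db, list(experiment_id = "e_new", tissue = "sheath"), tree)
  expect_equal(
    DBI::dbGetQuery(db, "SELECT tissue FROM experiment WHERE experiment_id = 'e_new'")$tissue,
    "sheath")
  # a tree without MS2 nodes cannot be deposited
  empty <- structure(list(root_mz = 500, sample_id = "A", ms2_nodes = list(),
                          ms3_nodes = list(), annotation = NULL),
                     class = "ion_tree")
  expect_error(mzdb_insert_tree(db, list(experiment_id = "e1"), empty), "MS2")
})

test_that("m/z queries respect absolute and ppm windows and RT filters", {
  f <- withr::local_tempfile(fileext = ".db")
  db <- mzdb_init(f); withr::defer(mzdb_close(db))
  tree <- build_867_tree()
  mzdb_insert_tree(db, list(experiment_id = "e1"), tree, rt = 300)
  expect_length(mzdb_query_mz(db, 867.2, tol_da(0.5)), 1L)
  expect_length(mzdb_query_mz(db, 400, tol_da(0.5)), 0L)
  expect_length(mzdb_query_mz(db, 867.2, tol_da(0.5), rt_window = c(290, 310)), 1L)
  expect_length(mzdb_query_mz(db, 867.2, tol_da(0.5), rt_window = c(10, 20)), 0L)
  # high-resolution record retrieved under a 20 ppm window
  hr <- tree; hr$root_mz <- 831.5005
  mzdb_insert_tree(db, list(experiment_id = "e1"), hr)
  expect_length(mzdb_query_mz(db, 831.5050, tol_ppm(20)), 1L)
})

test_that("library search ranks a stored copy first at distMS2 score 0", {
  f <- withr::local_tempfile(fileext = ".db")
  db <- mzdb_init(f); withr::defer(mzdb_close(db))
  tpls <- templates_trihexoside_isomers()
  # two isomer spectra stored under the same precursor
  for (k in 1:2) {
    tree <- structure(list(
      root_mz = 503, sample_id = sprintf("S%d", k),
      ms2_nodes = list(structure(list(chain = 503, peaks = tpls[[k]]$peaks,
                                      n_scans = 1L, agg = "max",
                                      sample_id = sprintf("S%d", k)),
                                 class = "rep_spectrum")),
      ms3_nodes = list(), annotation = NULL), class = "ion_tree")
    mzdb_insert_tree(db, list(experiment_id = sprintf("iso%d", k)), tree)
  }
  stored <- mzdb_query_mz(db, 503, tol_da(0.5))
  q <- stored[[1]]$ms2_spectrum
  hits <- mzdb_search(db, q, 503, tol_da(0.5))
  expect_equal(hits$record_id[1], stored[[1]]$record_id)
  expect_identical(hits$score[1], 0)
  # noisy copy of isomer 2 still ranks isomer 2 first
  noisy <- make_msn_scans(tpls[2], 1, noise_model(intensity_cv = 0.2, seed = 8))[[1]]
  hits2 <- mzdb_search(db, noisy$peaks, 503, tol_da(0.5))
  expect_equal(hits2$experiment_id[1], "iso2")
  expect_equal(nrow(mzdb_search(db, q, 503, tol_da(0.5), top_k = 1)), 1L)
  expect_equal(nrow(mzdb_search(db, q, 999, tol_da(0.5))), 0L)
})

test_that("annotation updates keep an audit trail of previous values", {
  f <- withr::local_tempfile(fileext = ".db")
  db <- mzdb_init(f); withr::defer(mzdb_close(db))
  id <- mzdb_insert_tree(db, list(experiment_id = "e1"), build_867_tree())
  rec <- mzdb_update_annotation(db, id, "penta-hexoside, [M+K]+")
  expect_equal(rec$annotation, "penta-hexoside, [M+K]+")
  mzdb_update_annotation(db, id, "peramine")
  audit <- DBI::dbGetQuery(db,
    "SELECT old_annotation FROM annotation_audit WHERE record_id = :r ORDER BY rowid",
    params = list(r = id))
  expect_equal(audit$old_annotation[2], "penta-hexoside, [M+K]+")
  expect_equal(mzdb_query_mz(db, 867, tol_da(0.5))[[1]]$annotation, "peramine")
  expect_error(mzdb_update_annotation(db, 9999, "x"), "no record")
})
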