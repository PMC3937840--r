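MZDB_SCHEMA_VERSION <- 1L

mzdb_schema_path <- function()
  system.file("extdata", "mzdb-schema.sql", package = "iontrees", mustWork = TRUE)

exec_sql_script <- function(con, path) {
  sql <- paste(readLines(path), collapse = "\n")
  sql <- gsub("--[^\n]*", "", sql)
  for (stmt in strsplit(sql, ";", fixed = TRUE)[[1]]) {
    if (nzchar(trimws(stmt))) DBI::dbExecute(con, stmt)
  }
}

#' Create (or open) a spectral-tree library
#'
#' The library ("mzDB") is a single-file SQLite database with two data
#' tables: `experiment` (biological origin and analytical meta-data) and
#' `mz` (one row per deposited ion tree: m/z, optional RT, serialized
#' MS^2/MS^3 representative spectra, free-text annotation). The schema is
#' shipped as plain SQL in `inst/extdata/mzdb-schema.sql`. `mzdb_init()` is
#' idempotent on an existing library of the same schema version and errors
#' on a version mismatch rather than migrating silently.
#'
#' @param path database file path.
#' @return open DBI connection (class `SQLiteConnection`); close with
#'   [mzdb_close()].
#' @export
mzdb_init <- function(path) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  ok <- FALSE
  on.exit(if (!ok) DBI::dbDisconnect(con))
  existing <- DBI::dbListTables(con)
  if ("schema_version" %in% existing) {
    v <- DBI::dbGetQuery(con, "SELECT version FROM schema_version")$version
    if (length(v) != 1L || v != MZDB_SCHEMA_VERSION)
      stop(sprintf("library at %s has schema version %s, expected %d; refusing to migrate",
                   path, paste(v, collapse = ","), MZDB_SCHEMA_VERSION))
  } else {
    exec_sql_script(con, mzdb_schema_path())
    DBI::dbExecute(con, "INSERT INTO schema_version (version) VALUES (:v)",
                   params = list(v = MZDB_SCHEMA_VERSION))
  }
  ok <- TRUE
  con
}

#' @rdname mzdb_init
#' @param db an open library connection.
#' @export
mzdb_open <- function(path) {
  if (!file.exists(path)) stop("no library at ", path)
  mzdb_init(path)
}

#' @rdname mzdb_init
#' @export
mzdb_close <- function(db) invisible(DBI::dbDisconnect(db))

# --- spectrum serialization: "mz:intensity" pairs, 6-decimal m/z ---------

serialize_peaks <- function(p) {
  if (nrow(p) == 0L) return("")
  paste(sprintf("%.6f:%.10g", p[, "mz"], p[, "intensity"]), collapse = " ")
}

deserialize_peaks <- function(s) {
  if (is.na(s) || !nzchar(s)) return(new_peaks())
  pairs <- strsplit(strsplit(s, " ", fixed = TRUE)[[1]], ":", fixed = TRUE)
  new_peaks(as.numeric(vapply(pairs, `[`, "", 1L)),
            as.numeric(vapply(pairs, `[`, "", 2L)))
}

serialize_ms3 <- function(nodes) {
  if (length(nodes) == 0L) return("")
  paste(vapply(nodes, function(n)
    paste0(paste(sprintf("%.6f", n$chain), collapse = ","), ">",
           serialize_peaks(n$peaks)),
    character(1)), collapse = ";")
}

deserialize_ms3 <- function(s) {
  if (is.na(s) || !nzchar(s)) return(list())
  lapply(strsplit(s, ";", fixed = TRUE)[[1]], function(node) {
    parts <- strsplit(node, ">", fixed = TRUE)[[1]]
    list(chain = as.numeric(strsplit(parts[1], ",", fixed = TRUE)[[1]]),
         peaks = deserialize_peaks(if (length(parts) > 1L) parts[2] else ""))
  })
}

experiment_fields <- c("experiment_id", "species", "tissue", "treatment",
                       "extraction_method", "chromatography", "ionization",
                       "polarity", "collision_energy", "preprocessing_notes")

#' Deposit an ion tree into the library
#'
#' The experiment row is upserted by `experiment_id`; the tree becomes one
#' `mz` row with its MS^2 and MS^3 representative spectra serialized as
#' `mz:intensity` text. Only QC-passed trees should be deposited (the
#' `qc_passed` flag records the caller's assertion). A second deposit for
#' the same (experiment, root m/z) is rejected unless `replace = TRUE`.
#'
#' @param db open library connection.
#' @param experiment named list/row with `experiment_id` and optionally
#'   the other experiment columns (species, tissue, treatment,
#'   extraction_method, chromatography, ionization, polarity,
#'   collision_energy, preprocessing_notes).
#' @param tree an `ion_tree` with at least one MS^2 node.
#' @param rt optional retention time (seconds) to store.
#' @param qc_passed logical flag recorded with the row.
#' @param replace replace an existing row for the same (experiment, m/z)?
#' @return integer `record_id` of the deposited row.
#' @export
mzdb_insert_tree <- function(db, experiment, tree, rt = NA_real_,
                             qc_passed = TRUE, replace = FALSE) {
  stopifnot(inherits(tree, "ion_tree"))
  if (length(tree$ms2_nodes) == 0L)
    stop("tree has no MS2 node; nothing to deposit")
  if (is.null(experiment$experiment_id) || !nzchar(experiment$experiment_id))
    stop("experiment record needs a non-empty experiment_id")
  eid <- as.character(experiment$experiment_id)
  vals <- lapply(experiment_fields, function(f) {
    v <- experiment[[f]]
    if (is.null(v) || length(v) == 0L) NA_character_ else as.character(v)
  })
  names(vals) <- experiment_fields
  n_exp <- DBI::dbGetQuery(db,
    "SELECT COUNT(*) AS n FROM experiment WHERE experiment_id = :id",
    params = list(id = eid))$n
  if (n_exp == 0L) {
    DBI::dbExecute(db, sprintf(
      "INSERT INTO experiment (%s) VALUES (%s)",
      paste(experiment_fields, collapse = ", "),
      paste0(":", experiment_fields, collapse = ", ")), params = vals)
  } else {
    DBI::dbExecute(db, sprintf(
      "UPDATE experiment SET %s WHERE experiment_id = :experiment_id",
      paste(sprintf("%s = :%s", experiment_fields[-1], experiment_fields[-1]),
            collapse = ", ")), params = vals)
  }
  dup <- DBI::dbGetQuery(db,
    "SELECT record_id FROM mz WHERE experiment_id = :id AND mz = :m",
    params = list(id = eid, m = tree$root_mz))
  if (nrow(dup)) {
    if (!replace)
      stop(sprintf("library already holds m/z %g for experiment '%s' (use replace = TRUE)",
                   tree$root_mz, eid))
    DBI::dbExecute(db, "DELETE FROM mz WHERE record_id = :r",
                   params = list(r = dup$record_id[1]))
  }
  DBI::dbExecute(db,
    "INSERT INTO mz (experiment_id, mz, rt, ms2_spectrum, ms3_spectra, annotation, qc_passed)
     VALUES (:e, :m, :rt, :s2, :s3, :ann, :qc)",
    params = list(e = eid, m = tree$root_mz, rt = rt,
                  s2 = serialize_peaks(tree$ms2_nodes[[1]]$peaks),
                  s3 = serialize_ms3(tree$ms3_nodes),
                  ann = if (is.null(tree$annotation)) NA_character_ else tree$annotation,
                  qc = as.integer(qc_passed)))
  as.integer(DBI::dbGetQuery(db, "SELECT last_insert_rowid() AS id")$id)
}

row_to_record <- function(r) {
  list(record_id = as.integer(r$record_id), experiment_id = r$experiment_id,
       mz = r$mz, rt = r$rt,
       ms2_spectrum = deserialize_peaks(r$ms2_spectrum),
       ms3_spectra = deserialize_ms3(r$ms3_spectra),
       annotation = if (is.na(r$annotation)) NULL else r$annotation,
       qc_passed = as.logical(r$qc_passed))
}

#' Query the library by m/z (and optionally RT)
#'
#' @param db open library connection.
#' @param mz query m/z.
#' @param tol match tolerance (absolute or ppm).
#' @param rt_window optional numeric `c(lo, hi)` retention-time filter in
#'   seconds (rows without RT are excluded when given).
#' @return list of records (`record_id`, `experiment_id`, `mz`, `rt`,
#'   `ms2_spectrum` peak matrix, `ms3_spectra`, `annotation`,
#'   `qc_passed`), ordered by |delta m/z|.
#' @export
mzdb_query_mz <- function(db, mz, tol, rt_window = NULL) {
  rows <- DBI::dbGetQuery(db, "SELECT * FROM mz")
  if (nrow(rows) == 0L) return(list())
  keep <- mz_within(rows$mz, mz, tol)
  if (!is.null(rt_window)) {
    stopifnot(length(rt_window) == 2L)
    keep <- keep & !is.na(rows$rt) &
      rows$rt >= rt_window[1] & rows$rt <= rt_window[2]
  }
  rows <- rows[keep, , drop = FALSE]
  if (nrow(rows) == 0L) return(list())
  rows <- rows[order(abs(rows$mz - mz)), , drop = FALSE]
  lapply(seq_len(nrow(rows)), function(i) row_to_record(rows[i, ]))
}

#' Search the library with a query MS^2 spectrum
#'
#' Candidate records are retrieved by precursor m/z and scored against
#' their stored MS^2 spectra with distMS2 (default) or the 1 - r baseline;
#' results come back in ascending score order, truncated to `top_k`. An
#' exact copy of a stored spectrum always ranks first with distMS2 score 0.
#'
#' @param db open library connection.
#' @param query_spectrum peak matrix of the query MS^2 spectrum.
#' @param precursor_mz precursor m/z of the query.
#' @param tol precursor match tolerance.
#' @param metric `"distms2"` or `"corr"`.
#' @param top_k maximum number of hits returned.
#' @param top_n,norm_mode spectral comparison parameters.
#' @param frag_tol fragment match tolerance (defaults to `tol`).
#' @return data.frame `record_id`, `experiment_id`, `mz`, `annotation`,
#'   `score` (zero rows when no candidate precursor matches).
#' @export
mzdb_search <- function(db, query_spectrum, precursor_mz, tol,
                        metric = c("distms2", "corr"), top_k = 5,
                        top_n = 5, norm_mode = c("sum", "base_peak"),
                        frag_tol = NULL) {
  metric <- match.arg(metric)
  norm_mode <- match.arg(norm_mode)
  if (is.null(frag_tol)) frag_tol <- tol
  cands <- mzdb_query_mz(db, precursor_mz, tol)
  if (length(cands) == 0L)
    return(data.frame(record_id = integer(0), experiment_id = character(0),
                      mz = numeric(0), annotation = character(0),
                      score = numeric(0)))
  score <- vapply(cands, function(r) {
    if (metric == "distms2")
      distms2(query_spectrum, r$ms2_spectrum, top_n = top_n,
              norm_mode = norm_mode, tol = frag_tol)
    else corr_distance(query_spectrum, r$ms2_spectrum, tol = frag_tol,
                       top_n = top_n)
  }, numeric(1))
  o <- order(score)[seq_len(min(top_k, length(score)))]
  data.frame(
    record_id = vapply(cands[o], `[[`, integer(1), "record_id"),
    experiment_id = vapply(cands[o], `[[`, "", "experiment_id"),
    mz = vapply(cands[o], `[[`, numeric(1), "mz"),
    annotation = vapply(cands[o], function(r)
      if (is.null(r$annotation)) NA_character_ else r$annotation, ""),
    score = score[o])
}

#' Update a record's annotation
#'
#' The previous annotation is kept in the `annotation_audit` table with a
#' timestamp before being replaced.
#'
#' @param db open library connection.
#' @param record_id id of the `mz` row.
#' @param text new annotation text.
#' @return the updated record (as from [mzdb_query_mz()]).
#' @export
mzdb_update_annotation <- function(db, record_id, text) {
  old <- DBI::dbGetQuery(db, "SELECT * FROM mz WHERE record_id = :r",
                         params = list(r = record_id))
  if (nrow(old) == 0L) stop("no record with record_id ", record_id)
  DBI::dbExecute(db,
    "INSERT INTO annotation_audit (record_id, old_annotation, changed_at)
     VALUES (:r, :a, :t)",
    params = list(r = record_id, a = old$annotation[1],
                  t = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  DBI::dbExecute(db, "UPDATE mz SET annotation = :a WHERE record_id = :r",
                 params = list(a = text, r = record_id))
  row_to_record(DBI::dbGetQuery(db, "SELECT * FROM mz WHERE record_id = :r",
                                params = list(r = record_id))[1, ])
}

#' Export both library tables as TSV
#'
#' @param db open library connection.
#' @param dir output directory (created if needed); writes
#'   `experiment.tsv` and `mz.tsv`.
#' @return `dir`, invisibly.
#' @export
mzdb_export_tsv <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tab in c("experiment", "mz")) {
    utils::write.table(DBI::dbGetQuery(db, sprintf("SELECT * FROM %s", tab)),
                       file.path(dir, paste0(tab, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
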