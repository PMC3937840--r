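-- mzDB: two-table relational spectral-tree library.
-- "experiment" holds biological and analytical meta-data; "mz" holds one
-- row per deposited ion tree: the m/z, optional retention time, the
-- serialized MS2/MS3 representative spectra and a free-text annotation.
-- "annotation_audit" keeps previous annotation values with timestamps;
-- "schema_version" guards against silent migrations.

CREATE TABLE IF NOT EXISTS schema_version (
  version INTEGER NOT NULL
);

CREATE TABLE IF NOT EXISTS experiment (
  experiment_id       TEXT PRIMARY KEY,
  species             TEXT,
  tissue              TEXT,
  treatment           TEXT,
  extraction_method   TEXT,
  chromatography      TEXT,
  ionization          TEXT,
  polarity            TEXT,
  collision_energy    TEXT,
  preprocessing_notes TEXT
);

CREATE TABLE IF NOT EXISTS mz (
  record_id     INTEGER PRIMARY KEY AUTOINCREMENT,
  experiment_id TEXT NOT NULL REFERENCES experiment(experiment_id),
  mz            REAL NOT NULL,
  rt            REAL,
  ms2_spectrum  TEXT NOT NULL,
  ms3_spectra   TEXT,
  annotation    TEXT,
  qc_passed     INTEGER NOT NULL DEFAULT 1
);

CREATE TABLE IF NOT EXISTS annotation_audit (
  record_id      INTEGER NOT NULL REFERENCES mz(record_id),
  old_annotation TEXT,
  changed_at     TEXT NOT NULL
);

CREATE INDEX IF NOT EXISTS idx_mz_mz ON mz(mz);
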