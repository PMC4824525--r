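test_that("OpenSWATH-headered TSV reads with the built-in dialect", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "ProteinName\tFullPeptideName\tCharge\tfilename\tIntensity\tm_score\tdecoy",
    "1/P0A1\tPEPTIDEA\t2\tf1.mzML\t1200.5\t0.0001\t0",
    "1/P0A1\tPEPTIDEA\t3\tf1.mzML\t300\t0.002\t0",
    "2/P0A1/P0B2\tPEPTIDEB\t2\tf1.mzML\t88\t0.3\t0",
    "DECOY_1/P0C3\tEDITPEPX\t2\tf1.mzML\t40\t0.5\t1"
  ), path)
  t <- read_peakgroup_table(path)
  expect_s3_class(t, "peakgroup_table")
  expect_equal(nrow(t), 4L)
  expect_named(t, c("protein_name", "peptide_sequence_mod",
                    "precursor_charge", "filename", "intensity", "m_score",
                    "decoy", "run_id"), ignore.order = TRUE)
  expect_equal(t$decoy, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("decoy flag falls back to the protein-name marker", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "ProteinName\tFullPeptideName\tCharge\tfilename\tIntensity\tm_score",
    "1/P0A1\tPEPTIDEA\t2\tf1\t1200\t0.0001",
    "DECOY_2/P0A1/P0B2\tPEPTIDEB\t2\tf1\t88\t0.3"
  ), path)
  t <- read_peakgroup_table(path)
  expect_equal(t$decoy, c(FALSE, TRUE))
})

test_that("missing minimal fields are reported by role name", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ProteinName\tFullPeptideName\tCharge\tfilename\tIntensity",
               "1/P1\tAAA\t2\tf1\t100"), path)
  expect_error(read_peakgroup_table(path), "score")

  df <- data.frame(ProteinName = "1/P1", filename = "f1", m_score = 0.1)
  expect_error(import_peakgroups(df, pg_dialect()), "signal")
})

test_that("generic import maps vendor headers and keeps extras", {
  df <- data.frame(
    "R.FileName" = c("s1", "s1"),
    "PG.ProteinGroups" = c("1/P1", "1/P2"),
    "EG.ModifiedSequence" = c("AAAK", "CCCK"),
    "FG.Charge" = 2:3,
    "FG.Quantity" = c(100, 200),
    "EG.Qvalue" = c(0.001, 0.01),
    "iRT" = c(35.2, 60.1),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  mapping <- c("R.FileName" = "filename", "PG.ProteinGroups" = "protein_name",
               "EG.ModifiedSequence" = "peptide_sequence_mod",
               "FG.Charge" = "precursor_charge", "FG.Quantity" = "intensity",
               "EG.Qvalue" = "m_score")
  t <- import_peakgroups(df, mapping)
  expect_s3_class(t, "peakgroup_table")
  expect_true("iRT" %in% names(t))
  expect_equal(t$iRT, df$iRT)

  bad <- c(mapping, "iRT" = "m_score")
  expect_error(import_peakgroups(df, bad), "collision")
})

test_that("validation rejects duplicates, cardinality mismatch and inconsistent decoy flags", {
  expect_error(make_pg(peptide_sequence_mod = c("A", "A"),
                       filename = c("f1", "f1")),
               "duplicate")
  expect_error(make_pg(peptide_sequence_mod = "A",
                       aggr_fragment_annotation = "y1_1;y2_1;y3_1",
                       aggr_peak_area = "1;2"),
               "cardinality mismatch")
  expect_error(make_pg(peptide_sequence_mod = "A", protein_name = "1/P1",
                       decoy = TRUE),
               "disagrees")
  expect_error(make_pg(peptide_sequence_mod = "A", intensity = -5),
               "negative intensity")
})

test_that("out-of-range m-scores are retained but flagged unusable", {
  t <- make_pg(peptide_sequence_mod = c("A", "B", "C"),
               m_score = c(0.01, 2, -1))
  expect_equal(nrow(t), 3L)
  expect_equal(attr(t, "n_unscored"), 2L)
  expect_equal(is.na(t$m_score), c(FALSE, TRUE, TRUE))
})

test_that("write/read TSV round trip is the identity on canonical fields", {
  sim <- simulate_peakgroups(sim_config(n_proteins = 10, seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peakgroup_table(sim$data, path)
  back <- read_peakgroup_table(path)
  for (col in intersect(names(sim$data), names(back))) {
    expect_identical(back[[col]], sim$data[[col]], label = col)
  }
  # a second write is byte-identical (fixed float format)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_peakgroup_table(back, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("decoy inference from marker matches the explicit column", {
  sim <- simulate_peakgroups(sim_config(n_proteins = 10, seed = 4))
  df <- as.data.frame(sim$data)
  df$decoy <- NULL
  t <- suppressMessages(as_peakgroup_table(df))
  expect_identical(t$decoy, sim$data$decoy)
})

test_that("reduce_columns keeps the canonical set and is idempotent", {
  t <- make_pg(peptide_sequence_mod = c("A", "B"), iRT = c(1, 2),
               extra_score = c(9, 9))
  r1 <- reduce_columns(t)
  expect_equal(nrow(r1), 2L)
  expect_false(any(c("iRT", "extra_score") %in% names(r1)))
  expect_identical(reduce_columns(r1), r1)
  # no rt column: reduced without error
  expect_false("rt" %in% names(r1))
})

test_that("MSstats-like tables convert back to peakgroup format", {
  ms <- data.frame(
    ProteinName = rep(c("P1", "P2"), each = 3),
    PeptideSequence = rep(c("AAAK", "CCCK"), each = 3),
    PrecursorCharge = 2L,
    Condition = rep(c("ctrl", "trt", "ctrl"), 2),
    BioReplicate = rep(c("1", "1", "2"), 2),
    Run = rep(c("r1", "r2", "r3"), 2),
    Intensity = c(10, 20, 30, 40, 50, 60),
    stringsAsFactors = FALSE
  )
  t <- from_msstats_like(ms)
  expect_equal(nrow(t), 6L)
  expect_equal(sort(unique(t$condition)), c("ctrl", "trt"))
  expect_equal(attr(t, "n_unscored"), 6L)

  expect_error(from_msstats_like(ms[setdiff(names(ms), "Run")]), "Run")
  empty <- from_msstats_like(ms[0, ])
  expect_s3_class(empty, "peakgroup_table")
  expect_equal(nrow(empty), 0L)
})

test_that("peakgroup -> MSstats -> peakgroup round trip preserves the id multiset", {
  sim <- simulate_peakgroups(sim_config(n_proteins = 8, seed = 5))
  t <- annotate_samples(sim$data, sim$design)
  tt <- disaggregate(t)
  ms <- to_msstats(tt)
  back <- from_msstats_like(ms)
  key <- function(x) sort(paste(x$protein_name, x$peptide_sequence_mod,
                                x$precursor_charge, x$run_id, x$intensity))
  tg <- t[!t$decoy, ]
  expect_equal(key(back), key(tg))
})

test_that("protein names parse into multiplicity and accessions", {
  p <- parse_protein_name(c("1/P1", "2/P1/P2", "DECOY_2/P1/P2", "P9"))
  expect_equal(p$multiplicity, c(1L, 2L, 2L, 1L))
  expect_equal(p$accessions, c("P1", "P1/P2", "P1/P2", "P9"))
  expect_equal(p$is_decoy_name, c(FALSE, FALSE, TRUE, FALSE))
})
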