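# engineered table: at c = 0.01, 200 distinct target assays and 10 decoy
# assays pass; further targets/decoys sit above the cutoff
fdr_formula_fixture <- function() {
  n_t <- 200; n_d <- 10
  make_pg(
    protein_name = c(rep("1/PT", n_t + 20), rep("DECOY_1/PT", n_d + 5)),
    peptide_sequence_mod = c(sprintf("TPEP%03d", 1:(n_t + 20)),
                             sprintf("DPEP%03d", 1:(n_d + 5))),
    filename = "r1",
    m_score = c(rep(0.005, n_t), rep(0.5, 20), rep(0.008, n_d), rep(0.6, 5))
  )
}

test_that("FDR equals fft * decoys / targets on engineered counts", {
  t <- fdr_formula_fixture()
  p <- fdr_parameters(fft = 1, thresholds = c(0.01))
  ft <- estimate_fdr_overall(t, p)
  a <- ft[ft$level == "assay", ]
  expect_equal(c(a$targets, a$decoys), c(200, 10))
  expect_equal(a$fdr, 0.05)

  ft2 <- estimate_fdr_overall(t, fdr_parameters(fft = 0.5, c(0.01)))
  expect_equal(ft2$fdr[ft2$level == "assay"], 0.025)
})

test_that("decoy rate reports distinct peptide counts and their ratio", {
  t <- fdr_formula_fixture()
  r <- assess_decoy_rate(t)
  expect_equal(r$target_peptides, 220)
  expect_equal(r$decoy_peptides, 15)
  expect_equal(r$ratio, 15 / 220)

  t2 <- make_pg(peptide_sequence_mod = c("A", "B"))
  expect_warning(r2 <- assess_decoy_rate(t2), "no decoy")
  expect_equal(r2$ratio, 0)
})

test_that("unit counts equal brute-force enumeration on random tables", {
  grid <- default_mscore_grid()
  for (seed in 1:8) {
    t <- random_small_pg(seed)
    ft <- suppressWarnings(estimate_fdr_overall(t, fdr_parameters(fft = 0.7)))
    for (lev in c("assay", "peptide", "protein")) {
      mins <- bf_unit_mins(t, lev)
      sub <- ft[ft$level == lev, ]
      for (k in seq(1, length(grid), by = 10)) {
        bf <- bf_counts(mins, grid[k])
        expect_equal(sub$targets[k], unname(bf["targets"]))
        expect_equal(sub$decoys[k], unname(bf["decoys"]))
      }
      ok <- sub$targets > 0
      expect_equal(sub$fdr[ok], 0.7 * sub$decoys[ok] / sub$targets[ok])
      expect_true(all(is.nan(sub$fdr[!ok])))
    }
  }
})

test_that("passing counts are non-decreasing in the threshold at every level", {
  sim <- simulate_peakgroups(sim_config(n_proteins = 20, seed = 61))
  ft <- estimate_fdr_overall(sim$data, fdr_parameters())
  cube <- estimate_fdr_by_run(sim$data, fdr_parameters())
  for (lev in c("assay", "peptide", "protein")) {
    sub <- ft[ft$level == lev, ]  # thresholds descending
    expect_true(all(diff(sub$targets) <= 0))
    expect_true(all(diff(sub$decoys) <= 0))
    for (r in unique(cube$run_id)) {
      s <- cube[cube$run_id == r & cube$level == lev, ]
      expect_true(all(diff(s$targets) <= 0))
      expect_true(all(diff(s$decoys) <= 0))
    }
  }
})

test_that("distinct-unit collapse orders decoy counts across levels", {
  sim <- simulate_peakgroups(sim_config(n_proteins = 30, seed = 62))
  ft <- estimate_fdr_overall(sim$data, fdr_parameters())
  d <- function(lev) ft$decoys[ft$level == lev]
  expect_true(all(d("protein") <= d("peptide")))
  expect_true(all(d("peptide") <= d("assay")))
})

test_that("two identical runs give identical per-run and global tables", {
  t1 <- fdr_formula_fixture()
  df <- as.data.frame(t1)
  df2 <- df
  df2$filename <- "r2"
  df2$run_id <- "r2"
  t <- suppressMessages(as_peakgroup_table(rbind(df, df2)))
  p <- fdr_parameters(thresholds = c(0.05, 0.01, 0.001))
  cube <- estimate_fdr_by_run(t, p)
  g <- estimate_fdr_overall(t, p)
  for (r in c("r1", "r2")) {
    s <- cube[cube$run_id == r, c("level", "mscore_cutoff", "targets",
                                  "decoys", "fdr")]
    rownames(s) <- NULL
    expect_equal(s, as.data.frame(g), ignore_attr = TRUE)
  }
  # single run: the cube collapses to the overall table
  cube1 <- estimate_fdr_by_run(t1, p)
  g1 <- estimate_fdr_overall(t1, p)
  expect_equal(cube1$fdr, g1$fdr)
})

test_that("a run with extra passing decoys has higher FDR everywhere", {
  targets <- data.frame(
    protein_name = "1/PT",
    peptide_sequence_mod = rep(sprintf("T%02d", 1:50), 2),
    precursor_charge = 2L,
    filename = rep(c("r1", "r2"), each = 50),
    intensity = 100,
    m_score = 1e-21,  # passes the whole grid
    stringsAsFactors = FALSE
  )
  decoys <- data.frame(
    protein_name = "DECOY_1/PT",
    peptide_sequence_mod = c(sprintf("D%02d", 1:5), sprintf("D%02d", 1:10)),
    precursor_charge = 2L,
    filename = c(rep("r1", 5), rep("r2", 10)),
    intensity = 100,
    m_score = c(rep(0.9, 5), rep(1e-21, 10)),
    stringsAsFactors = FALSE
  )
  t <- suppressMessages(as_peakgroup_table(rbind(targets, decoys)))
  cube <- estimate_fdr_by_run(t, fdr_parameters())
  a1 <- cube[cube$run_id == "r1" & cube$level == "assay", ]
  a2 <- cube[cube$run_id == "r2" & cube$level == "assay", ]
  expect_true(all(a2$fdr > a1$fdr))
})

test_that("runs without decoys are flagged undefined", {
  t <- make_pg(
    protein_name = c("1/P1", "DECOY_1/P1", "1/P1"),
    peptide_sequence_mod = c("AAA", "XXX", "AAA"),
    filename = c("r1", "r1", "r2")
  )
  cube <- estimate_fdr_by_run(t, fdr_parameters(thresholds = 0.01))
  expect_true(all(is.na(cube$fdr[cube$run_id == "r2"])))
  expect_false(anyNA(cube$fdr[cube$run_id == "r1" & cube$targets > 0]))
})

test_that("false positives accumulate over runs at the peptide level", {
  # the same 100 true peptides pass in each of 4 runs; each run contributes
  # one distinct passing decoy peptide
  runs <- paste0("r", 1:4)
  targets <- expand.grid(pep = sprintf("T%03d", 1:100), run = runs,
                         stringsAsFactors = FALSE)
  t <- make_pg(
    protein_name = c(rep("1/PT", nrow(targets)), rep("DECOY_1/PT", 4)),
    peptide_sequence_mod = c(targets$pep, paste0("D", 1:4)),
    filename = c(targets$run, runs),
    m_score = 1e-4
  )
  cube <- estimate_fdr_by_run(t, fdr_parameters(thresholds = 0.01))
  per_run <- cube$fdr[cube$level == "assay"]
  expect_equal(per_run, rep(1 / 100, 4))
  g <- estimate_fdr_overall(t, fdr_parameters(thresholds = 0.01))
  expect_equal(g$fdr[g$level == "peptide"], 4 / 100)
  expect_true(all(g$fdr[g$level == "peptide"] >= per_run))
})

test_that("threshold search picks the largest grid point under target", {
  # fft 0.5: fdr(1e-2) = 0.5 * 4/100 = 0.02, fdr(1e-3) = 0.5 * 1/100 = 0.005
  t <- make_pg(
    protein_name = c(rep("1/PT", 100), rep("DECOY_1/PT", 4)),
    peptide_sequence_mod = c(sprintf("T%03d", 1:100), paste0("D", 1:4)),
    filename = "r1",
    m_score = c(rep(5e-4, 100), 8e-4, rep(5e-3, 3))
  )
  p <- fdr_parameters(fft = 0.5, thresholds = c(1e-2, 1e-3))
  th <- suppressMessages(mscore_for_fdr(t, "assay", 0.01, p))
  expect_equal(unclass(th), 1e-3, ignore_attr = TRUE)
  expect_equal(attr(th, "achieved_fdr"), 0.005)

  th2 <- suppressMessages(mscore_for_fdr(t, "assay", 0.03, p))
  expect_equal(unclass(th2), 1e-2, ignore_attr = TRUE)

  expect_error(suppressMessages(mscore_for_fdr(t, "assay", 0.001, p)),
               "no m-score threshold")
})

test_that("filtering at the calibrated threshold achieves the target FDR", {
  sim <- simulate_peakgroups(sim_config(seed = 71, false_target_fraction = 0.2))
  t <- sim$data
  p <- fdr_parameters()
  for (lev in c("assay", "peptide", "protein")) {
    for (target in c(0.01, 0.05)) {
      th <- suppressMessages(mscore_for_fdr(t, lev, target, p))
      f <- suppressMessages(filter_mscore(t, unclass(th)))
      ft <- suppressWarnings(estimate_fdr_overall(f, p))
      sub <- ft[ft$level == lev & ft$mscore_cutoff == unclass(th), ]
      expect_lte(sub$fdr, target)
    }
  }
})
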