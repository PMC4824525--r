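# Fixture builders and independent oracles shared across the suite.
# Oracles are deliberately naive (row loops, explicit enumeration) and do not
# reuse package internals.

# compact peakgroup-table builder; scalars recycle over the longest column
make_pg <- function(..., decoy_marker = "DECOY_") {
  df <- data.frame(..., stringsAsFactors = FALSE)
  if (is.null(df$protein_name)) df$protein_name <- "1/P1"
  if (is.null(df$peptide_sequence_mod)) df$peptide_sequence_mod <- "PEPTIDEA"
  if (is.null(df$precursor_charge)) df$precursor_charge <- 2L
  if (is.null(df$filename)) df$filename <- "run1"
  if (is.null(df$intensity)) df$intensity <- 100
  if (is.null(df$m_score)) df$m_score <- 1e-3
  suppressMessages(as_peakgroup_table(df, decoy_marker = decoy_marker))
}

std_design <- function(runs, conditions, replicates) {
  data.frame(filename = runs, condition = conditions,
             bio_replicate = replicates, run = runs,
             stringsAsFactors = FALSE)
}

# a fixture whose decoys mirror the targets row-for-row: same scores,
# intensities, runs, charges and protein structure, distinct sequences and
# marked protein names
mirror_fixture <- function() {
  peps <- c("AAAAK", "CCCCK", "DDDDK", "EEEEK", "FFFFK")
  prots <- c("1/P1", "1/P1", "2/P1/P2", "1/P2", "1/P3")
  runs <- c("r1", "r2", "r3", "r4")
  grid <- expand.grid(p = seq_along(peps), r = seq_along(runs))
  set.seed(42)
  scores <- round(10^stats::runif(nrow(grid), -6, 0), 10)
  intens <- round(stats::runif(nrow(grid), 50, 5000), 2)
  tgt <- data.frame(
    protein_name = prots[grid$p],
    peptide_sequence_mod = peps[grid$p],
    precursor_charge = 2L,
    filename = runs[grid$r],
    intensity = intens,
    m_score = scores,
    stringsAsFactors = FALSE
  )
  dec <- tgt
  dec$protein_name <- paste0("DECOY_", tgt$protein_name)
  dec$peptide_sequence_mod <- chartr("ACDEF", "VWYHM", tgt$peptide_sequence_mod)
  t <- suppressMessages(as_peakgroup_table(rbind(tgt, dec)))
  design <- std_design(runs, rep(c("ctrl", "trt"), each = 2),
                       rep(c("1", "2"), times = 2))
  annotate_samples(t, design)
}

# random small table (<= 50 rows) exercising decoys, shared proteins and
# sentinel scores; unique (peptide, charge, filename) by construction
random_small_pg <- function(seed) {
  set.seed(seed)
  peps <- paste0("PEP", LETTERS[1:12])
  combos <- expand.grid(pep = peps, charge = 2:3,
                        file = c("f1", "f2", "f3"),
                        stringsAsFactors = FALSE)
  n <- sample(5:50, 1)
  rows <- combos[sample.int(nrow(combos), n), ]
  decoy <- stats::runif(n) < 0.4
  base <- ifelse(stats::runif(n) < 0.25,
                 paste0("2/Q", sample(1:4, n, TRUE), "/Q", sample(5:8, n, TRUE)),
                 paste0("1/Q", sample(1:6, n, TRUE)))
  score <- signif(10^stats::runif(n, -8, 0), 6)
  score[stats::runif(n) < 0.05] <- NA  # sentinel rows
  suppressMessages(as_peakgroup_table(data.frame(
    protein_name = ifelse(decoy, paste0("DECOY_", base), base),
    peptide_sequence_mod = rows$pep,
    precursor_charge = rows$charge,
    filename = rows$file,
    intensity = round(stats::runif(n, 10, 1000), 3),
    m_score = score,
    stringsAsFactors = FALSE
  )))
}

# independent brute-force oracle: best score per distinct unit via a row
# loop, then explicit counting of passing units
bf_unit_mins <- function(t, level, marker = "DECOY_") {
  units <- list()
  for (i in seq_len(nrow(t))) {
    if (!is.finite(t$m_score[i])) next
    key <- switch(level,
      assay = paste(t$peptide_sequence_mod[i], t$precursor_charge[i]),
      peptide = t$peptide_sequence_mod[i],
      protein = {
        nm <- sub(marker, "", t$protein_name[i], fixed = TRUE)
        sub("^[0-9]+/", "", nm)
      })
    key <- paste(t$decoy[i], key)
    units[[key]] <- min(c(units[[key]], t$m_score[i]))
  }
  units
}

bf_counts <- function(unit_mins, threshold) {
  pass <- names(unit_mins)[unlist(unit_mins) <= threshold]
  c(targets = sum(startsWith(pass, "FALSE")),
    decoys = sum(startsWith(pass, "TRUE")))
}

# brute-force evaluation of the condition/freqobs filter rules (assay kept
# wholesale); returns the set of kept assay keys
bf_freqobs_keys <- function(t, cutoff, min_fraction) {
  keys <- unique(paste(t$peptide_sequence_mod, t$precursor_charge))
  runs <- unique(t$run_id)
  kept <- character(0)
  for (k in keys) {
    sel <- paste(t$peptide_sequence_mod, t$precursor_charge) == k
    n_pass <- 0
    for (r in runs) {
      x <- t[sel & t$run_id == r, ]
      if (any(is.finite(x$m_score) & x$m_score <= cutoff)) n_pass <- n_pass + 1
    }
    if (n_pass / length(runs) >= min_fraction) kept <- c(kept, k)
  }
  kept
}

bf_condition_keys <- function(t, cutoff, min_obs, mode) {
  keys <- unique(paste(t$peptide_sequence_mod, t$precursor_charge))
  conds <- unique(t$condition)
  kept <- character(0)
  for (k in keys) {
    sel <- paste(t$peptide_sequence_mod, t$precursor_charge) == k
    ok_per_cond <- logical(length(conds))
    for (ci in seq_along(conds)) {
      x <- t[sel & t$condition == conds[ci], ]
      reps <- unique(x$bio_replicate[is.finite(x$m_score) &
                                     x$m_score <= cutoff])
      ok_per_cond[ci] <- length(reps) >= min_obs
    }
    keep <- if (mode == "any") any(ok_per_cond) else all(ok_per_cond)
    if (keep) kept <- c(kept, k)
  }
  kept
}

# per-cell Monte-Carlo standard error for |estimated - true| FDR comparison:
# Poisson noise on the decoy count plus counting noise on the false-target
# fraction among passing targets
fdr_mc_se <- function(fft, targets, decoys, n_false) {
  sqrt(fft^2 * max(decoys, 1) / targets^2 +
       max(n_false, 1) * (targets - n_false) / targets^3)
}
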