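# Synthetic OpenSWATH-like peakgroup tables with ground-truth labels.
#
# Score model: true-target m-scores are log10-normal (most true targets score
# very confidently); false targets and decoys draw from one shared
# Uniform(0, 1) null, the p-value-like null under which the decoy count
# models the false-target count -- the assumption that licenses the FFT
# correction.  With one mirrored decoy per target peptide (decoy_fraction =
# 1) the correct correction factor equals the generated false-target
# fraction exactly.
#
# Intensity model: log-normal peptide abundances with per-condition fold
# changes on a subset of proteins and multiplicative replicate noise of
# sigma_rep on the natural-log scale (CV ~= sqrt(exp(sigma^2) - 1)).

#' Simulation configuration
#'
#' Defaults emulate a small two-condition SWATH study: 2 conditions x 2
#' biological replicates (4 injections), 50 proteins with 2-4 peptides of
#' 3-6 transitions each, one mirrored decoy per target peptide, 10% false
#' targets, ~15% replicate CV and 5% per-run dropout.
#'
#' @param n_proteins number of target proteins.
#' @param peptides_per_protein integer range `c(min, max)`.
#' @param transitions_per_peptide integer range `c(min, max)`.
#' @param conditions condition labels (no delimiter characters).
#' @param replicates_per_condition biological replicates per condition.
#' @param false_target_fraction fraction of target peptides that are false
#'   identifications, in [0, 1) — the generator's true FFT when
#'   `decoy_fraction = 1`.
#' @param decoy_fraction probability that a target peptide gets a mirrored
#'   decoy counterpart.
#' @param shared_peptide_fraction fraction of peptides mapping to 2 proteins
#'   (emitted with the `"2/"` multiplicity prefix).
#' @param second_charge_fraction fraction of peptides also measured at a
#'   second precursor charge state.
#' @param diff_protein_fraction fraction of proteins with a condition
#'   effect.
#' @param log2_fold_change condition effect size for affected proteins.
#' @param sigma_rep replicate noise sd on the natural-log intensity scale.
#' @param mu_log10_true,sd_log10_true log10 m-score distribution of true
#'   targets (truncated at m-score 1).
#' @param dropout per-(assay, run) probability that the row is missing.
#' @param seed RNG seed (integer).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 50L,
                       peptides_per_protein = c(2L, 4L),
                       transitions_per_peptide = c(3L, 6L),
                       conditions = c("plasma0", "plasma10"),
                       replicates_per_condition = 2L,
                       false_target_fraction = 0.1,
                       decoy_fraction = 1,
                       shared_peptide_fraction = 0.1,
                       second_charge_fraction = 0.2,
                       diff_protein_fraction = 0.2,
                       log2_fold_change = 1,
                       sigma_rep = 0.15,
                       mu_log10_true = -5,
                       sd_log10_true = 1.5,
                       dropout = 0.05,
                       seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              peptides_per_protein = as.integer(peptides_per_protein),
              transitions_per_peptide = as.integer(transitions_per_peptide),
              conditions = as.character(conditions),
              replicates_per_condition = as.integer(replicates_per_condition),
              false_target_fraction = false_target_fraction,
              decoy_fraction = decoy_fraction,
              shared_peptide_fraction = shared_peptide_fraction,
              second_charge_fraction = second_charge_fraction,
              diff_protein_fraction = diff_protein_fraction,
              log2_fold_change = log2_fold_change,
              sigma_rep = sigma_rep,
              mu_log10_true = mu_log10_true,
              sd_log10_true = sd_log10_true,
              dropout = dropout,
              seed = as.integer(seed))
  if (cfg$n_proteins < 1L) stop("n_proteins must be >= 1")
  if (length(cfg$conditions) < 1L || cfg$replicates_per_condition < 1L) {
    stop("at least one condition with one replicate is required (zero runs)")
  }
  if (cfg$false_target_fraction < 0 || cfg$false_target_fraction >= 1) {
    stop("false_target_fraction must be in [0, 1)")
  }
  if (cfg$decoy_fraction < 0 || cfg$decoy_fraction > 1) {
    stop("decoy_fraction must be in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

.random_peptides <- function(n) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- character(0)
  while (length(seqs) < n) {
    more <- vapply(seq_len(n - length(seqs)), function(i) {
      paste(sample(aa, sample(8:15, 1L), replace = TRUE), collapse = "")
    }, "")
    seqs <- unique(c(seqs, more))
  }
  seqs[seq_len(n)]
}

# transition identifiers embed the precursor charge (as OpenSWATH assay
# libraries do), so fragments of the same peptide at different precursor
# charges stay distinct in wide reshapes
.random_fragments <- function(k, precursor_charge) {
  grid <- expand.grid(ion = c("b", "y"), pos = 3:12, chg = 1:2,
                      stringsAsFactors = FALSE)
  pick <- grid[sample.int(nrow(grid), k), , drop = FALSE]
  paste0("p", precursor_charge, "_", pick$ion, pick$pos, "_", pick$chg)
}

# draw from a single RNG stream keyed by the seed; caller's RNG state is
# restored on exit
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic peakgroup table with ground truth
#'
#' Produces an OpenSWATH-like long-format table (one row per assay per
#' injection), the matching study design, and a label table marking every
#' target assay as a true or false identification and every decoy as such.
#' Filenames encode condition and replicate
#' (`swathsim_<condition>_rep<r>_<k>.mzML`), so [design_from_filenames()]
#' can recover the design.  Output is deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with elements `data` (a `peakgroup_table`), `labels`
#'   (columns `peptide_sequence_mod`, `precursor_charge`, `protein_name`,
#'   `class` in `true_target`/`false_target`/`decoy`), and `design`.
#' @export
simulate_peakgroups <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, .simulate_impl(config))
}

.simulate_impl <- function(cfg) {
  # runs / design
  reps <- seq_len(cfg$replicates_per_condition)
  design <- expand.grid(bio_replicate = paste0("rep", reps),
                        condition = cfg$conditions,
                        stringsAsFactors = FALSE)
  design <- design[order(design$condition, design$bio_replicate), ]
  design$filename <- sprintf("swathsim_%s_%s_%03d.mzML", design$condition,
                             design$bio_replicate, seq_len(nrow(design)))
  design$run <- design$filename
  design <- design[, c("filename", "condition", "bio_replicate", "run")]
  rownames(design) <- NULL
  n_runs <- nrow(design)

  # target proteins and peptides
  prots <- sprintf("sp%03d", seq_len(cfg$n_proteins))
  n_pep <- sample(seq(cfg$peptides_per_protein[1], cfg$peptides_per_protein[2]),
                  cfg$n_proteins, replace = TRUE)
  pep_prot <- rep(seq_len(cfg$n_proteins), n_pep)
  n_peptides <- length(pep_prot)
  pep_seq <- .random_peptides(n_peptides)

  # shared peptides map to a second protein ("2/" multiplicity prefix)
  shared <- stats::runif(n_peptides) < cfg$shared_peptide_fraction &
    cfg$n_proteins > 1L
  second <- vapply(pep_prot, function(p) {
    s <- sample.int(cfg$n_proteins, 1L)
    if (s == p) (p %% cfg$n_proteins) + 1L else s
  }, 0L)
  pep_name <- ifelse(shared,
                     paste0("2/", prots[pep_prot], "/", prots[second]),
                     paste0("1/", prots[pep_prot]))

  false_pep <- stats::runif(n_peptides) < cfg$false_target_fraction
  decoy_pep <- stats::runif(n_peptides) < cfg$decoy_fraction

  # assays: every peptide at one charge, a fraction at a second charge
  charge1 <- sample(2:3, n_peptides, replace = TRUE)
  two_chg <- stats::runif(n_peptides) < cfg$second_charge_fraction
  assay_pep <- c(seq_len(n_peptides), which(two_chg))
  assay_chg <- c(charge1, ifelse(charge1[two_chg] == 2L, 3L, 2L))

  # abundance model (per peptide, per condition)
  prot_mu <- stats::rnorm(cfg$n_proteins, mean = log(5e4), sd = 1.2)
  diff_prot <- stats::runif(cfg$n_proteins) < cfg$diff_protein_fraction
  pep_off <- stats::rnorm(n_peptides, 0, 0.5)
  cond_idx <- match(design$condition, cfg$conditions)
  # condition effect applies from the second condition on
  cond_eff <- outer(diff_prot * cfg$log2_fold_change * log(2),
                    as.numeric(cond_idx > 1L))

  build_rows <- function(ap, ac, names_vec, seqs, is_decoy, is_false) {
    n_assay <- length(ap)
    rows <- vector("list", n_assay)
    for (i in seq_len(n_assay)) {
      p <- ap[i]
      k <- sample(seq(cfg$transitions_per_peptide[1],
                      cfg$transitions_per_peptide[2]), 1L)
      frags <- .random_fragments(k, ac[i])
      w <- stats::rgamma(k, shape = 2)
      w <- w / sum(w)
      mu_base <- prot_mu[pep_prot[p]] + pep_off[p]
      from_null <- is_false[p] || is_decoy
      per_run <- vector("list", n_runs)
      for (r in seq_len(n_runs)) {
        if (stats::runif(1) < cfg$dropout) next
        m <- if (from_null) {
          stats::runif(1)
        } else {
          10^min(stats::rnorm(1, cfg$mu_log10_true, cfg$sd_log10_true), 0)
        }
        mu <- mu_base + cond_eff[pep_prot[p], r] +
          stats::rnorm(1, 0, cfg$sigma_rep)
        areas <- round(w * exp(mu), 4)
        per_run[[r]] <- data.frame(
          protein_name = names_vec[p],
          peptide_sequence_mod = seqs[p],
          peptide_sequence_stripped = seqs[p],
          precursor_charge = ac[i],
          filename = design$filename[r],
          run_id = design$run[r],
          intensity = sum(areas),
          m_score = m,
          rt = round(stats::runif(1, 100, 6000), 2),
          aggr_fragment_annotation = paste(frags, collapse = ";"),
          aggr_peak_area = paste(.fmt_shortest(areas), collapse = ";"),
          stringsAsFactors = FALSE
        )
      }
      rows[[i]] <- do.call(rbind, per_run)
    }
    do.call(rbind, rows)
  }

  target_rows <- build_rows(assay_pep, assay_chg, pep_name, pep_seq,
                            is_decoy = FALSE, is_false = false_pep)

  # mirrored decoys: same structure, distinct (reversed) sequences, marked
  # protein names, null scores
  dec_idx <- which(decoy_pep)
  dec_rows <- NULL
  dec_seq <- character(0)
  if (length(dec_idx)) {
    dec_seq_all <- rep(NA_character_, n_peptides)
    dec_seq_all[dec_idx] <- vapply(pep_seq[dec_idx], function(s) {
      paste(rev(strsplit(s, "")[[1]]), collapse = "")
    }, "")
    dec_name_all <- paste0("DECOY_", pep_name)
    keep_assay <- assay_pep %in% dec_idx
    dec_rows <- build_rows(assay_pep[keep_assay], assay_chg[keep_assay],
                           dec_name_all, dec_seq_all,
                           is_decoy = TRUE, is_false = false_pep)
    dec_seq <- dec_seq_all
  }

  data <- rbind(target_rows, dec_rows)
  data$decoy <- grepl("DECOY_", data$protein_name, fixed = TRUE)
  data <- suppressMessages(as_peakgroup_table(data))

  labels <- data.frame(
    peptide_sequence_mod = c(pep_seq[assay_pep],
                             if (length(dec_idx))
                               dec_seq[assay_pep[assay_pep %in% dec_idx]]),
    precursor_charge = c(assay_chg,
                         if (length(dec_idx))
                           assay_chg[assay_pep %in% dec_idx]),
    protein_name = c(pep_name[assay_pep],
                     if (length(dec_idx))
                       paste0("DECOY_", pep_name[assay_pep[assay_pep %in% dec_idx]])),
    class = c(ifelse(false_pep[assay_pep], "false_target", "true_target"),
              if (length(dec_idx))
                rep("decoy", sum(assay_pep %in% dec_idx))),
    stringsAsFactors = FALSE
  )
  labels <- unique(labels)

  list(data = data, labels = labels, design = design)
}

#' Label-based true FDR among passing target units
#'
#' Exhaustively counts, at the given threshold and level, the target units
#' whose best m-score passes and returns the fraction of them labelled
#' false — the ground-truth quantity the decoy-based estimator approximates.
#' At the peptide level a peptide is false when all its assays are false; at
#' the protein level a protein is false when all its peptides are false.
#'
#' @param labels label table from [simulate_peakgroups()].
#' @param t the matching `peakgroup_table`.
#' @param threshold m-score threshold.
#' @param level `"assay"`, `"peptide"` or `"protein"`.
#' @return the true FDR (0 when no target unit passes).
#' @export
true_fdr <- function(labels, t, threshold,
                     level = c("assay", "peptide", "protein")) {
  level <- match.arg(level)
  stopifnot(inherits(t, "peakgroup_table"))
  marker <- .decoy_marker(t)
  tl <- labels[labels$class != "decoy", , drop = FALSE]
  unit_of <- function(pep, chg, prot) {
    switch(level,
      assay   = paste(pep, chg, sep = "/"),
      peptide = pep,
      protein = .protein_key(prot, marker))
  }
  # unit is false iff all its labelled assays are false
  lu <- unit_of(tl$peptide_sequence_mod, tl$precursor_charge, tl$protein_name)
  false_unit <- vapply(split(tl$class == "false_target", lu), all, NA)

  tg <- t[!t$decoy & .scored(t), , drop = FALSE]
  ku <- unit_of(tg$peptide_sequence_mod, tg$precursor_charge, tg$protein_name)
  best <- vapply(split(tg$m_score, ku), min, 0)
  pass <- names(best)[best <= threshold]
  if (!length(pass)) return(0)
  hit <- match(pass, names(false_unit))
  if (anyNA(hit)) {
    stop("unlabeled target unit(s): ",
         paste(utils::head(pass[is.na(hit)], 5L), collapse = ", "))
  }
  mean(false_unit[hit])
}
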