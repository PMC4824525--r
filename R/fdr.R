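# Target-decoy FDR estimation with the FFT (pi0) correction.
#
# A unit (assay, peptide or protein) is identified at threshold c if its best
# (minimum) m-score over its rows is <= c.  With T(c) distinct passing target
# units and D(c) distinct passing decoy units,
#
#     FDR(c) = FFT * D(c) / T(c)
#
# where FFT in (0, 1] is the fraction of false targets (pi0), the correction
# for the ratio of decoys to false targets; FFT = 1 is the conservative naive
# target-decoy estimate.

.fdr_levels <- c("assay", "peptide", "protein")

#' Default m-score threshold grid
#'
#' Quarter-decade steps from 1e-1 down to 1e-20, i.e. `10^(-k/4)` for
#' `k = 4, ..., 80`, in descending order.  The threshold search of
#' [mscore_for_fdr()] is resolution-limited by this grid, which is why the
#' achieved FDR is always reported alongside the selected threshold.
#'
#' @return descending numeric vector of thresholds.
#' @export
default_mscore_grid <- function() 10^(-(4:80) / 4)

#' FDR estimation parameters
#'
#' @param fft fraction of false targets (pi0) in (0, 1]; multiplies the
#'   decoy/target ratio.  The default 1 never understates the FDR.
#' @param thresholds strictly positive m-score cutoffs; sorted descending.
#' @return list of class `fdr_parameters`.
#' @export
fdr_parameters <- function(fft = 1, thresholds = default_mscore_grid()) {
  if (!is.numeric(fft) || length(fft) != 1L || !is.finite(fft) ||
      fft <= 0 || fft > 1) {
    stop("fft must be a single value in (0, 1]")
  }
  if (!length(thresholds)) stop("threshold grid must be non-empty")
  if (!all(is.finite(thresholds) & thresholds > 0)) {
    stop("thresholds must be strictly positive")
  }
  structure(list(fft = fft,
                 thresholds = sort(unique(thresholds), decreasing = TRUE)),
            class = "fdr_parameters")
}

#' Decoy rate report
#'
#' Counts distinct decoy and target peptides and their ratio — a first
#' sanity check that decoys are present and roughly in the expected
#' proportion before any FDR estimation.
#'
#' @param t a `peakgroup_table` with the decoy flag populated.
#' @return list of class `decoy_rate_report` with `target_peptides`,
#'   `decoy_peptides`, `ratio`.
#' @export
assess_decoy_rate <- function(t) {
  stopifnot(inherits(t, "peakgroup_table"))
  n_t <- length(unique(t$peptide_sequence_mod[!t$decoy]))
  n_d <- length(unique(t$peptide_sequence_mod[t$decoy]))
  if (n_d == 0L) {
    warning("no decoy entries present; FDR estimation will be impossible")
  }
  structure(list(target_peptides = n_t, decoy_peptides = n_d,
                 ratio = if (n_t > 0) n_d / n_t else NA_real_),
            class = "decoy_rate_report")
}

#' @export
print.decoy_rate_report <- function(x, ...) {
  cat("decoy rate: ", x$decoy_peptides, " decoy / ", x$target_peptides,
      " target peptides (ratio ", format(x$ratio, digits = 4), ")\n",
      sep = "")
  invisible(x)
}

# best (minimum) m-score per distinct unit, split by decoy status;
# only rows with a usable m-score contribute
.unit_best_scores <- function(t, level) {
  s <- t[.scored(t), , drop = FALSE]
  key <- switch(level,
    assay   = paste(s$peptide_sequence_mod, s$precursor_charge, sep = "/"),
    peptide = s$peptide_sequence_mod,
    protein = .protein_key(s$protein_name, .decoy_marker(t))
  )
  grp <- paste0(as.integer(s$decoy), "\r", key)
  best <- vapply(split(s$m_score, grp), min, 0)
  is_decoy <- startsWith(names(best), "1")
  list(target = unname(best[!is_decoy]), decoy = unname(best[is_decoy]))
}

# counts of units passing each threshold, for one sorted score vector
.pass_counts <- function(scores, thresholds) {
  if (!length(scores)) return(integer(length(thresholds)))
  s <- sort(scores)
  findInterval(thresholds, s)  # number of scores <= threshold
}

.fdr_one_table <- function(t, p) {
  th <- p$thresholds
  out <- lapply(.fdr_levels, function(lev) {
    b <- .unit_best_scores(t, lev)
    T_ <- .pass_counts(b$target, th)
    D_ <- .pass_counts(b$decoy, th)
    fdr <- ifelse(T_ > 0, p$fft * D_ / T_, NaN)
    data.frame(level = lev, mscore_cutoff = th, targets = T_, decoys = D_,
               fdr = fdr, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Estimate FDR globally across all runs
#'
#' For each threshold of the grid and each level (assay = modified peptide x
#' charge; peptide = modified peptide; protein = accession set, multiplicity
#' prefix and decoy marker stripped), counts the distinct target and decoy
#' units whose best m-score over all runs passes the threshold and reports
#' `fdr = fft * decoys / targets`.  A protein passes as soon as any of its
#' peptides' assays passes.  Cells with zero passing targets are undefined
#' (`NaN`), never zero.
#'
#' @param t a `peakgroup_table` with decoys present.
#' @param p an `fdr_parameters` object.
#' @return data frame of class `fdr_table` (columns `level`,
#'   `mscore_cutoff`, `targets`, `decoys`, `fdr`) with attribute `fft`.
#' @export
estimate_fdr_overall <- function(t, p = fdr_parameters()) {
  stopifnot(inherits(t, "peakgroup_table"), inherits(p, "fdr_parameters"))
  if (!any(t$decoy)) {
    warning("no decoy entries; all decoy counts are zero and the FDR ",
            "estimate is uninformative (see assess_decoy_rate)")
  }
  out <- .fdr_one_table(t, p)
  structure(out, class = c("fdr_table", "data.frame"), fft = p$fft)
}

#' Estimate FDR within each run
#'
#' [estimate_fdr_overall()] applied independently to each run's rows and
#' stacked.  Runs containing no decoy rows are flagged undefined (`NA` FDR):
#' without decoys the run contributes no estimate.
#'
#' @inheritParams estimate_fdr_overall
#' @return data frame of class `fdr_cube` (columns `run_id`, `level`,
#'   `mscore_cutoff`, `targets`, `decoys`, `fdr`) with attribute `fft`.
#' @export
estimate_fdr_by_run <- function(t, p = fdr_parameters()) {
  stopifnot(inherits(t, "peakgroup_table"), inherits(p, "fdr_parameters"))
  runs <- unique(t$run_id)
  if (!length(runs)) stop("no runs in table")
  out <- lapply(runs, function(r) {
    tr <- t[t$run_id == r, , drop = FALSE]
    tab <- .fdr_one_table(tr, p)
    if (!any(tr$decoy)) tab$fdr <- NA_real_
    cbind(run_id = r, tab, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out), class = c("fdr_cube", "data.frame"),
            fft = p$fft)
}

#' m-score threshold achieving a target FDR
#'
#' Searches the threshold grid for the largest (most permissive) cutoff
#' whose estimated FDR at the requested level is at or below `target_fdr`,
#' and reports the achieved FDR alongside (the search is resolution-limited
#' by the grid).
#'
#' @param t a `peakgroup_table`.
#' @param level `"assay"`, `"peptide"` or `"protein"`.
#' @param target_fdr target FDR in (0, 1).
#' @param p an `fdr_parameters` object.
#' @return the selected threshold (class `mscore_threshold`) with attributes
#'   `achieved_fdr`, `level`, `target_fdr`.
#' @export
mscore_for_fdr <- function(t, level = c("assay", "peptide", "protein"),
                           target_fdr, p = fdr_parameters()) {
  level <- match.arg(level)
  stopifnot(is.numeric(target_fdr), length(target_fdr) == 1L,
            target_fdr > 0, target_fdr < 1)
  ft <- estimate_fdr_overall(t, p)
  ft <- ft[ft$level == level, , drop = FALSE]
  ok <- is.finite(ft$fdr) & ft$fdr <= target_fdr
  if (!any(ok)) {
    stop("no m-score threshold on the grid achieves ", level, " FDR <= ",
         target_fdr, "; use a finer/lower grid or stricter upstream scoring")
  }
  i <- which(ok)[which.max(ft$mscore_cutoff[ok])]
  message(sprintf("mscore_for_fdr: threshold %.4g achieves %s FDR %.4g (target %.4g)",
                  ft$mscore_cutoff[i], level, ft$fdr[i], target_fdr))
  structure(ft$mscore_cutoff[i], achieved_fdr = ft$fdr[i], level = level,
            target_fdr = target_fdr, class = "mscore_threshold")
}

#' @export
print.mscore_threshold <- function(x, ...) {
  cat(sprintf("m-score threshold %.6g (%s FDR achieved %.4g, target %.4g)\n",
              unclass(x), attr(x, "level"), attr(x, "achieved_fdr"),
              attr(x, "target_fdr")))
  invisible(x)
}

#' Write an FDR table or cube as tidy TSV
#'
#' @param x an `fdr_table` or `fdr_cube`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fdr_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     na = "", row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.fdr_table <- function(x, ...) {
  cat("fdr_table (fft = ", attr(x, "fft"), "), ",
      length(unique(x$mscore_cutoff)), " thresholds\n", sep = "")
  for (lev in unique(x$level)) {
    sub <- x[x$level == lev & is.finite(x$fdr), , drop = FALSE]
    if (!nrow(sub)) next
    i <- which.max(sub$mscore_cutoff)
    cat(sprintf("  %-8s at m-score %.3g: %d targets, %d decoys, FDR %.4g\n",
                lev, sub$mscore_cutoff[i], sub$targets[i], sub$decoys[i],
                sub$fdr[i]))
  }
  invisible(x)
}

#' Plot estimated FDR against the m-score threshold
#'
#' One line per level (global table) or per run and level (cube).
#'
#' @param x an `fdr_table` or `fdr_cube`.
#' @param level for cubes, which level to plot (default `"assay"`).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.fdr_table <- function(x, ...) {
  th <- sort(unique(x$mscore_cutoff), decreasing = TRUE)
  levs <- unique(x$level)
  m <- sapply(levs, function(l) {
    sub <- x[x$level == l, , drop = FALSE]
    sub$fdr[match(th, sub$mscore_cutoff)]
  })
  graphics::matplot(log10(th), m, type = "l", lty = 1,
                    xlab = "log10 m-score threshold", ylab = "estimated FDR",
                    ...)
  graphics::legend("topleft", legend = levs, lty = 1,
                   col = seq_along(levs), bty = "n")
  invisible(x)
}

#' @rdname plot.fdr_table
#' @export
plot.fdr_cube <- function(x, level = "assay", ...) {
  sub <- x[x$level == level, , drop = FALSE]
  th <- sort(unique(sub$mscore_cutoff), decreasing = TRUE)
  runs <- unique(sub$run_id)
  m <- sapply(runs, function(r) {
    s <- sub[sub$run_id == r, , drop = FALSE]
    s$fdr[match(th, s$mscore_cutoff)]
  })
  graphics::matplot(log10(th), m, type = "l", lty = 1,
                    xlab = "log10 m-score threshold",
                    ylab = paste("estimated", level, "FDR"), ...)
  graphics::legend("topleft", legend = runs, lty = 1,
                   col = seq_along(runs), bty = "n")
  invisible(x)
}
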