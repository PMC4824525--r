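# Replicate quality control: analyte counts, inter-run correlation,
# coefficients of variation and summed-signal matrices.  Decoys are excluded
# from every QC output: QC describes the measured targets.

.targets <- function(t) t[!t$decoy, , drop = FALSE]

#' Count analytes per run
#'
#' For each run, the number of distinct target precursors
#' (modified peptide x charge), distinct target peptides and distinct target
#' proteins.
#'
#' @param t a `peakgroup_table`.
#' @return data frame with columns `run_id`, `precursors`, `peptides`,
#'   `proteins`, one row per run.
#' @export
count_analytes <- function(t) {
  stopifnot(inherits(t, "peakgroup_table"), nrow(t) > 0)
  runs <- unique(t$run_id)
  tg <- .targets(t)
  marker <- .decoy_marker(t)
  out <- lapply(runs, function(r) {
    x <- tg[tg$run_id == r, , drop = FALSE]
    data.frame(
      run_id = r,
      precursors = length(unique(paste(x$peptide_sequence_mod,
                                       x$precursor_charge))),
      peptides = length(unique(x$peptide_sequence_mod)),
      proteins = length(unique(.protein_key(x$protein_name, marker))),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

# assay x run intensity matrix (targets only), NA for unobserved cells
.assay_matrix <- function(t) {
  tg <- .targets(t)
  runs <- unique(t$run_id)
  key <- paste(tg$peptide_sequence_mod, tg$precursor_charge, sep = "/")
  analytes <- unique(key)
  m <- matrix(NA_real_, length(analytes), length(runs),
              dimnames = list(analytes, runs))
  m[cbind(match(key, analytes), match(tg$run_id, runs))] <- tg$intensity
  m
}

#' Pairwise correlation of analyte intensities between runs
#'
#' Intensities are matched on (modified peptide, charge) across runs and
#' correlated pairwise-complete.  The default is Pearson correlation of
#' log2 intensities (non-positive and missing values dropped pairwise);
#' Spearman on raw intensities is available for nonlinear but monotone
#' distortions.  Run pairs sharing fewer than 3 analytes are flagged
#' undefined (`NA`).
#'
#' @param t a `peakgroup_table` with at least 2 runs.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param transform `"log2"` (default) or `"none"`.
#' @return symmetric run x run correlation matrix with unit diagonal.
#' @export
correlation_between_samples <- function(t,
                                        method = c("pearson", "spearman"),
                                        transform = c("log2", "none")) {
  stopifnot(inherits(t, "peakgroup_table"))
  method <- match.arg(method)
  transform <- match.arg(transform)
  m <- .assay_matrix(t)
  if (ncol(m) < 2L) stop("correlation requires at least 2 runs")
  if (transform == "log2") {
    m[!is.na(m) & m <= 0] <- NA_real_
    m <- log2(m)
  }
  cc <- stats::cor(m, use = "pairwise.complete.obs", method = method)
  shared <- crossprod(!is.na(m))
  cc[shared < 3L] <- NA_real_
  diag(cc) <- 1
  cc
}

#' Summed-signal matrix per peptide or protein
#'
#' Wide analyte x run matrix of target intensities.  The peptide level sums
#' intensity over charge states per (modified peptide, run); the protein
#' level sums over all the protein's peptides per run.  Unobserved cells are
#' `NA` (written as empty cells by [write_signal_matrix()]).
#'
#' @param t a `peakgroup_table`.
#' @param level `"peptide"` or `"protein"`.
#' @return numeric matrix with analyte row names and run column names.
#' @export
signal_matrix <- function(t, level = c("peptide", "protein")) {
  stopifnot(inherits(t, "peakgroup_table"))
  level <- match.arg(level)
  tg <- .targets(t)
  runs <- unique(t$run_id)
  key <- if (level == "peptide") {
    tg$peptide_sequence_mod
  } else {
    .protein_key(tg$protein_name, .decoy_marker(t))
  }
  analytes <- unique(key)
  m <- matrix(NA_real_, length(analytes), length(runs),
              dimnames = list(analytes, runs))
  if (nrow(tg)) {
    s <- rowsum(tg$intensity,
                group = paste(match(key, analytes), match(tg$run_id, runs)))
    ij <- do.call(rbind, lapply(strsplit(rownames(s), " ", fixed = TRUE),
                                as.integer))
    m[ij] <- s[, 1L]
  }
  m
}

#' Write a signal matrix as TSV
#'
#' @param m matrix from [signal_matrix()].
#' @param path output path.
#' @param label name of the row-label column, default `"analyte"`.
#' @return `path`, invisibly.
#' @export
write_signal_matrix <- function(m, path, label = "analyte") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- label
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

.cv <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / mean(x)
}

#' Coefficients of variation within replicates and across all samples
#'
#' For each analyte (peptide or protein, via [signal_matrix()]), the CV
#' (sample standard deviation / mean, raw intensity scale) is computed
#' within each condition's replicates and across all samples ("total"
#' scope).  Analytes with fewer than 2 finite observations in a scope are
#' excluded; conditions with a single replicate are excluded from the
#' within-replicate scope with a warning.
#'
#' @param t an annotated `peakgroup_table`.
#' @param level `"peptide"` or `"protein"`.
#' @return data frame of class `cv_table` with columns `level`, `scope`
#'   (`"within-replicates"`/`"total"`), `group` (condition or `"all"`),
#'   `analyte`, `cv`.
#' @export
cv_table <- function(t, level = c("peptide", "protein")) {
  stopifnot(inherits(t, "peakgroup_table"))
  level <- match.arg(level)
  if (!all(c("condition", "bio_replicate") %in% names(t))) {
    stop("cv_table needs an annotated table; run annotate_samples() first")
  }
  m <- signal_matrix(t, level)
  run_cond <- unique(data.frame(run_id = t$run_id, condition = t$condition,
                                stringsAsFactors = FALSE))
  cond_of <- run_cond$condition[match(colnames(m), run_cond$run_id)]

  one_scope <- function(cols, scope, group) {
    cv <- apply(m[, cols, drop = FALSE], 1L, .cv)
    keep <- is.finite(cv)
    if (!any(keep)) return(NULL)
    data.frame(level = level, scope = scope, group = group,
               analyte = rownames(m)[keep], cv = unname(cv[keep]),
               stringsAsFactors = FALSE)
  }

  pieces <- list()
  for (cond in unique(cond_of)) {
    cols <- which(cond_of == cond)
    if (length(cols) < 2L) {
      warning("condition '", cond, "' has a single replicate; ",
              "excluded from within-replicate CV")
      next
    }
    pieces[[length(pieces) + 1L]] <-
      one_scope(cols, "within-replicates", cond)
  }
  pieces[[length(pieces) + 1L]] <- one_scope(seq_len(ncol(m)), "total", "all")
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("cv_table", "data.frame")
  out
}

#' Boxplot of CVs per scope/group
#'
#' @param x a `cv_table`.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.cv_table <- function(x, ...) {
  grp <- factor(paste(x$scope, x$group, sep = ": "))
  graphics::boxplot(x$cv ~ grp, xlab = "", ylab = "coefficient of variation",
                    las = 2, ...)
  invisible(x)
}

#' Heatmap of the between-sample correlation matrix
#'
#' @param m matrix from [correlation_between_samples()].
#' @param ... passed to [graphics::image()].
#' @export
plot_correlation <- function(m, ...) {
  n <- ncol(m)
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                  axes = FALSE, xlab = "", ylab = "", ...)
  graphics::axis(1, at = seq_len(n), labels = colnames(m), las = 2)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(m)), las = 2)
  invisible(m)
}
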