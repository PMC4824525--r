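# Filter suite.  Every predicate is blind to the decoy flag, so target and
# decoy rows are treated identically and the decoy-estimated FDR remains
# interpretable after filtering.  All filters preserve row order and attach
# a removal report (rows and assay units before/after) as the
# "filter_report" attribute.

.assay_key <- function(t) {
  paste(t$peptide_sequence_mod, t$precursor_charge, sep = "/")
}

.filter_result <- function(t_new, t_old, filter) {
  report <- list(
    filter = filter,
    rows_before = nrow(t_old), rows_after = nrow(t_new),
    assays_before = length(unique(.assay_key(t_old))),
    assays_after = length(unique(.assay_key(t_new)))
  )
  message(sprintf("%s: kept %d of %d rows (%d of %d assays)",
                  filter, report$rows_after, report$rows_before,
                  report$assays_after, report$assays_before))
  rownames(t_new) <- NULL
  structure(t_new,
            class = class(t_old),
            decoy_marker = attr(t_old, "decoy_marker"),
            n_unscored = sum(!is.finite(t_new$m_score)),
            filter_report = report)
}

#' Removal report of the last filter applied
#'
#' @param t a filtered `peakgroup_table`.
#' @return list with `filter`, `rows_before`, `rows_after`, `assays_before`,
#'   `assays_after`, or `NULL` when `t` has not been filtered.
#' @export
filter_report <- function(t) attr(t, "filter_report")

#' Filter rows by m-score
#'
#' Keeps rows whose m-score is at or below `cutoff`.  Rows without a usable
#' m-score are removed (they cannot satisfy a score criterion); their count
#' is part of the removal report.
#'
#' @param t a `peakgroup_table`.
#' @param cutoff m-score threshold in (0, 1].
#' @return filtered `peakgroup_table`.
#' @export
filter_mscore <- function(t, cutoff) {
  stopifnot(inherits(t, "peakgroup_table"),
            is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0, cutoff <= 1)
  keep <- .scored(t) & t$m_score <= cutoff
  out <- t[keep, , drop = FALSE]
  if (!nrow(out)) warning("filter_mscore: no row passes cutoff ", cutoff)
  .filter_result(out, t, "filter_mscore")
}

# run sets in which each assay passes the cutoff
.passing_runs_by_assay <- function(t, cutoff) {
  pass <- .scored(t) & t$m_score <= cutoff
  split(t$run_id[pass], .assay_key(t)[pass])
}

#' Filter assays by frequency of observation across runs
#'
#' Keeps every row (including sub-threshold ones in other runs) of assays
#' that pass `cutoff` in at least `min_fraction` of all runs; assays are
#' kept or dropped wholesale, so downstream tools can still impute or weight
#' across runs.
#'
#' @param t an annotated `peakgroup_table`.
#' @param cutoff m-score threshold.
#' @param min_fraction required fraction of runs, in (0, 1].
#' @return filtered `peakgroup_table`.
#' @export
filter_mscore_freqobs <- function(t, cutoff, min_fraction) {
  stopifnot(inherits(t, "peakgroup_table"),
            is.numeric(min_fraction), length(min_fraction) == 1L,
            min_fraction > 0, min_fraction <= 1)
  n_runs <- length(unique(t$run_id))
  pr <- .passing_runs_by_assay(t, cutoff)
  n_pass <- vapply(pr, function(r) length(unique(r)), 0L)
  keep_keys <- names(n_pass)[n_pass / n_runs >= min_fraction]
  out <- t[.assay_key(t) %in% keep_keys, , drop = FALSE]
  .filter_result(out, t, "filter_mscore_freqobs")
}

#' Filter assays by replicate observations within conditions
#'
#' Keeps assays that pass `cutoff` in at least `min_obs` distinct biological
#' replicates of at least one condition (`mode = "any"`, default) or of
#' every condition (`mode = "every"`).  Assays are kept wholesale (all their
#' rows, including sub-threshold ones).
#'
#' @param t an annotated `peakgroup_table`.
#' @param cutoff m-score threshold.
#' @param min_obs required number of replicate observations (positive
#'   integer).
#' @param mode `"any"` or `"every"`.
#' @return filtered `peakgroup_table`.
#' @export
filter_mscore_condition <- function(t, cutoff, min_obs,
                                    mode = c("any", "every")) {
  stopifnot(inherits(t, "peakgroup_table"),
            is.numeric(min_obs), length(min_obs) == 1L, min_obs >= 1)
  mode <- match.arg(mode)
  if (!all(c("condition", "bio_replicate") %in% names(t))) {
    stop("filter_mscore_condition needs an annotated table; ",
         "run annotate_samples() first")
  }
  conds <- unique(t$condition)
  max_reps <- max(vapply(conds, function(cn)
    length(unique(t$bio_replicate[t$condition == cn])), 0L))
  if (min_obs > max_reps) {
    warning("min_obs (", min_obs, ") exceeds the largest condition size (",
            max_reps, "); no assay can pass")
  }

  pass <- .scored(t) & t$m_score <= cutoff
  key <- .assay_key(t)
  # distinct replicates per (assay, condition) among passing rows
  pk <- paste(key[pass], t$condition[pass], sep = "\r")
  reps <- split(t$bio_replicate[pass], pk)
  n_rep <- vapply(reps, function(r) length(unique(r)), 0L)
  pk_assay <- sub("\r.*$", "", names(n_rep))
  ok <- n_rep >= min_obs
  keep_keys <- if (mode == "any") {
    unique(pk_assay[ok])
  } else {
    cnt <- table(pk_assay[ok])
    names(cnt)[cnt == length(conds)]
  }
  out <- t[key %in% keep_keys, , drop = FALSE]
  .filter_result(out, t, "filter_mscore_condition")
}

#' Keep only proteotypic peptides
#'
#' Retains rows whose peptide maps to exactly one protein (multiplicity
#' prefix `"1/"` or no prefix when prefixes are in use) and strips the
#' `"1/"` prefix from the retained protein names.  Decoy status is
#' irrelevant to the rule.  When the table carries no multiplicity prefixes
#' at all, proteotypicity is unknown and the table is returned unchanged
#' with a warning.
#'
#' @param t a `peakgroup_table`.
#' @return filtered `peakgroup_table` with cleaned protein names.
#' @export
filter_proteotypic <- function(t) {
  stopifnot(inherits(t, "peakgroup_table"))
  marker <- .decoy_marker(t)
  p <- parse_protein_name(t$protein_name, marker)
  if (nrow(t) && !any(p$has_prefix)) {
    warning("no multiplicity prefixes present; proteotypicity unknown, ",
            "table returned unchanged")
    return(.filter_result(t, t, "filter_proteotypic"))
  }
  keep <- p$multiplicity == 1L
  out <- t[keep, , drop = FALSE]
  pk <- p[keep, , drop = FALSE]
  out$protein_name <- ifelse(pk$is_decoy_name,
                             paste0(marker, pk$accessions), pk$accessions)
  message("filter_proteotypic: ", sum(keep), " proteotypic vs ",
          sum(!keep), " shared-peptide rows")
  .filter_result(out, t, "filter_proteotypic")
}

# summed intensity per (protein group, peptide), all runs pooled
.peptide_totals <- function(t) {
  grp <- .protein_group(t$protein_name, .decoy_marker(t))
  key <- paste(grp, t$peptide_sequence_mod, sep = "\r")
  tot <- rowsum(t$intensity, key)
  parts <- strsplit(rownames(tot), "\r", fixed = TRUE)
  data.frame(protein = vapply(parts, `[`, "", 1L),
             peptide = vapply(parts, `[`, "", 2L),
             total = tot[, 1L], stringsAsFactors = FALSE)
}

#' Keep the n most intense peptides per protein
#'
#' Peptides are ranked within each protein by their intensity summed over
#' all runs (ties broken by lexicographic peptide sequence); rows of the top
#' `n` peptides are kept.
#'
#' @param t a `peakgroup_table`.
#' @param n number of peptides to keep per protein (>= 1).
#' @return filtered `peakgroup_table`.
#' @export
filter_on_max_peptides <- function(t, n) {
  stopifnot(inherits(t, "peakgroup_table"),
            is.numeric(n), length(n) == 1L, n >= 1)
  pt <- .peptide_totals(t)
  pt <- pt[order(pt$protein, -pt$total, pt$peptide, method = "radix"), ]
  rank <- stats::ave(seq_len(nrow(pt)), pt$protein, FUN = seq_along)
  keep_pairs <- paste(pt$protein, pt$peptide, sep = "\r")[rank <= n]
  grp <- .protein_group(t$protein_name, .decoy_marker(t))
  keep <- paste(grp, t$peptide_sequence_mod, sep = "\r") %in% keep_pairs
  .filter_result(t[keep, , drop = FALSE], t, "filter_on_max_peptides")
}

#' Keep proteins with at least n quantified peptides
#'
#' @param t a `peakgroup_table`.
#' @param n minimum number of distinct peptides per protein (>= 1).
#' @return filtered `peakgroup_table`.
#' @export
filter_on_min_peptides <- function(t, n) {
  stopifnot(inherits(t, "peakgroup_table"),
            is.numeric(n), length(n) == 1L, n >= 1)
  grp <- .protein_group(t$protein_name, .decoy_marker(t))
  pep_count <- vapply(split(t$peptide_sequence_mod, grp),
                      function(p) length(unique(p)), 0L)
  keep_prot <- names(pep_count)[pep_count >= n]
  .filter_result(t[grp %in% keep_prot, , drop = FALSE], t,
                 "filter_on_min_peptides")
}
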