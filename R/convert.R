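# Disaggregation of peakgroups to transition level and converters to the
# MSstats, mapDIA and aLFQ input schemas.  Decoy rows are excluded from all
# converter outputs by default: downstream statistics assume targets, while
# decoys belong to FDR estimation.

#' Disaggregate peakgroups to transition level
#'
#' Splits the `";"`-joined `aggr_fragment_annotation` / `aggr_peak_area`
#' fields into one row per transition, copying all identification and
#' annotation fields and retaining the peakgroup intensity as a pass-through
#' column.  Token order is preserved, so re-aggregation ([re_aggregate()])
#' reproduces the original aggregated strings byte-for-byte.  The table is
#' processed in chunks, keeping memory proportional to the chunk size.
#'
#' @param t a `peakgroup_table` with cardinality-consistent aggregated
#'   fields on every row.
#' @param chunk_size rows of `t` processed per chunk.
#' @return a `transition_table` (data frame with the peakgroup fields plus
#'   `fragment_ion` and `transition_intensity`).
#' @export
disaggregate <- function(t, chunk_size = 50000L) {
  stopifnot(inherits(t, "peakgroup_table"))
  need <- c("aggr_fragment_annotation", "aggr_peak_area")
  miss <- setdiff(need, names(t))
  if (length(miss)) {
    stop("disaggregate needs aggregated transition fields: ",
         paste(miss, collapse = ", "))
  }
  empty <- which(is.na(t$aggr_fragment_annotation) |
                 !nzchar(t$aggr_fragment_annotation) |
                 is.na(t$aggr_peak_area) | !nzchar(t$aggr_peak_area))
  if (length(empty)) {
    stop("empty aggregated transition field at row(s): ",
         paste(utils::head(empty, 5L), collapse = ", "))
  }

  base_cols <- setdiff(names(t), need)
  chunks <- split(seq_len(nrow(t)),
                  (seq_len(nrow(t)) - 1L) %/% as.integer(chunk_size))
  pieces <- lapply(chunks, function(idx) {
    ann <- strsplit(t$aggr_fragment_annotation[idx], ";", fixed = TRUE)
    area <- strsplit(t$aggr_peak_area[idx], ";", fixed = TRUE)
    n_a <- lengths(ann)
    n_b <- lengths(area)
    if (any(n_a != n_b)) {
      stop("transition annotation/area cardinality mismatch at row(s): ",
           paste(utils::head(idx[n_a != n_b], 5L), collapse = ", "))
    }
    out <- as.data.frame(t)[rep(idx, n_a), base_cols, drop = FALSE]
    out$fragment_ion <- unlist(ann, use.names = FALSE)
    out$transition_intensity <- as.numeric(unlist(area, use.names = FALSE))
    out
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL

  tk <- paste(out$fragment_ion, out$peptide_sequence_mod,
              out$precursor_charge, out$run_id, sep = "\r")
  if (anyDuplicated(tk)) {
    stop("duplicate (fragment, peptide, charge, run) after disaggregation ",
         "at transition row(s): ",
         paste(utils::head(which(duplicated(tk)), 5L), collapse = ", "))
  }
  structure(out, class = c("transition_table", "data.frame"),
            decoy_marker = .decoy_marker(t))
}

#' Re-aggregate a transition table into peakgroup rows
#'
#' Inverse of [disaggregate()]: joins transitions back into the `";"`-joined
#' aggregated fields per (modified peptide, charge, injection), in row
#' order.  Transition intensities are re-formatted with the same
#' shortest-round-trip representation used when writing tables, so
#' disaggregate-then-re-aggregate is byte-identical for tables written by
#' this package.
#'
#' @param tt a `transition_table`.
#' @return a `peakgroup_table`.
#' @export
re_aggregate <- function(tt) {
  stopifnot(inherits(tt, "transition_table"))
  key <- paste(tt$peptide_sequence_mod, tt$precursor_charge, tt$filename,
               sep = "\r")
  idx <- split(seq_len(nrow(tt)), factor(key, levels = unique(key)))
  first <- vapply(idx, `[`, 0L, 1L)
  keep <- setdiff(names(tt), c("fragment_ion", "transition_intensity"))
  out <- as.data.frame(tt)[first, keep, drop = FALSE]
  out$aggr_fragment_annotation <-
    vapply(idx, function(i) paste(tt$fragment_ion[i], collapse = ";"), "")
  out$aggr_peak_area <-
    vapply(idx, function(i)
      paste(.fmt_shortest(tt$transition_intensity[i]), collapse = ";"), "")
  rownames(out) <- NULL
  suppressMessages(as_peakgroup_table(out, .decoy_marker(tt)))
}

.require_annotated <- function(tt, fun) {
  if (!all(c("condition", "bio_replicate", "run_id") %in% names(tt))) {
    stop(fun, " needs an annotated table; run annotate_samples() before ",
         "disaggregating")
  }
}

.drop_decoys <- function(tt, keep_decoys) {
  if (keep_decoys) tt else tt[!tt$decoy, , drop = FALSE]
}

#' Convert to the MSstats input format
#'
#' Emits exactly the columns `ProteinName`, `PeptideSequence`,
#' `PrecursorCharge`, `FragmentIon`, `ProductCharge`, `IsotopeLabelType`,
#' `Condition`, `BioReplicate`, `Run`, `Intensity` (in this order), one row
#' per transition.  `IsotopeLabelType` is the constant `"L"`;
#' `ProductCharge` is parsed from the fragment annotation with
#' `product_charge_pattern` when encoded there, else left empty.
#'
#' @param tt an annotated `transition_table`.
#' @param keep_decoys retain decoy rows (default drops them).
#' @param product_charge_pattern regex with one capture group extracting the
#'   product charge from the fragment annotation.
#' @return data frame in MSstats format.
#' @export
to_msstats <- function(tt, keep_decoys = FALSE,
                       product_charge_pattern = "_([0-9]+)$") {
  stopifnot(inherits(tt, "transition_table"))
  .require_annotated(tt, "to_msstats")
  tt <- .drop_decoys(tt, keep_decoys)
  has <- grepl(product_charge_pattern, tt$fragment_ion)
  pc <- rep(NA_integer_, nrow(tt))
  pc[has] <- as.integer(sub(paste0("^.*", product_charge_pattern), "\\1",
                            tt$fragment_ion[has]))
  data.frame(
    ProteinName = tt$protein_name,
    PeptideSequence = tt$peptide_sequence_mod,
    PrecursorCharge = tt$precursor_charge,
    FragmentIon = tt$fragment_ion,
    ProductCharge = pc,
    IsotopeLabelType = "L",
    Condition = tt$condition,
    BioReplicate = tt$bio_replicate,
    Run = tt$run_id,
    Intensity = tt$transition_intensity,
    stringsAsFactors = FALSE
  )
}

#' Convert to the mapDIA input format (wide)
#'
#' Reshapes the transition table from long to wide: columns `ProteinName`,
#' `PeptideSequence`, `FragmentIon`, then one intensity column per sample
#' ordered by (condition, biological replicate), and optionally a terminal
#' `RT` column (mean retention time of the fragment over samples).  Missing
#' observations are written as `0`, which mapDIA's numeric parser expects.
#'
#' @param tt an annotated `transition_table`.
#' @param design optional design data frame fixing the sample order;
#'   defaults to the (condition, replicate, run) triples present in `tt`.
#' @param rt append the `RT` column.
#' @param keep_decoys retain decoy rows.
#' @return wide data frame in mapDIA format.
#' @export
to_mapdia <- function(tt, design = NULL, rt = FALSE, keep_decoys = FALSE) {
  stopifnot(inherits(tt, "transition_table"))
  .require_annotated(tt, "to_mapdia")
  tt <- .drop_decoys(tt, keep_decoys)

  if (is.null(design)) {
    samples <- unique(data.frame(run = tt$run_id, condition = tt$condition,
                                 bio_replicate = tt$bio_replicate,
                                 stringsAsFactors = FALSE))
  } else {
    design <- .validate_design(design)
    samples <- design[design$run %in% tt$run_id,
                      c("run", "condition", "bio_replicate")]
  }
  samples <- samples[order(samples$condition, samples$bio_replicate,
                           samples$run, method = "radix"), , drop = FALSE]
  sample_label <- paste(samples$condition, samples$bio_replicate, sep = "_")
  if (anyDuplicated(sample_label)) {
    sample_label <- paste(sample_label, samples$run, sep = "_")
  }

  row_key <- paste(tt$protein_name, tt$peptide_sequence_mod,
                   tt$fragment_ion, sep = "\r")
  keys <- unique(row_key)
  ci <- match(tt$run_id, samples$run)
  ri <- match(row_key, keys)
  cell <- paste(ri, ci)
  if (anyDuplicated(cell)) {
    d <- which(duplicated(cell))[1L]
    stop("ambiguous cell: duplicate (protein, peptide, fragment, sample) ",
         "at transition row ", d)
  }
  m <- matrix(0, length(keys), nrow(samples))
  m[cbind(ri, ci)] <- tt$transition_intensity

  first <- match(keys, row_key)
  out <- data.frame(
    ProteinName = tt$protein_name[first],
    PeptideSequence = tt$peptide_sequence_mod[first],
    FragmentIon = tt$fragment_ion[first],
    stringsAsFactors = FALSE
  )
  wide <- as.data.frame(m)
  names(wide) <- sample_label
  out <- cbind(out, wide)
  if (rt) {
    if (!"rt" %in% names(tt)) stop("rt requested but no rt field present")
    out$RT <- as.numeric(tapply(tt$rt, factor(ri, seq_along(keys)),
                                function(x) mean(x, na.rm = TRUE)))
  }
  out
}

#' Convert to the aLFQ input format
#'
#' Emits the columns `run_id`, `protein_id`, `peptide_id`, `transition_id`,
#' `peptide_intensity`, `transition_intensity`, `concentration`.  The
#' peptide identifier joins the modified sequence and precursor charge; the
#' peptide intensity is the source peakgroup intensity (constant within a
#' (run, peptide) group).  Concentrations default to the placeholder `"?"`
#' unless a named map per protein is supplied.
#'
#' @param tt an annotated `transition_table`.
#' @param concentration optional named vector/list mapping protein
#'   identifiers to known concentrations.
#' @param keep_decoys retain decoy rows.
#' @return data frame in aLFQ format.
#' @export
to_alfq <- function(tt, concentration = NULL, keep_decoys = FALSE) {
  stopifnot(inherits(tt, "transition_table"))
  .require_annotated(tt, "to_alfq")
  tt <- .drop_decoys(tt, keep_decoys)
  prot <- .protein_group(tt$protein_name, .decoy_marker(tt))
  pep <- paste(tt$peptide_sequence_mod, tt$precursor_charge, sep = "_")
  conc <- rep("?", nrow(tt))
  if (!is.null(concentration)) {
    hit <- match(prot, names(concentration))
    conc[!is.na(hit)] <- as.character(unlist(concentration)[hit[!is.na(hit)]])
  }
  data.frame(
    run_id = tt$run_id,
    protein_id = prot,
    peptide_id = pep,
    transition_id = paste(pep, tt$fragment_ion, sep = "_"),
    peptide_intensity = tt$intensity,
    transition_intensity = tt$transition_intensity,
    concentration = conc,
    stringsAsFactors = FALSE
  )
}

#' Write a converter output as TSV
#'
#' Tab-separated, unquoted, `NA` written as empty — the header line is
#' byte-exact as required by the downstream tools.
#'
#' @param df output of [to_msstats()], [to_mapdia()] or [to_alfq()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_converted <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
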