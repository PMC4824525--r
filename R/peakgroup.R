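#' swathtools: processing of SWATH-MS/DIA peakgroup tables
#'
#' Reads OpenSWATH-style long-format peakgroup tables, annotates them with a
#' study design, computes replicate QC metrics, estimates decoy-based FDR with
#' the FFT (pi0) correction, filters the data, and converts it to the input
#' formats of MSstats, mapDIA and aLFQ.
#'
#' @keywords internal
"_PACKAGE"

# Canonical field set.  Every downstream operation works on these names; the
# on-disk header vocabulary is the OpenSWATH one (see .pg_header_map).
.pg_fields <- c(
  "protein_name", "peptide_sequence_mod", "peptide_sequence_stripped",
  "precursor_charge", "filename", "run_id", "intensity", "m_score", "decoy",
  "rt", "aggr_fragment_annotation", "aggr_peak_area",
  "condition", "bio_replicate"
)

# canonical field -> on-disk (OpenSWATH-vocabulary) header
.pg_header_map <- c(
  protein_name             = "ProteinName",
  peptide_sequence_mod     = "FullPeptideName",
  peptide_sequence_stripped = "Sequence",
  precursor_charge         = "Charge",
  filename                 = "filename",
  run_id                   = "run_id",
  intensity                = "Intensity",
  m_score                  = "m_score",
  decoy                    = "decoy",
  rt                       = "RT",
  aggr_fragment_annotation = "aggr_Fragment_Annotation",
  aggr_peak_area           = "aggr_Peak_Area",
  condition                = "Condition",
  bio_replicate            = "BioReplicate"
)

# the four minimal fields, keyed by the role name used in error messages
.pg_minimal <- c(
  protein   = "protein_name",
  injection = "filename",
  signal    = "intensity",
  score     = "m_score"
)

#' Built-in column dialects
#'
#' A dialect maps source header names to the canonical field names used by
#' all swathtools operations.  The built-in `"openswath"` dialect covers the
#' headers of an OpenSWATH export (`ProteinName`, `FullPeptideName`,
#' `Charge`, `filename`, `Intensity`, `m_score`, `decoy`,
#' `aggr_Fragment_Annotation`, `aggr_Peak_Area`, ...).
#'
#' @param name dialect name; currently only `"openswath"`.
#' @return named character vector: names are source headers, values canonical
#'   field names.
#' @export
pg_dialect <- function(name = "openswath") {
  name <- match.arg(name)
  m <- names(.pg_header_map)
  names(m) <- unname(.pg_header_map)
  m
}

#' Read a column dialect from a file
#'
#' Accepts either a YAML file (`.yml`/`.yaml`) or a plain `key=value` file,
#' one `source_header=canonical_field` pair per line (`#` comments allowed).
#'
#' @param path file path.
#' @return named character vector usable as the `dialect`/`mapping` argument
#'   of [read_peakgroup_table()] and [import_peakgroups()].
#' @export
read_dialect <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    x <- yaml::read_yaml(path)
    out <- vapply(x, as.character, "")
    return(out)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("malformed dialect line(s): ", paste(lines[bad], collapse = "; "))
  }
  out <- trimws(vapply(parts, `[`, "", 2L))
  names(out) <- trimws(vapply(parts, `[`, "", 1L))
  out
}

# shortest decimal representation that round-trips the double exactly
.fmt_shortest <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    if (is.finite(v) && v == trunc(v) && abs(v) < 1e15) {
      return(sprintf("%.0f", v))
    }
    for (d in c(15L, 16L, 17L)) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    s
  }, character(1))
}

.coerce_decoy <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "t", "yes")] <- TRUE
  out[x %in% c("0", "false", "f", "no")] <- FALSE
  out
}

#' Construct and validate a peakgroup table
#'
#' Validates a data frame already using canonical field names and returns a
#' `peakgroup_table`.  The decoy flag is taken from an explicit `decoy`
#' column when present, otherwise inferred from the protein-name marker.
#' Rows whose m-score is non-finite or outside (0, 1] are retained (they can
#' still be converted) but flagged unusable for FDR estimation and score
#' filters; the count is reported.
#'
#' @param df data frame with canonical field names (see [pg_dialect()] for
#'   the mapping from OpenSWATH headers).
#' @param decoy_marker substring of `protein_name` marking decoy entries.
#' @return a `peakgroup_table` (a `data.frame` subclass).
#' @export
as_peakgroup_table <- function(df, decoy_marker = "DECOY_") {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)

  missing_min <- .pg_minimal[!(.pg_minimal %in% names(df))]
  if (length(missing_min)) {
    stop("missing required field(s): ",
         paste(sprintf("%s (%s)", names(missing_min), missing_min),
               collapse = ", "))
  }

  df$protein_name <- as.character(df$protein_name)
  df$filename <- as.character(df$filename)
  if (!"run_id" %in% names(df) || all(is.na(df$run_id))) {
    df$run_id <- df$filename
  } else {
    df$run_id <- as.character(df$run_id)
  }
  if ("precursor_charge" %in% names(df)) {
    df$precursor_charge <- as.integer(df$precursor_charge)
  }
  df$intensity <- as.numeric(df$intensity)

  if (nrow(df)) {
    neg <- which(is.finite(df$intensity) & df$intensity < 0)
    if (length(neg)) {
      stop("negative intensity at row(s): ",
           paste(utils::head(neg, 5L), collapse = ", "))
    }
  }

  # decoy: explicit column takes precedence over the name marker
  marker_hit <- grepl(decoy_marker, df$protein_name, fixed = TRUE)
  if ("decoy" %in% names(df) && !all(is.na(df$decoy))) {
    df$decoy <- .coerce_decoy(df$decoy)
    if (anyNA(df$decoy)) {
      stop("decoy flag not interpretable at row(s): ",
           paste(utils::head(which(is.na(df$decoy)), 5L), collapse = ", "))
    }
    mism <- which(df$decoy != marker_hit)
    if (length(mism)) {
      stop("decoy flag disagrees with protein-name marker '", decoy_marker,
           "' at row(s): ", paste(utils::head(mism, 5L), collapse = ", "))
    }
  } else {
    df$decoy <- marker_hit
  }

  # m-score: sentinel / out-of-range scores are kept but flagged unusable
  ms <- suppressWarnings(as.numeric(df$m_score))
  bad <- !is.finite(ms) | ms <= 0 | ms > 1
  ms[bad] <- NA_real_
  df$m_score <- ms
  n_unscored <- sum(bad)
  if (n_unscored > 0) {
    message("as_peakgroup_table: ", n_unscored,
            " row(s) carry a missing/out-of-range m-score; they are excluded",
            " from FDR estimation and score filters")
  }

  if ("rt" %in% names(df)) df$rt <- as.numeric(df$rt)

  # one row per (modified peptide, charge, injection)
  if (all(c("peptide_sequence_mod", "precursor_charge") %in% names(df)) &&
      nrow(df)) {
    key <- paste(df$peptide_sequence_mod, df$precursor_charge, df$filename,
                 sep = "\r")
    dup <- which(duplicated(key))
    if (length(dup)) {
      stop("duplicate (peptide, charge, injection) at row(s): ",
           paste(utils::head(dup, 5L), collapse = ", "))
    }
  }

  # aggregated transition fields must have matching cardinality
  if (all(c("aggr_fragment_annotation", "aggr_peak_area") %in% names(df)) &&
      nrow(df)) {
    has <- !is.na(df$aggr_fragment_annotation) & !is.na(df$aggr_peak_area) &
      nzchar(df$aggr_fragment_annotation) & nzchar(df$aggr_peak_area)
    na_tok <- lengths(strsplit(df$aggr_fragment_annotation[has], ";",
                               fixed = TRUE))
    nb_tok <- lengths(strsplit(df$aggr_peak_area[has], ";", fixed = TRUE))
    mism <- which(has)[na_tok != nb_tok]
    if (length(mism)) {
      stop("transition annotation/area cardinality mismatch at row(s): ",
           paste(utils::head(mism, 5L), collapse = ", "))
    }
  }

  rownames(df) <- NULL
  structure(df,
            class = c("peakgroup_table", "data.frame"),
            decoy_marker = decoy_marker,
            n_unscored = n_unscored)
}

#' Read a long-format peakgroup table
#'
#' Reads a tab-delimited peakgroup export (one row per quantified precursor
#' peptide per injection) and maps its headers to the canonical field names
#' through a dialect.  The OpenSWATH dialect is applied by default; a custom
#' dialect can be a named character vector or a file path accepted by
#' [read_dialect()].
#'
#' @param path tab-delimited file with a header row.
#' @param dialect `"openswath"`, a named character vector
#'   (source header -> canonical field), or a dialect file path.
#' @param decoy_marker see [as_peakgroup_table()].
#' @return a `peakgroup_table`.
#' @export
read_peakgroup_table <- function(path, dialect = "openswath",
                                 decoy_marker = "DECOY_") {
  if (is.character(dialect) && length(dialect) == 1L && is.null(names(dialect))) {
    dialect <- if (file.exists(dialect) && !identical(dialect, "openswath")) {
      read_dialect(dialect)
    } else {
      pg_dialect(dialect)
    }
  }
  df <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  import_peakgroups(df, dialect, decoy_marker = decoy_marker)
}

#' Import a generic column-labelled table
#'
#' Renames columns of `df` according to `mapping` (source header ->
#' canonical field) and validates the result.  Unmapped columns are carried
#' through untouched, so vendor-specific extras survive the import.
#'
#' @param df data frame with arbitrary headers.
#' @param mapping named character vector; names are source headers present in
#'   `df`, values are canonical field names.
#' @param decoy_marker see [as_peakgroup_table()].
#' @return a `peakgroup_table`.
#' @export
import_peakgroups <- function(df, mapping, decoy_marker = "DECOY_") {
  stopifnot(is.data.frame(df), is.character(mapping), !is.null(names(mapping)))
  mapping <- mapping[names(mapping) %in% names(df)]
  if (anyDuplicated(unname(mapping))) {
    dup <- unique(mapping[duplicated(mapping)])
    stop("mapping target collision: several source columns map to ",
         paste(dup, collapse = ", "))
  }
  nm <- names(df)
  hit <- match(nm, names(mapping))
  nm[!is.na(hit)] <- unname(mapping[hit[!is.na(hit)]])
  names(df) <- nm
  as_peakgroup_table(df, decoy_marker = decoy_marker)
}

#' Write a peakgroup table as canonical TSV
#'
#' Writes tab-separated UTF-8 text with the OpenSWATH header vocabulary and
#' no quoting.  Floating point values use the shortest decimal representation
#' that reproduces the double exactly, so `read_peakgroup_table()` of the
#' written file restores the canonical fields bit-exactly.
#'
#' @param t a `peakgroup_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_peakgroup_table <- function(t, path) {
  stopifnot(inherits(t, "peakgroup_table"))
  keep <- intersect(.pg_fields, names(t))
  out <- as.data.frame(t)[keep]
  for (col in intersect(c("intensity", "m_score", "rt"), keep)) {
    out[[col]] <- .fmt_shortest(out[[col]])
  }
  if ("decoy" %in% keep) out$decoy <- as.integer(out$decoy)
  names(out) <- unname(.pg_header_map[keep])
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Rebuild a peakgroup table from an MSstats-like table
#'
#' Inverse of the annotation + conversion direction: reconstructs a
#' long-format peakgroup table from a table with MSstats-style columns
#' (`ProteinName`, `PeptideSequence`, `PrecursorCharge`, `Condition`,
#' `BioReplicate`, `Run`, `Intensity`).  When a `FragmentIon` column is
#' present the transition rows of each precursor/run are re-aggregated into
#' the `aggr_*` fields and the peakgroup intensity is their sum.  No m-score
#' exists in this direction, so the score field is a missing sentinel and the
#' rows are flagged unusable for FDR estimation.
#'
#' @param df MSstats-format data frame.
#' @return a `peakgroup_table` with `condition`/`bio_replicate` populated.
#' @export
from_msstats_like <- function(df) {
  req <- c("ProteinName", "PeptideSequence", "PrecursorCharge",
           "Condition", "BioReplicate", "Run", "Intensity")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("missing required MSstats column(s): ", paste(miss, collapse = ", "))
  }
  if (!nrow(df)) {
    out <- data.frame(protein_name = character(), peptide_sequence_mod = character(),
                      precursor_charge = integer(), filename = character(),
                      run_id = character(), condition = character(),
                      bio_replicate = character(), intensity = numeric(),
                      m_score = numeric(), stringsAsFactors = FALSE)
    return(suppressMessages(as_peakgroup_table(out)))
  }
  base <- data.frame(
    protein_name = as.character(df$ProteinName),
    peptide_sequence_mod = as.character(df$PeptideSequence),
    precursor_charge = as.integer(df$PrecursorCharge),
    filename = as.character(df$Run),
    run_id = as.character(df$Run),
    condition = as.character(df$Condition),
    bio_replicate = as.character(df$BioReplicate),
    intensity = as.numeric(df$Intensity),
    m_score = NA_real_,
    stringsAsFactors = FALSE
  )
  if ("FragmentIon" %in% names(df)) {
    key <- paste(base$peptide_sequence_mod, base$precursor_charge,
                 base$filename, sep = "\r")
    if (anyDuplicated(key)) {
      idx <- split(seq_len(nrow(base)), factor(key, levels = unique(key)))
      first <- vapply(idx, `[`, 0L, 1L)
      agg <- base[first, , drop = FALSE]
      agg$intensity <- vapply(idx, function(i) sum(base$intensity[i]), 0)
      agg$aggr_fragment_annotation <-
        vapply(idx, function(i) paste(df$FragmentIon[i], collapse = ";"), "")
      agg$aggr_peak_area <-
        vapply(idx, function(i) paste(.fmt_shortest(base$intensity[i]),
                                      collapse = ";"), "")
      base <- agg
    }
  }
  suppressMessages(as_peakgroup_table(base))
}

#' Reduce a peakgroup table to the canonical columns
#'
#' Retains exactly the canonical fields used by the annotation, QC, FDR,
#' filtering and conversion operations and drops everything else.  Row count
#' is unchanged and the operation is idempotent.
#'
#' @param t a `peakgroup_table`.
#' @return the reduced `peakgroup_table`.
#' @export
reduce_columns <- function(t) {
  stopifnot(inherits(t, "peakgroup_table"))
  keep <- intersect(.pg_fields, names(t))
  out <- as.data.frame(t)[keep]
  structure(out,
            class = class(t),
            decoy_marker = attr(t, "decoy_marker"),
            n_unscored = attr(t, "n_unscored"))
}

# --- protein-name helpers -------------------------------------------------

# strip the decoy marker, returning list(core=..., prefix=marker or "")
.strip_marker <- function(name, marker) {
  hit <- grepl(marker, name, fixed = TRUE)
  core <- ifelse(hit, sub(marker, "", name, fixed = TRUE), name)
  list(core = core, hit = hit)
}

#' Parse protein names into multiplicity and accessions
#'
#' OpenSWATH encodes peptides mapping to several proteins with a leading
#' `"N/"` multiplicity prefix and slash-joined accessions, e.g.
#' `"2/P0A1/P0B2"`; decoy entries carry the decoy marker inside the name.
#'
#' @param name character vector of protein names.
#' @param decoy_marker decoy substring, default `"DECOY_"`.
#' @return data frame with columns `multiplicity` (integer; 1 when no prefix
#'   is present), `accessions` (the slash-joined accession list, prefix and
#'   marker removed), `is_decoy_name`, and `has_prefix`.
#' @export
parse_protein_name <- function(name, decoy_marker = "DECOY_") {
  s <- .strip_marker(name, decoy_marker)
  has_prefix <- grepl("^[0-9]+/", s$core)
  mult <- rep(1L, length(name))
  mult[has_prefix] <- as.integer(sub("^([0-9]+)/.*$", "\\1",
                                     s$core[has_prefix]))
  acc <- ifelse(has_prefix, sub("^[0-9]+/", "", s$core), s$core)
  data.frame(multiplicity = mult, accessions = acc,
             is_decoy_name = s$hit, has_prefix = has_prefix,
             stringsAsFactors = FALSE)
}

# canonical protein unit key: accession set with multiplicity prefix and
# decoy marker stripped (target and decoy units are separated by the decoy
# flag, never by this key)
.protein_key <- function(name, decoy_marker = "DECOY_") {
  parse_protein_name(name, decoy_marker)$accessions
}

# protein grouping key for filters: multiplicity prefix stripped but decoy
# marker kept, so filter predicates never consult the decoy flag yet decoy
# and target proteins group separately
.protein_group <- function(name, decoy_marker = "DECOY_") {
  p <- parse_protein_name(name, decoy_marker)
  ifelse(p$is_decoy_name, paste0(decoy_marker, p$accessions), p$accessions)
}

.decoy_marker <- function(t) {
  m <- attr(t, "decoy_marker")
  if (is.null(m)) "DECOY_" else m
}

# rows usable for FDR estimation / score filtering
.scored <- function(t) is.finite(t$m_score)

#' @export
print.peakgroup_table <- function(x, ...) {
  n_assay <- if (all(c("peptide_sequence_mod", "precursor_charge") %in%
                     names(x))) {
    length(unique(paste(x$peptide_sequence_mod, x$precursor_charge)))
  } else NA_integer_
  cat("peakgroup_table: ", nrow(x), " rows, ",
      length(unique(x$run_id)), " run(s), ",
      n_assay, " assay(s), ", sum(x$decoy), " decoy row(s)\n", sep = "")
  if (isTRUE(attr(x, "n_unscored") > 0)) {
    cat("  (", attr(x, "n_unscored"),
        " row(s) without a usable m-score)\n", sep = "")
  }
  annotated <- all(c("condition", "bio_replicate") %in% names(x))
  cat("  annotated: ", if (annotated) "yes" else "no", "\n", sep = "")
  invisible(x)
}
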