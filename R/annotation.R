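# Study-design handling: joining experimental metadata onto the peakgroup
# table, or deriving it from structured filenames.

#' Read a study-design table
#'
#' Tab-delimited file with header `Filename`, `Condition`, `BioReplicate`
#' and optional `Run` (header case is ignored).  When `Run` is absent each
#' injection is its own run, identified by its filename.
#'
#' @param path file path.
#' @return data frame with columns `filename`, `condition`, `bio_replicate`,
#'   `run`.
#' @export
read_study_design <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(names(df))
  want <- c(filename = "filename", condition = "condition",
            bio_replicate = "bioreplicate", run = "run")
  idx <- match(want, nm)
  if (anyNA(idx[1:3])) {
    stop("study design must have columns Filename, Condition, BioReplicate; ",
         "missing: ", paste(names(want)[1:3][is.na(idx[1:3])], collapse = ", "))
  }
  out <- data.frame(filename = as.character(df[[idx[1]]]),
                    condition = as.character(df[[idx[2]]]),
                    bio_replicate = as.character(df[[idx[3]]]),
                    stringsAsFactors = FALSE)
  out$run <- if (is.na(idx[4])) out$filename else as.character(df[[idx[4]]])
  .validate_design(out)
}

.validate_design <- function(d) {
  stopifnot(is.data.frame(d))
  need <- c("filename", "condition", "bio_replicate")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("study design missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!"run" %in% names(d)) d$run <- d$filename
  d$filename <- as.character(d$filename)
  dup <- unique(d$filename[duplicated(d$filename)])
  if (length(dup)) {
    stop("duplicate filename(s) in study design: ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  d
}

#' Write a study-design table
#'
#' @param d design data frame (`filename`, `condition`, `bio_replicate`,
#'   optional `run`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_study_design <- function(d, path) {
  d <- .validate_design(d)
  out <- data.frame(Filename = d$filename, Condition = d$condition,
                    BioReplicate = d$bio_replicate, Run = d$run,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Annotate a peakgroup table with the study design
#'
#' Populates `condition`, `bio_replicate` and `run_id` on every row by
#' joining the design on filename.  The join is exact by default; with
#' `match = "substring"` a design filename matches any data filename that
#' contains it (useful when the design lists basenames and the data carries
#' full paths).
#'
#' @param t a `peakgroup_table`.
#' @param design design data frame (see [read_study_design()]).
#' @param strict error when a data filename has no design entry (default);
#'   otherwise such rows keep `NA` annotation with a warning.
#' @param match `"exact"` or `"substring"`.
#' @return the annotated `peakgroup_table`; row count and all other fields
#'   are unchanged.
#' @export
annotate_samples <- function(t, design, strict = TRUE,
                             match = c("exact", "substring")) {
  stopifnot(inherits(t, "peakgroup_table"))
  match <- match.arg(match)
  design <- .validate_design(design)

  files <- unique(t$filename)
  if (match == "exact") {
    hits <- lapply(files, function(f) which(design$filename == f))
  } else {
    hits <- lapply(files, function(f)
      which(vapply(design$filename, grepl, NA, x = f, fixed = TRUE)))
  }
  n_hit <- lengths(hits)
  multi <- files[n_hit > 1L]
  if (length(multi)) {
    stop("data filename(s) matching more than one design row: ",
         paste(utils::head(multi, 5L), collapse = ", "))
  }
  unmatched <- files[n_hit == 0L]
  if (length(unmatched)) {
    if (strict) {
      stop("filename(s) not present in the study design: ",
           paste(unmatched, collapse = ", "))
    }
    warning("filename(s) without design entry left unannotated: ",
            paste(unmatched, collapse = ", "))
  }

  di <- rep(NA_integer_, length(files))
  di[n_hit == 1L] <- vapply(hits[n_hit == 1L], `[`, 0L, 1L)
  row_di <- di[base::match(t$filename, files)]

  t$condition <- design$condition[row_di]
  t$bio_replicate <- design$bio_replicate[row_di]
  run <- design$run[row_di]
  t$run_id <- ifelse(is.na(run), t$run_id, run)
  t
}

# strip compression suffix and one file extension from a basename
.basename_stem <- function(x) {
  b <- basename(x)
  b <- sub("\\.(gz|bz2|xz|zip)$", "", b, ignore.case = TRUE)
  tools::file_path_sans_ext(b)
}

#' Derive the study design from structured filenames
#'
#' When condition and replicate are encoded in the injection filenames
#' (e.g. `"study_ctrl_rep1_001.mzML"`), the design table can be extracted
#' directly: the basename (extension stripped) is split on `sep` and the
#' requested token positions provide condition, replicate and, optionally,
#' run.  Without a `run_token` each distinct filename is its own run.
#'
#' @param filenames character vector (duplicates are de-duplicated).
#' @param sep token delimiter, default `"_"`.
#' @param condition_token,replicate_token,run_token 1-based token positions;
#'   `run_token = NULL` uses the filename as run.
#' @return design data frame (`filename`, `condition`, `bio_replicate`,
#'   `run`), one row per distinct filename.
#' @export
design_from_filenames <- function(filenames, sep = "_",
                                  condition_token = 2L,
                                  replicate_token = 3L,
                                  run_token = NULL) {
  files <- unique(filenames)
  toks <- strsplit(.basename_stem(files), sep, fixed = TRUE)
  need <- max(condition_token, replicate_token,
              if (is.null(run_token)) 0L else run_token)
  short <- lengths(toks) < need
  if (any(short)) {
    stop("filename(s) with fewer than ", need, " '", sep, "'-separated ",
         "tokens: ", paste(utils::head(files[short], 5L), collapse = ", "))
  }
  data.frame(
    filename = files,
    condition = vapply(toks, `[`, "", condition_token),
    bio_replicate = vapply(toks, `[`, "", replicate_token),
    run = if (is.null(run_token)) files else vapply(toks, `[`, "", run_token),
    stringsAsFactors = FALSE
  )
}
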