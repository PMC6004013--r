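#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

#' Reserved sample-metadata columns of a peak table
#'
#' A peak table is a tibble with one row per injection. The leading columns
#' hold sample metadata; every remaining column is a feature intensity
#' (non-negative, arbitrary units, `NA` = missing). Feature metadata
#' (m/z in Da, retention time in minutes) travels in the `"features"`
#' attribute, a tibble with columns `feature_id`, `mz`, `rt`.
#'
#' @return Character vector of reserved column names.
#' @export
meta_cols <- function() {
  c("sample_id", "patient_id", "batch", "injection_order",
    "role", "class_label", "visit_index")
}

sample_roles <- c("QC", "CONDITIONING_QC", "BLANK", "STUDY")
class_tokens <- c("BC", "CTRL", "MONITOR", "NA")

#' Construct a peak table
#'
#' @param samples Tibble of sample metadata with the columns of
#'   [meta_cols()].
#' @param intensities Numeric matrix, samples in rows and features in
#'   columns (column names are feature ids), or a data frame coercible to
#'   one.
#' @param features Optional tibble with `feature_id`, `mz` (Da, > 0) and
#'   `rt` (min, >= 0). Defaults to placeholder metadata.
#' @return A validated `peak_tbl` (a tibble).
#' @export
peak_table <- function(samples, intensities, features = NULL) {
  intensities <- as.matrix(intensities)
  if (is.null(colnames(intensities))) {
    colnames(intensities) <- sprintf("F%04d", seq_len(ncol(intensities)))
  }
  if (nrow(intensities) != nrow(samples)) {
    abort("intensity matrix and sample metadata disagree on sample count")
  }
  if (is.null(features)) {
    features <- tibble(
      feature_id = colnames(intensities),
      mz = seq(100, 1000, length.out = ncol(intensities)),
      rt = seq(0.5, 9.5, length.out = ncol(intensities))
    )
  }
  tbl <- dplyr::bind_cols(
    as_tibble(samples)[meta_cols()],
    as_tibble(intensities)
  )
  new_peak_table(tbl, features)
}

new_peak_table <- function(tbl, features) {
  tbl <- as_tibble(tbl)
  attr(tbl, "features") <- as_tibble(features)
  class(tbl) <- unique(c("peak_tbl", class(tbl)))
  validate_peak_table(tbl)
}

#' Validate a peak table
#'
#' Checks the structural invariants: unique sample ids, unique
#' (batch, injection order) pairs, known role and class tokens, STUDY
#' samples carrying a patient id, conditioning QCs preceding all other
#' injections of their batch, positive m/z, and non-negative intensities.
#'
#' @param x A `peak_tbl`.
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
validate_peak_table <- function(x) {
  missing_meta <- setdiff(meta_cols(), names(x))
  if (length(missing_meta) > 0) {
    abort(paste0("missing metadata column(s): ",
                 paste(missing_meta, collapse = ", ")))
  }
  if (anyDuplicated(x$sample_id)) {
    dup <- unique(x$sample_id[duplicated(x$sample_id)])
    abort(paste0("duplicate sample_id: ", paste(dup, collapse = ", ")))
  }
  bad_role <- setdiff(unique(x$role), sample_roles)
  if (length(bad_role) > 0) {
    abort(paste0("unknown role token: ", paste(bad_role, collapse = ", ")))
  }
  cls <- x$class_label[!is.na(x$class_label)]
  bad_cls <- setdiff(unique(cls), class_tokens)
  if (length(bad_cls) > 0) {
    abort(paste0("unknown class_label token: ",
                 paste(bad_cls, collapse = ", ")))
  }
  if (anyDuplicated(x[c("batch", "injection_order")])) {
    abort("(batch, injection_order) pairs must be unique")
  }
  study <- x$role == "STUDY"
  if (any(study & is.na(x$patient_id))) {
    abort("STUDY samples must have a patient_id")
  }
  for (b in unique(x$batch)) {
    in_b <- x$batch == b
    cond <- in_b & x$role == "CONDITIONING_QC"
    if (any(cond) && any(in_b & !x[["role"]] %in% "CONDITIONING_QC")) {
      if (max(x$injection_order[cond]) >
          min(x$injection_order[in_b & x$role != "CONDITIONING_QC"])) {
        abort(paste0("conditioning QCs must precede all other injections ",
                     "in batch ", b))
      }
    }
  }
  fm <- feature_meta(x)
  if (!is.null(fm)) {
    if (anyDuplicated(fm$feature_id)) abort("duplicate feature_id")
    if (any(fm$mz <= 0, na.rm = TRUE)) abort("feature mz must be > 0")
  }
  im <- intensity_matrix(x)
  if (any(im < 0, na.rm = TRUE)) abort("intensities must be non-negative")
  invisible(x)
}

#' @rdname peak_table_accessors
#' @export
feature_ids <- function(x) setdiff(names(x), meta_cols())

#' Peak-table accessors
#'
#' `feature_ids()` returns the feature column names; `intensity_matrix()`
#' the numeric sample-by-feature matrix (rownames = sample ids);
#' `sample_meta()` the metadata columns; `feature_meta()` the feature
#' metadata tibble carried in the `"features"` attribute (or `NULL`).
#'
#' @param x A `peak_tbl`.
#' @name peak_table_accessors
#' @export
intensity_matrix <- function(x) {
  m <- as.matrix(x[feature_ids(x)])
  storage.mode(m) <- "double"
  rownames(m) <- x$sample_id
  m
}

#' @rdname peak_table_accessors
#' @export
sample_meta <- function(x) as_tibble(x[meta_cols()])

#' @rdname peak_table_accessors
#' @export
feature_meta <- function(x) attr(x, "features", exact = TRUE)

#' Replace the intensity block of a peak table
#'
#' Keeps sample metadata and feature metadata aligned; used by the
#' correction stages, which transform intensities but never reorder rows.
#'
#' @param x A `peak_tbl`.
#' @param m Numeric matrix with `nrow(x)` rows; column names select and
#'   order the retained features.
#' @return A `peak_tbl` with the new intensities.
#' @export
set_intensities <- function(x, m) {
  fm <- feature_meta(x)
  if (!is.null(fm)) fm <- fm[match(colnames(m), fm$feature_id), ]
  tbl <- dplyr::bind_cols(sample_meta(x), as_tibble(m))
  new_peak_table(tbl, fm)
}

#' Read a peak table from delimited text
#'
#' Expects samples in rows and features in columns, with the reserved
#' metadata columns of [meta_cols()] leading. The delimiter (comma or tab)
#' is detected from the header line. Empty cells are missing values; the
#' literal token `"NA"` in `class_label` is a valid class (cystoscopy
#' outcome unknown), so files must encode missingness as empty cells.
#'
#' @param path Path to a CSV/TSV peak table.
#' @param feature_path Optional path to a feature-metadata CSV with columns
#'   `feature_id`, `mz`, `rt`.
#' @return A validated `peak_tbl`.
#' @export
read_peak_table <- function(path, feature_path = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tbl <- readr::read_delim(path, delim = delim, na = "",
                           col_types = readr::cols(.default = "c"),
                           show_col_types = FALSE, progress = FALSE)
  tbl$batch <- as.integer(tbl$batch)
  tbl$injection_order <- as.integer(tbl$injection_order)
  tbl$visit_index <- as.integer(tbl$visit_index)
  for (col in setdiff(names(tbl), meta_cols())) {
    tbl[[col]] <- as.double(tbl[[col]])
  }
  features <- NULL
  if (!is.null(feature_path)) {
    features <- readr::read_csv(feature_path, na = "",
                                col_types = readr::cols(.default = "c"),
                                show_col_types = FALSE, progress = FALSE)
    features$mz <- as.double(features$mz)
    features$rt <- as.double(features$rt)
  } else {
    features <- tibble(feature_id = setdiff(names(tbl), meta_cols()),
                       mz = NA_real_, rt = NA_real_)
  }
  new_peak_table(tbl, features)
}

#' Write a peak table to delimited text
#'
#' Missing intensities are written as empty cells so they survive a
#' round-trip as `NA`, distinct from zero.
#'
#' @param x A `peak_tbl`.
#' @param path Output path; `.tsv` extension selects tab delimiting.
#' @param feature_path Optional path for the feature-metadata CSV.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(x, path, feature_path = NULL) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  out <- as_tibble(as.data.frame(x))
  for (col in setdiff(names(out), meta_cols())) {
    # shortest exact decimal so intensities survive the round-trip
    # bit-for-bit
    v <- sprintf("%.17g", out[[col]])
    v[is.na(out[[col]])] <- NA_character_
    out[[col]] <- v
  }
  readr::write_delim(out, path, delim = delim, na = "")
  if (!is.null(feature_path)) {
    fm <- feature_meta(x)
    for (col in c("mz", "rt")) {
      v <- sprintf("%.17g", fm[[col]])
      v[is.na(fm[[col]])] <- NA_character_
      fm[[col]] <- v
    }
    readr::write_csv(fm, feature_path, na = "")
  }
  invisible(path)
}

#' Drop conditioning injections
#'
#' Column-conditioning QC replicates injected at the head of each batch are
#' acquisition overhead; they are excluded before any analysis. Idempotent.
#'
#' @param x A `peak_tbl`.
#' @return The table without `CONDITIONING_QC` rows.
#' @export
exclude_conditioning <- function(x) {
  keep <- x$role != "CONDITIONING_QC"
  new_peak_table(x[keep, , drop = FALSE], feature_meta(x))
}

#' Split study samples into train and validation sets by patient
#'
#' All samples of a patient land in the subset the assignment names, so no
#' patient can leak between model fitting and validation.
#'
#' @param x A `peak_tbl`.
#' @param assignment Named character vector (or two-column data frame
#'   `patient_id`, `subset`) mapping every STUDY patient to `"train"` or
#'   `"validation"`.
#' @return A `split_plan`: list with `train_sample_ids`,
#'   `validation_sample_ids` and a per-class `counts` tibble.
#' @export
split_by_patient <- function(x, assignment) {
  if (is.data.frame(assignment)) {
    assignment <- stats::setNames(assignment$subset, assignment$patient_id)
  }
  bad <- setdiff(unique(assignment), c("train", "validation"))
  if (length(bad) > 0) {
    abort(paste0("assignment values must be 'train' or 'validation', got: ",
                 paste(bad, collapse = ", ")))
  }
  study <- x[x$role == "STUDY", ]
  unassigned <- setdiff(unique(study$patient_id), names(assignment))
  if (length(unassigned) > 0) {
    abort(paste0("unassigned patient(s): ",
                 paste(unassigned, collapse = ", ")))
  }
  subset <- unname(assignment[study$patient_id])
  counts <- study |>
    dplyr::mutate(subset = subset) |>
    dplyr::count(.data$subset, .data$class_label) |>
    tidyr::pivot_wider(names_from = "subset", values_from = "n",
                       values_fill = 0L)
  plan <- list(
    train_sample_ids = study$sample_id[subset == "train"],
    validation_sample_ids = study$sample_id[subset == "validation"],
    counts = counts
  )
  structure(plan, class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("Patient-wise split plan\n")
  cat("  train:      ", length(x$train_sample_ids), "samples\n")
  cat("  validation: ", length(x$validation_sample_ids), "samples\n")
  print(x$counts)
  invisible(x)
}

#' Serialize a split plan to JSON
#'
#' @param plan A `split_plan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(
    list(train_sample_ids = plan$train_sample_ids,
         validation_sample_ids = plan$validation_sample_ids,
         counts = plan$counts),
    path, auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}
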