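#' @title Feature matrix container
#'
#' @description Validated subjects-by-features real matrix with unique subject
#' IDs and feature names. This is the unit of data every harmonization and
#' evaluation function operates on (rows = subjects, columns = features, e.g.
#' regional cortical thickness values).
#'
#' @param values numeric matrix, subjects in rows, features in columns.
#' @param subject_ids character vector of unique subject identifiers; defaults
#'   to `rownames(values)`.
#' @param feature_names character vector of unique feature names; defaults to
#'   `colnames(values)`.
#' @return An object of class `feature_matrix` with elements `values`,
#'   `subject_ids`, `feature_names`.
#' @export
feature_matrix <- function(values, subject_ids = rownames(values),
                           feature_names = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(subject_ids)) subject_ids <- paste0("subj", seq_len(nrow(values)))
  if (is.null(feature_names)) feature_names <- paste0("feat", seq_len(ncol(values)))
  subject_ids <- as.character(subject_ids)
  feature_names <- as.character(feature_names)
  if (!is.numeric(values)) stop("feature values must be numeric")
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("feature matrix must have at least 2 subjects and 2 features")
  if (anyNA(values) || any(!is.finite(values)))
    stop("feature matrix contains missing or non-finite values")
  if (length(subject_ids) != nrow(values))
    stop("subject_ids length does not match number of rows")
  if (length(feature_names) != ncol(values))
    stop("feature_names length does not match number of columns")
  if (anyDuplicated(subject_ids))
    stop("duplicate subject IDs: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  if (anyDuplicated(feature_names))
    stop("duplicate feature names: ",
         paste(unique(feature_names[duplicated(feature_names)]), collapse = ", "))
  dimnames(values) <- list(subject_ids, feature_names)
  structure(list(values = values, subject_ids = subject_ids,
                 feature_names = feature_names),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d subjects x %d features\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Covariate design container
#'
#' Holds per-subject biological covariates together with batch membership.
#' Categorical covariates are dummy-coded dropping the lexicographically first
#' level; continuous covariates pass through unchanged. Batch is stored both as
#' a factor and as a one-hot indicator matrix of size B (even for B = 2), so
#' downstream stages generalize to more than two batches.
#'
#' @param raw_covariates data.frame of numeric or categorical covariates
#'   (one row per subject), or NULL for a covariate-free design.
#' @param batch_labels vector coercible to factor with >= 2 subjects per level.
#' @param subject_ids character vector of unique subject IDs.
#' @return Object of class `covariate_design` with elements `raw_covariates`,
#'   `design` (encoded n x d matrix), `batch_labels`, `batch_onehot`,
#'   `subject_ids`.
#' @export
covariate_design <- function(raw_covariates, batch_labels, subject_ids = NULL) {
  batch_labels <- droplevels(as.factor(batch_labels))
  n <- length(batch_labels)
  if (is.null(subject_ids)) subject_ids <- paste0("subj", seq_len(n))
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != n) stop("subject_ids length mismatch")
  if (anyDuplicated(subject_ids)) stop("duplicate subject IDs in design")
  tab <- table(batch_labels)
  if (any(tab < 2L))
    stop("every batch level needs >= 2 subjects; offending level(s): ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  if (is.null(raw_covariates)) {
    raw_covariates <- data.frame(row.names = subject_ids)
  }
  raw_covariates <- as.data.frame(raw_covariates)
  if (nrow(raw_covariates) != n && ncol(raw_covariates) > 0L)
    stop("covariate table has ", nrow(raw_covariates), " rows, expected ", n)
  design <- encode_design(raw_covariates)
  rownames(design) <- subject_ids
  B <- nlevels(batch_labels)
  onehot <- matrix(0, n, B, dimnames = list(subject_ids, levels(batch_labels)))
  onehot[cbind(seq_len(n), as.integer(batch_labels))] <- 1
  structure(list(raw_covariates = raw_covariates, design = design,
                 batch_labels = batch_labels, batch_onehot = onehot,
                 subject_ids = subject_ids),
            class = "covariate_design")
}

#' @export
print.covariate_design <- function(x, ...) {
  cat(sprintf("<covariate_design> %d subjects, %d design column(s), %d batch(es): %s\n",
              length(x$subject_ids), ncol(x$design), nlevels(x$batch_labels),
              paste(levels(x$batch_labels), collapse = ", ")))
  invisible(x)
}

# Dummy-code a covariate data.frame: numerics as-is, categoricals with the
# lexicographically first level dropped as reference.
encode_design <- function(df) {
  n <- nrow(df)
  cols <- list()
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.numeric(v)) {
      if (anyNA(v)) stop("missing values in covariate '", nm, "'")
      cols[[nm]] <- matrix(as.numeric(v), ncol = 1,
                           dimnames = list(NULL, nm))
    } else {
      f <- factor(as.character(v), levels = sort(unique(as.character(v))))
      if (anyNA(f)) stop("missing values in covariate '", nm, "'")
      if (nlevels(f) < 2L) {
        warning("covariate '", nm, "' is constant; dropped from the design")
        next
      }
      m <- matrix(0, n, nlevels(f) - 1L)
      colnames(m) <- paste0(nm, levels(f)[-1L])
      for (j in seq_len(nlevels(f) - 1L)) m[, j] <- as.numeric(f == levels(f)[j + 1L])
      cols[[nm]] <- m
    }
  }
  if (length(cols) == 0L) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  do.call(cbind, cols)
}

infer_delim <- function(path, delimiter = NULL) {
  if (!is.null(delimiter)) return(delimiter)
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read an aligned feature/covariate dataset from CSV or TSV files
#'
#' Reads a feature table and a covariate table, aligns their rows by subject
#' ID (order in the covariate file is irrelevant), validates both, and returns
#' the pair of containers the harmonization pipeline consumes.
#'
#' @param features_path path to a CSV/TSV with an ID column and one numeric
#'   column per feature.
#' @param covariates_path path to a CSV/TSV with the ID column, the batch
#'   column and the biological covariates.
#' @param batch_column name of the batch column in the covariate file.
#' @param covariate_columns character vector of biological covariate column
#'   names to use (may be empty).
#' @param id_column name of the subject-ID column, present in both files.
#' @param delimiter optional field separator overriding the
#'   extension-based inference (`.tsv` -> tab, otherwise comma).
#' @return `list(features = feature_matrix, design = covariate_design)`.
#' @export
read_dataset <- function(features_path, covariates_path, batch_column,
                         covariate_columns = character(), id_column = "id",
                         delimiter = NULL) {
  fdat <- utils::read.table(features_path, header = TRUE,
                            sep = infer_delim(features_path, delimiter),
                            colClasses = "character", check.names = FALSE,
                            stringsAsFactors = FALSE)
  cdat <- utils::read.table(covariates_path, header = TRUE,
                            sep = infer_delim(covariates_path, delimiter),
                            check.names = FALSE, stringsAsFactors = FALSE)
  for (nm in c(id_column)) {
    if (!nm %in% names(fdat)) stop("id column '", nm, "' missing from ", features_path)
    if (!nm %in% names(cdat)) stop("id column '", nm, "' missing from ", covariates_path)
  }
  if (!batch_column %in% names(cdat))
    stop("batch column '", batch_column, "' missing from ", covariates_path)
  missing_cov <- setdiff(covariate_columns, names(cdat))
  if (length(missing_cov) > 0L)
    stop("covariate column(s) missing: ", paste(missing_cov, collapse = ", "))

  fids <- as.character(fdat[[id_column]])
  cids <- as.character(cdat[[id_column]])
  only_f <- setdiff(fids, cids)
  only_c <- setdiff(cids, fids)
  if (length(only_f) > 0L || length(only_c) > 0L)
    stop("subject IDs do not align; missing from covariates: [",
         paste(only_f, collapse = ", "), "]; missing from features: [",
         paste(only_c, collapse = ", "), "]")

  feat_cols <- setdiff(names(fdat), id_column)
  vals <- matrix(NA_real_, nrow(fdat), length(feat_cols),
                 dimnames = list(fids, feat_cols))
  for (j in seq_along(feat_cols)) {
    raw <- fdat[[feat_cols[j]]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) | raw == "")
    if (length(bad) > 0L)
      stop("non-numeric feature cell at row ", bad[1L], ", column '",
           feat_cols[j], "' (value: '", raw[bad[1L]], "')")
    vals[, j] <- num
  }
  cdat <- cdat[match(fids, cids), , drop = FALSE]

  features <- feature_matrix(vals, subject_ids = fids, feature_names = feat_cols)
  design <- covariate_design(
    raw_covariates = cdat[, covariate_columns, drop = FALSE],
    batch_labels = cdat[[batch_column]],
    subject_ids = fids)
  list(features = features, design = design)
}

#' Write harmonized output to CSV
#'
#' Writes the harmonized matrix (original feature scale) with the subject-ID
#' column first and the original feature order preserved, so that
#' `read_dataset()` on the written file recovers the matrix.
#'
#' @param result a `deepcombat_result` (see [deepcombat()]) or a
#'   `feature_matrix`.
#' @param out_path output file path (`.csv` or `.tsv`).
#' @param id_column name for the subject-ID column.
#' @return `out_path`, invisibly.
#' @export
write_harmonized <- function(result, out_path, id_column = "id") {
  fm <- if (inherits(result, "deepcombat_result")) result$harmonized else result
  if (!inherits(fm, "feature_matrix")) stop("result must contain a feature_matrix")
  df <- data.frame(fm$subject_ids, fm$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(id_column, fm$feature_names)
  ok <- tryCatch({
    utils::write.table(df, out_path, sep = infer_delim(out_path, NULL),
                       row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) stop("cannot write '", out_path, "': ", conditionMessage(e)))
  invisible(out_path)
}
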