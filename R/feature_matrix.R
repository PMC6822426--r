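#' Construct a feature matrix of protein/transcript measurements
#'
#' The central data container of the package: a samples x features numeric
#' matrix (RPPA-style total/phospho protein levels, or transcript levels)
#' with per-feature annotations (measurement kind, receptor flag) and
#' per-sample metadata (tumor type).  Missing measurements are represented
#' explicitly as `NA`, never as zero.
#'
#' @param values Numeric matrix, samples in rows, features in columns; both
#'   dimnames must be set and unique.  `NA` marks a missing measurement.
#' @param feature_meta Optional data frame with columns `feature_id`,
#'   `kind` (one of `"total"`, `"phospho"`, `"transcript"`) and
#'   `is_receptor` (logical).  When absent, `kind` is inferred from the
#'   feature id: ids carrying a phosphosite suffix such as `"HER3-Y1289"`
#'   or `"BRAF_S445"` are classed `"phospho"`, all others `"total"`, and
#'   `is_receptor` defaults to `FALSE`.
#' @param sample_meta Optional data frame with columns `sample_id` and
#'   `tumor_type` (e.g. `"melanoma"` / `"non-melanoma"`).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, feature_meta = NULL, sample_meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have sample row names and feature column names")
  dup_s <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "))
  dup_f <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_f))
    stop("duplicate feature id(s): ", paste(dup_f, collapse = ", "))

  if (is.null(feature_meta)) {
    feature_meta <- data.frame(
      feature_id = colnames(values),
      kind = infer_feature_kind(colnames(values)),
      is_receptor = FALSE,
      stringsAsFactors = FALSE
    )
  } else {
    feature_meta <- as.data.frame(feature_meta, stringsAsFactors = FALSE)
    need <- c("feature_id", "kind", "is_receptor")
    miss <- setdiff(need, names(feature_meta))
    if (length(miss))
      stop("feature_meta lacks column(s): ", paste(miss, collapse = ", "))
    idx <- match(colnames(values), feature_meta$feature_id)
    if (anyNA(idx))
      stop("feature_meta missing annotation for: ",
           paste(colnames(values)[is.na(idx)], collapse = ", "))
    feature_meta <- feature_meta[idx, need, drop = FALSE]
    bad <- setdiff(unique(feature_meta$kind), c("total", "phospho", "transcript"))
    if (length(bad))
      stop("unknown feature kind(s): ", paste(bad, collapse = ", "))
    feature_meta$is_receptor <- as.logical(feature_meta$is_receptor)
  }
  rownames(feature_meta) <- NULL

  if (is.null(sample_meta)) {
    sample_meta <- data.frame(
      sample_id = rownames(values),
      tumor_type = NA_character_,
      stringsAsFactors = FALSE
    )
  } else {
    sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "tumor_type") %in% names(sample_meta)))
      stop("sample_meta needs columns 'sample_id' and 'tumor_type'")
    idx <- match(rownames(values), sample_meta$sample_id)
    if (anyNA(idx))
      stop("sample_meta missing row(s) for: ",
           paste(rownames(values)[is.na(idx)], collapse = ", "))
    sample_meta <- sample_meta[idx, c("sample_id", "tumor_type"), drop = FALSE]
  }
  rownames(sample_meta) <- NULL

  structure(
    list(values = values, feature_meta = feature_meta, sample_meta = sample_meta),
    class = "feature_matrix"
  )
}

# Phosphosite naming convention: a site suffix like "-Y1289", "_S445",
# "_pY1068" or "_T202-Y204" marks a phospho measurement.
infer_feature_kind <- function(ids) {
  phospho <- grepl("[_-]p?[YST][0-9]+", ids)
  ifelse(phospho, "phospho", "total")
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  kinds: %s\n",
              paste(sprintf("%s=%d", names(table(x$feature_meta$kind)),
                            table(x$feature_meta$kind)), collapse = ", ")))
  cat(sprintf("  receptor-flagged: %d, missing entries: %d (%.1f%%)\n",
              sum(x$feature_meta$is_receptor), sum(is.na(x$values)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
`[.feature_matrix` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  fm <- x$feature_meta[match(colnames(v), x$feature_meta$feature_id), , drop = FALSE]
  sm <- x$sample_meta[match(rownames(v), x$sample_meta$sample_id), , drop = FALSE]
  feature_matrix(v, fm, sm)
}

#' Sample ids of a feature matrix or response vector
#' @param x A `feature_matrix` or `response_vector`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(x) {
  if (inherits(x, "feature_matrix")) rownames(x$values)
  else if (inherits(x, "response_vector")) x$sample_ids
  else stop("no sample ids for class ", paste(class(x), collapse = "/"))
}

#' Construct a drug-sensitivity response vector
#'
#' Holds the per-sample normalized area under the dose-response inhibition
#' curve (IC50 AUC), the continuous sensitivity readout modelled throughout
#' the package.  Values are bounded in \[0, 1\]; higher means more sensitive.
#'
#' @param sample_ids Character vector of unique sample ids.
#' @param auc Numeric vector of the same length with values in \[0, 1\].
#' @return An object of class `response_vector`.
#' @export
response_vector <- function(sample_ids, auc) {
  sample_ids <- as.character(sample_ids)
  auc <- as.numeric(auc)
  if (length(sample_ids) != length(auc))
    stop("sample_ids and auc differ in length")
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "))
  if (anyNA(auc) || any(auc < 0 | auc > 1))
    stop("auc values must lie in [0, 1] and be non-missing")
  structure(list(sample_ids = sample_ids, auc = stats::setNames(auc, sample_ids)),
            class = "response_vector")
}

#' @export
print.response_vector <- function(x, ...) {
  cat(sprintf("<response_vector> %d samples, AUC range [%.3g, %.3g]\n",
              length(x$auc), min(x$auc), max(x$auc)))
  invisible(x)
}

#' Read a delimited feature matrix from disk
#'
#' Expects samples as rows with a leading `sample_id` column and a header of
#' feature ids.  Tab is the default separator; comma is accepted (and
#' auto-detected for `.csv` paths).  Empty cells or the token `"NA"` denote
#' missing measurements.
#'
#' @param path Path to the delimited file.
#' @param sep Field separator; `NULL` (default) picks `","` for `.csv`
#'   files and tab otherwise.
#' @param annotations Optional path to a feature-annotation sidecar: a
#'   delimited table with columns `feature_id`, `kind` and (optionally)
#'   `is_receptor`.
#' @param sample_meta Optional path to a sample-metadata table with columns
#'   `sample_id` and `tumor_type`.
#' @param missing_tokens Cell values to treat as missing.
#' @return A [feature_matrix].
#' @export
read_feature_matrix <- function(path, sep = NULL, annotations = NULL,
                                sample_meta = NULL,
                                missing_tokens = c("", "NA")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           na.strings = character())
  if (ncol(raw) < 2) stop("expected a sample-id column plus >=1 feature column")
  ids <- raw[[1]]
  feats <- colnames(raw)[-1]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate sample id(s): ", paste(dup, collapse = ", "))
  dupf <- unique(feats[duplicated(feats)])
  if (length(dupf)) stop("duplicate feature id(s): ", paste(dupf, collapse = ", "))

  vals <- matrix(NA_real_, nrow(raw), length(feats),
                 dimnames = list(ids, feats))
  for (j in seq_along(feats)) {
    cell <- trimws(raw[[j + 1L]])
    is_missing <- is.na(cell) | cell %in% missing_tokens
    num <- suppressWarnings(as.numeric(cell))
    bad <- !is_missing & is.na(num)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("non-numeric value '%s' at sample '%s', feature '%s'",
                   cell[i], ids[i], feats[j]))
    }
    vals[, j] <- ifelse(is_missing, NA_real_, num)
  }

  fmeta <- NULL
  if (!is.null(annotations)) {
    ann <- utils::read.table(annotations, sep = sep_of(annotations),
                             header = TRUE, stringsAsFactors = FALSE)
    if (!"is_receptor" %in% names(ann)) ann$is_receptor <- FALSE
    ann$is_receptor <- as.logical(ann$is_receptor)
    fmeta <- ann
  }
  smeta <- NULL
  if (!is.null(sample_meta)) {
    smeta <- utils::read.table(sample_meta, sep = sep_of(sample_meta),
                               header = TRUE, stringsAsFactors = FALSE)
  }
  feature_matrix(vals, feature_meta = fmeta, sample_meta = smeta)
}

sep_of <- function(path) if (grepl("\\.csv$", path)) "," else "\t"

#' Read a response table of per-sample sensitivity AUC values
#'
#' @param path Delimited file with columns `sample_id` and `auc`.
#' @param sep Field separator; auto-detected from the extension by default.
#' @return A [response_vector].
#' @export
read_response <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- sep_of(path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("sample_id", "auc") %in% names(tab)))
    stop("response table needs columns 'sample_id' and 'auc'")
  response_vector(tab$sample_id, tab$auc)
}

#' Write a feature matrix to delimited text
#' @param x A [feature_matrix].
#' @param path Output path (`.csv` switches the separator to comma).
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(x, path) {
  df <- data.frame(sample_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep_of(path), row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}
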