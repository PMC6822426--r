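#' Extract a resistance/sensitivity signature from VIP scores
#'
#' Features with VIP > 1 form the signature; each is assigned a direction
#' from the sign of its predictive weight: negative weights mark
#' resistance-associated features (high levels go with low sensitivity
#' AUC), positive weights sensitivity-associated ones.  Features are
#' ordered by decreasing absolute weight.
#'
#' @param vip A `vip_table` from [compute_vip()].
#' @return A data frame of class `signature_table` with `feature_id`,
#'   `vip`, `weight` and `direction`.  An empty signature is returned with
#'   a warning when no feature exceeds the threshold.
#' @export
select_signature <- function(vip) {
  if (!all(c("feature_id", "vip", "weight") %in% names(vip)))
    stop("expected a vip_table with feature_id, vip and weight")
  sel <- vip[vip$vip > 1, , drop = FALSE]
  if (!nrow(sel)) warning("no feature has VIP > 1; signature is empty")
  sel$direction <- ifelse(sel$weight < 0, "resistance-associated",
                          "sensitivity-associated")
  sel <- sel[order(-abs(sel$weight)), , drop = FALSE]
  rownames(sel) <- NULL
  out <- sel[, c("feature_id", "vip", "weight", "direction")]
  class(out) <- c("signature_table", "data.frame")
  out
}

#' Univariate correlation of a single feature with drug sensitivity
#'
#' Ordinary least-squares R-squared of the response on one feature, with
#' the slope sign, as used to compare how well individual transcripts,
#' total proteins and phosphoproteins track sensitivity.
#'
#' @param feature_values Numeric vector (one feature across samples).
#' @param y Aligned [response_vector] or numeric response.
#' @param feature_id,layer Optional identifiers recorded in the result;
#'   `layer` is one of `"transcript"`, `"total"`, `"phospho"`.
#' @return A one-row data frame with `feature_id`, `layer`, `r_squared`
#'   and `slope_sign`.
#' @export
univariate_correlation <- function(feature_values, y, feature_id = NA_character_,
                                   layer = NA_character_) {
  v <- as.numeric(feature_values)
  yv <- if (inherits(y, "response_vector")) as.numeric(y$auc) else as.numeric(y)
  if (length(v) != length(yv)) stop("feature and response differ in length")
  if (length(v) < 3) stop("need at least 3 paired observations")
  if (stats::sd(v) == 0) stop("constant feature")
  r <- stats::cor(v, yv)
  data.frame(feature_id = feature_id, layer = layer,
             r_squared = r^2, slope_sign = sign(r),
             stringsAsFactors = FALSE)
}

#' Layer-matched univariate correlation table
#'
#' For groups of matched (transcript, total protein, phosphoprotein)
#' features, computes the univariate R-squared of each available layer
#' against sensitivity and summarizes which layer correlates best per
#' group.  Layers missing a feature (empty id or id absent from the
#' layer's matrix) are skipped and logged.
#'
#' @param groups Data frame with columns `gene_id`, `total_feature_id`,
#'   `phospho_feature_id` (empty string or `NA` allowed; `gene_id` doubles
#'   as the transcript feature id).
#' @param layers Named list of [feature_matrix] objects, names among
#'   `"transcript"`, `"total"`, `"phospho"`.
#' @param y [response_vector] aligned (by id) with the layer matrices.
#' @return A data frame of `CorrelationRecord` rows (`group`, `feature_id`,
#'   `layer`, `r_squared`, `slope_sign`) with attributes `skipped` (log of
#'   unresolvable layer/group pairs) and `winners` (best layer per group).
#' @export
correlation_table <- function(groups, layers, y) {
  stopifnot(is.data.frame(groups))
  id_col <- c(transcript = "gene_id", total = "total_feature_id",
              phospho = "phospho_feature_id")
  records <- list()
  skipped <- list()
  for (g in seq_len(nrow(groups))) {
    gname <- groups$gene_id[g]
    for (layer in names(id_col)) {
      fid <- groups[[id_col[[layer]]]][g]
      if (is.null(fid) || is.na(fid) || !nzchar(fid)) next
      fm <- layers[[layer]]
      if (is.null(fm) || !fid %in% colnames(fm$values)) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(group = gname, layer = layer, feature_id = fid,
                     stringsAsFactors = FALSE)
        next
      }
      ids <- intersect(sample_ids(fm), sample_ids(y))
      rec <- univariate_correlation(fm$values[ids, fid], y$auc[ids],
                                    feature_id = fid, layer = layer)
      rec$group <- gname
      records[[length(records) + 1L]] <- rec
    }
  }
  if (!length(records))
    stop("no resolvable feature in any layer for any group")
  out <- do.call(rbind, records)[, c("group", "feature_id", "layer",
                                     "r_squared", "slope_sign")]
  rownames(out) <- NULL
  winners <- do.call(rbind, lapply(split(out, out$group), function(d)
    data.frame(group = d$group[1], best_layer = d$layer[which.max(d$r_squared)],
               stringsAsFactors = FALSE)))
  rownames(winners) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
                          else data.frame(group = character(),
                                          layer = character(),
                                          feature_id = character())
  attr(out, "winners") <- winners
  out
}

#' Read a gene/total/phospho feature mapping file
#'
#' @param path Delimited file with columns `gene_id`, `total_feature_id`,
#'   `phospho_feature_id` (empty entries allowed).
#' @return Data frame suitable for [correlation_table()].
#' @export
read_feature_mapping <- function(path) {
  tab <- utils::read.table(path, sep = sep_of(path), header = TRUE,
                           stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need <- c("gene_id", "total_feature_id", "phospho_feature_id")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("mapping file lacks column(s): ", paste(miss, collapse = ", "))
  tab
}
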