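#' Specification for a synthetic RPPA-like dataset
#'
#' Describes the generative model used for validation: a latent predictive
#' direction (an affine function of a uniform \[0,1\] sensitivity AUC) loads
#' onto a small set of planted features with chosen signs, while an
#' independent response-orthogonal latent factor, driven by a binary tumor
#' type label, loads onto a second feature set — the structure the
#' orthogonal-component machinery of O-PLS exists to separate.  Feature
#' annotations (phospho fraction, receptor flags) and feature-biased
#' missingness emulate an RPPA panel.
#'
#' @param n_samples,n_features Matrix dimensions (defaults 30 x 200, the
#'   regime used throughout the package's recovery checks; the motivating
#'   data were 26 x 232).
#' @param planted_idx Indices of predictive features.
#' @param planted_signs Signs (+1 sensitivity- / -1 resistance-associated)
#'   of the planted loadings; default half and half.
#' @param orth_idx Indices of orthogonal-factor features.
#' @param orth_strength Orthogonal factor amplitude relative to the
#'   predictive signal (1 = comparable, 3 = dominating confound).
#' @param receptor_idx Indices flagged `is_receptor` (default the last 16
#'   features, disjoint from the planted set).
#' @param frac_phospho Fraction of features annotated as phospho.
#' @param noise_sd Additive Gaussian noise SD (0.45 puts the recoverable
#'   signal near R-squared 0.8 for 10 unit loadings).
#' @param missing_fraction Background missingness rate.
#' @param frac_poorly_detected Fraction of (non-planted, non-orthogonal,
#'   non-receptor) features made mostly missing, giving the 25% detection
#'   filter real work.
#' @param seed Integer seed; all randomness is drawn from this single seed
#'   in a fixed documented order.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 30, n_features = 200,
                           planted_idx = 1:10,
                           planted_signs = rep(c(1, -1), length.out = length(planted_idx)),
                           orth_idx = seq(max(planted_idx) + 1L,
                                          max(planted_idx) + 30L),
                           orth_strength = 1,
                           receptor_idx = seq(n_features - 15L, n_features),
                           frac_phospho = 0.25,
                           noise_sd = 0.45,
                           missing_fraction = 0.02,
                           frac_poorly_detected = 0.05,
                           seed = 1) {
  if (max(planted_idx, orth_idx, receptor_idx) > n_features)
    stop("feature index exceeds n_features")
  if (length(planted_signs) != length(planted_idx))
    stop("planted_signs and planted_idx differ in length")
  if (length(planted_idx) > n_features) stop("more planted features than features")
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate an RPPA-like feature matrix with planted ground truth
#'
#' Draws `y ~ Uniform(0, 1)`, forms the predictive latent score
#' `t = y - mean(y)`, an independent tumor-type-driven orthogonal score
#' `t_o`, and builds `X = t p' + t_o p_o' + noise` with the spec's planted
#' signed loadings, then applies feature-biased missingness.  Everything
#' needed to test recovery — loadings, scores, labels, planted ids — is
#' returned as ground truth.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `x` (a [feature_matrix]), `y` (a [response_vector])
#'   and `truth` (scores, loadings, planted/orthogonal feature ids and
#'   signs, tumor type labels).
#' @export
generate_rppa_like <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_samples; p <- spec$n_features
  feat_ids <- sprintf("F%03d", seq_len(p))
  samp_ids <- sprintf("CL%02d", seq_len(n))

  withr::with_seed(spec$seed, {
    # draw order is fixed: response, tumor labels, phospho assignment,
    # orthogonal loading signs, noise, poorly-detected set, missing mask.
    # y is uniform conditioned on a non-degenerate study: at least 4
    # resistant (< 0.2) and 4 sensitive lines, so every tumor-type x
    # resistance stratum below can hold >= 2 members
    y <- stats::runif(n)
    tries <- 0L
    while ((sum(y < 0.2) < 4 || sum(y >= 0.2) < 4) && tries < 100L) {
      y <- stats::runif(n)
      tries <- tries + 1L
    }
    # tumor type is balanced within each resistance class: marginally a
    # fair coin for every sample, hence independent of y
    resist <- y < 0.2
    tumor <- character(n)
    tumor[resist] <- sample(rep(c("melanoma", "non-melanoma"),
                                length.out = sum(resist)))
    tumor[!resist] <- sample(rep(c("melanoma", "non-melanoma"),
                                 length.out = sum(!resist)))
    phospho <- sample(seq_len(p), round(spec$frac_phospho * p))
    orth_signs <- sample(c(-1, 1), length(spec$orth_idx), replace = TRUE)

    t_pred <- y - mean(y)
    g <- ifelse(tumor == "melanoma", 1, -1)
    gc <- g - mean(g)
    t_orth <- spec$orth_strength * stats::sd(t_pred) * gc / stats::sd(gc)

    p_load <- numeric(p); p_load[spec$planted_idx] <- spec$planted_signs
    po_load <- numeric(p); po_load[spec$orth_idx] <- orth_signs

    X <- tcrossprod(t_pred, p_load) + tcrossprod(t_orth, po_load) +
      matrix(stats::rnorm(n * p, sd = spec$noise_sd), n, p)
    dimnames(X) <- list(samp_ids, feat_ids)

    protected <- unique(c(spec$planted_idx, spec$orth_idx, spec$receptor_idx))
    eligible <- setdiff(seq_len(p), protected)
    n_poor <- min(length(eligible), round(spec$frac_poorly_detected * p))
    poor <- if (n_poor > 0) sample(eligible, n_poor) else integer()
    miss_prob <- matrix(spec$missing_fraction, n, p)
    miss_prob[, poor] <- 0.95
    mask <- matrix(stats::runif(n * p) < miss_prob, n, p)
    X[mask] <- NA_real_
  })

  feat_ids_out <- feat_ids
  feat_ids_out[phospho] <- paste0(feat_ids[phospho], "_pY",
                                  100 + seq_along(phospho))
  colnames(X) <- feat_ids_out
  fmeta <- data.frame(
    feature_id = feat_ids_out,
    kind = ifelse(seq_len(p) %in% phospho, "phospho", "total"),
    is_receptor = seq_len(p) %in% spec$receptor_idx,
    stringsAsFactors = FALSE
  )
  smeta <- data.frame(sample_id = samp_ids, tumor_type = tumor,
                      stringsAsFactors = FALSE)
  x <- feature_matrix(X, fmeta, smeta)
  yv <- response_vector(samp_ids, y)
  truth <- list(
    t_pred = stats::setNames(t_pred, samp_ids),
    t_orth = stats::setNames(t_orth, samp_ids),
    p_load = stats::setNames(p_load, feat_ids_out),
    po_load = stats::setNames(po_load, feat_ids_out),
    planted_features = feat_ids_out[spec$planted_idx],
    planted_signs = spec$planted_signs,
    orth_features = feat_ids_out[spec$orth_idx],
    receptor_features = feat_ids_out[spec$receptor_idx],
    poorly_detected = feat_ids_out[poor],
    tumor_type = stats::setNames(tumor, samp_ids),
    spec = spec
  )
  list(x = x, y = yv, truth = truth)
}

#' Preset synthetic regimes
#'
#' `"default"`: planted predictive signal with a comparable orthogonal
#' factor; `"confounded"`: orthogonal factor 3x the predictive signal;
#' `"null"`: no planted predictive signal (loadings zero).
#'
#' @param preset One of `"default"`, `"confounded"`, `"null"`.
#' @param seed Integer seed.
#' @return A [synthetic_spec()].
#' @export
synthetic_preset <- function(preset = c("default", "confounded", "null"),
                             seed = 1) {
  preset <- match.arg(preset)
  switch(preset,
    default = synthetic_spec(seed = seed),
    confounded = synthetic_spec(orth_strength = 3, seed = seed),
    null = synthetic_spec(planted_signs = rep(0, 10), seed = seed)
  )
}

#' Generate a dose-response viability plate with known Hill parameters
#'
#' Inverts the percent-inhibition formula around a nominal vehicle signal:
#' treated wells get `blank + A_min (1 - y/100) + noise` with `y` from the
#' Hill curve; duplicate treated wells plus exact vehicle and blank wells
#' are included so the plate round-trips through [percent_inhibition()].
#'
#' @param true_ic50,true_hill Hill curve parameters to plant.
#' @param doses Positive dose vector (uM); wells are generated in
#'   duplicate per dose.
#' @param noise_sd Gaussian noise SD on treated wells, as percent of
#'   `A_min` (0 = noise-free).
#' @param seed Integer seed.
#' @param arm Arm label written into the plate.
#' @param a_min Nominal blank-corrected vehicle signal.
#' @param blank Nominal blank signal.
#' @param n_replicates Treated wells per dose.
#' @return A `plate_table` data frame; the planted parameters are attached
#'   as attribute `truth`.
#' @export
generate_dose_response <- function(true_ic50, true_hill, doses,
                                   noise_sd = 2, seed = 1, arm = "drug1",
                                   a_min = 10000, blank = 500,
                                   n_replicates = 2) {
  if (any(doses <= 0)) stop("doses must be positive")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  inh <- 100 / (1 + (true_ic50 / rep(doses, each = n_replicates))^true_hill)
  noise <- withr::with_seed(seed,
    stats::rnorm(length(inh), sd = noise_sd / 100 * a_min))
  treated <- data.frame(
    arm = arm, well_type = "treated",
    dose_uM = rep(doses, each = n_replicates),
    # treated wells cannot read below the blank level, so full inhibition
    # saturates at exactly 100% rather than overshooting under noise
    signal = pmax(blank, blank + a_min * (1 - inh / 100) + noise),
    stringsAsFactors = FALSE
  )
  fixed <- data.frame(
    arm = arm,
    well_type = rep(c("vehicle", "blank"), each = 2),
    dose_uM = 0,
    signal = rep(c(blank + a_min, blank), each = 2),
    stringsAsFactors = FALSE
  )
  out <- plate_table(rbind(fixed, treated))
  attr(out, "truth") <- list(ic50 = true_ic50, hill = true_hill,
                             a_min = a_min, blank = blank)
  out
}

#' Generate a mono/mono/combination dose-response experiment
#'
#' The combination arm is generated so that the true Loewe index of the
#' underlying curves equals `interaction`: with monotherapy IC50s X1, X2
#' and mixing ratio (r1, r2), the combination IC50 on drug 1's axis is
#' `C = interaction / (1/X1 + (r2/r1)/X2)`.  `interaction < 1` plants
#' synergy, `> 1` antagonism, `= 1` additivity (a sham combination).
#'
#' @param mono1,mono2 Named vectors `c(ic50 = , hill = )`.
#' @param interaction Positive Loewe index to plant.
#' @param ratio Mixing ratio `c(drug1, drug2)`, default 1:2.
#' @param doses1,doses2,doses_combo Dose series per arm (combo on drug 1's
#'   axis); defaults are 10-point 2-fold series echoing a 33/66 uM design.
#' @param noise_sd Treated-well noise, percent of the vehicle level.
#' @param seed Integer seed (each arm uses a fixed offset from it).
#' @return List with `plates` (drug1/drug2/combo) and `truth` (planted
#'   parameters including the combination IC50 and Loewe index).
#' @export
generate_combo_experiment <- function(mono1, mono2, interaction = 1,
                                      ratio = c(1, 2),
                                      doses1 = 33 / 2^(9:0),
                                      doses2 = 66 / 2^(9:0),
                                      doses_combo = 33 / 2^(9:0),
                                      noise_sd = 1, seed = 1) {
  if (interaction <= 0) stop("interaction must be positive")
  combo_ic50 <- interaction / (1 / mono1[["ic50"]] +
                               (ratio[2] / ratio[1]) / mono2[["ic50"]])
  combo_hill <- mean(c(mono1[["hill"]], mono2[["hill"]]))
  plates <- list(
    drug1 = generate_dose_response(mono1[["ic50"]], mono1[["hill"]], doses1,
                                   noise_sd, seed = seed + 11L, arm = "drug1"),
    drug2 = generate_dose_response(mono2[["ic50"]], mono2[["hill"]], doses2,
                                   noise_sd, seed = seed + 22L, arm = "drug2"),
    combo = generate_dose_response(combo_ic50, combo_hill, doses_combo,
                                   noise_sd, seed = seed + 33L, arm = "combo")
  )
  list(plates = plates,
       truth = list(combo_ic50 = combo_ic50, combo_hill = combo_hill,
                    loewe_index = interaction, ratio = ratio))
}

#' Write a synthetic dataset to a directory of delimited files
#'
#' Materializes a preset regime as the standard text formats the curation
#' pipeline consumes: `matrix.tsv`, `response.tsv`, `sample_meta.tsv`,
#' `annotations.tsv`, plus `truth.json`.
#'
#' @param preset Passed to [synthetic_preset()].
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
simulate_to_dir <- function(preset = "default", seed = 1, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_rppa_like(synthetic_preset(preset, seed))
  write_feature_matrix(sim$x, file.path(out_dir, "matrix.tsv"))
  utils::write.table(
    data.frame(sample_id = sim$y$sample_ids, auc = as.numeric(sim$y$auc)),
    file.path(out_dir, "response.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  utils::write.table(sim$x$sample_meta, file.path(out_dir, "sample_meta.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(sim$x$feature_meta, file.path(out_dir, "annotations.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(sim$truth[c("planted_features", "orth_features",
                                   "receptor_features")],
                       file.path(out_dir, "truth.json"))
  invisible(out_dir)
}
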