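#' Validate a viability plate table
#'
#' A plate table has one row per well with columns `arm` (`drug1`,
#' `drug2` or `combo`), `well_type` (`treated`, `vehicle`, `blank`),
#' `dose_uM` (0 for vehicle/blank) and `signal` (raw luminescence).
#'
#' @param plate Data frame to validate.
#' @return The validated data frame, invisibly classed `plate_table`.
#' @export
plate_table <- function(plate) {
  need <- c("arm", "well_type", "dose_uM", "signal")
  miss <- setdiff(need, names(plate))
  if (length(miss))
    stop("plate table lacks column(s): ", paste(miss, collapse = ", "))
  if (!any(plate$well_type == "vehicle") || !any(plate$well_type == "blank"))
    stop("plate needs at least one vehicle and one blank well")
  if (any(plate$dose_uM < 0)) stop("doses must be nonnegative")
  if (any(plate$signal < 0)) stop("signals must be nonnegative")
  class(plate) <- unique(c("plate_table", class(plate)))
  plate
}

#' Percent inhibition from raw plate signals
#'
#' Blank-corrects all signals, sets `A_min` to the blank-corrected vehicle
#' mean, and converts each treated well to percent inhibition
#' `y = (A_min - x) / A_min * 100`.  Duplicate wells are averaged per
#' dose.  Growth stimulation appears as negative inhibition.
#'
#' @param plate A [plate_table()]-conformant data frame (single arm).
#' @return Data frame with `dose_uM`, `inhibition` (percent) and
#'   `n_wells`, ordered by dose; `A_min` is attached as an attribute.
#' @export
percent_inhibition <- function(plate) {
  plate <- plate_table(plate)
  blank <- mean(plate$signal[plate$well_type == "blank"])
  a_min <- mean(plate$signal[plate$well_type == "vehicle"]) - blank
  if (a_min <= 0)
    stop("blank-corrected vehicle mean is not positive; plate uninterpretable")
  tr <- plate[plate$well_type == "treated", , drop = FALSE]
  x <- tr$signal - blank
  inh <- (a_min - x) / a_min * 100
  agg <- stats::aggregate(inh, by = list(dose_uM = tr$dose_uM), FUN = mean)
  cnt <- stats::aggregate(inh, by = list(dose_uM = tr$dose_uM), FUN = length)
  out <- data.frame(dose_uM = agg$dose_uM, inhibition = agg$x,
                    n_wells = cnt$x)
  out <- out[order(out$dose_uM), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "A_min") <- a_min
  out
}

#' Fit a Hill dose-response curve
#'
#' Least-squares fit of the fixed-asymptote log-inhibitor model
#' \deqn{y = 100 / (1 + (IC_{50}/x)^{Hill})}
#' to percent-inhibition data.  Initialization takes IC50 from the dose
#' whose inhibition is nearest 50% (geometric mean of the dose range as a
#' fallback) and Hill = 1; the optimization is bounded with IC50 in
#' \[min dose/100, 100 max dose\] and Hill in \[0.1, 10\].  Fits that fail
#' to converge or whose IC50 sits at a bound (as happens when the IC50
#' exceeds the tested range) are flagged unreliable.
#'
#' @param doses Positive dose vector (uM).
#' @param inhibition Percent inhibition at each dose (values above 100 are
#'   rejected; negative values participate in the fit).
#' @return An object of class `hill_fit` with `ic50`, `hill`, `sse`,
#'   `fitted`, `reliable` and `diagnostics`.
#' @export
fit_hill <- function(doses, inhibition) {
  doses <- as.numeric(doses); inhibition <- as.numeric(inhibition)
  if (length(doses) != length(inhibition)) stop("length mismatch")
  keep <- doses > 0
  doses <- doses[keep]; inhibition <- inhibition[keep]
  if (length(unique(doses)) < 4)
    stop("need at least 4 distinct nonzero doses")
  if (any(inhibition > 100 + 1e-9))
    stop("inhibition above 100% is not representable by the model")

  lo <- c(ic50 = min(doses) / 100, hill = 0.1)
  hi <- c(ic50 = max(doses) * 100, hill = 10)
  near50 <- which.min(abs(inhibition - 50))
  ic50_0 <- doses[near50]
  if (!is.finite(ic50_0) || diff(range(inhibition)) < 1e-8)
    ic50_0 <- sqrt(min(doses) * max(doses))
  dat <- data.frame(x = doses, y = inhibition)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 100 / (1 + (ic50 / x)^hill), data = dat,
                      start = list(ic50 = ic50_0, hill = 1),
                      lower = lo, upper = hi,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(list(ic50 = NA_real_, hill = NA_real_, sse = NA_real_,
                          fitted = NULL, reliable = FALSE,
                          diagnostics = list(converged = FALSE,
                                             message = conditionMessage(fit)),
                          doses = doses, inhibition = inhibition),
                     class = "hill_fit"))
  }
  est <- stats::coef(fit)
  at_bound <- est["ic50"] <= lo["ic50"] * 1.01 || est["ic50"] >= hi["ic50"] * 0.99
  structure(list(
    ic50 = unname(est["ic50"]), hill = unname(est["hill"]),
    sse = sum(stats::residuals(fit)^2),
    fitted = stats::fitted(fit),
    reliable = !at_bound,
    diagnostics = list(converged = TRUE, at_bound = at_bound,
                       iterations = fit$convInfo$finIter),
    doses = doses, inhibition = inhibition
  ), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (is.na(x$ic50)) cat("<hill_fit> non-convergent (unreliable)\n")
  else cat(sprintf("<hill_fit> IC50 = %.4g uM, Hill = %.3g, SSE = %.3g%s\n",
                   x$ic50, x$hill, x$sse,
                   if (x$reliable) "" else " [unreliable]"))
  invisible(x)
}

#' Evaluate a Hill curve at given doses
#' @param object A `hill_fit`.
#' @param doses Dose vector (uM).
#' @param ... Unused.
#' @return Percent inhibition at each dose.
#' @export
predict.hill_fit <- function(object, doses, ...) {
  100 / (1 + (object$ic50 / doses)^object$hill)
}

#' Normalized area under a dose-response inhibition curve
#'
#' Defines the sensitivity AUC used for synthetic curves: the trapezoidal
#' integral of fractional inhibition (clipped to \[0, 1\]) over log10 dose,
#' divided by the log10 width of the dose range.  Bounded in \[0, 1\];
#' higher means more sensitive.
#'
#' @param curve Either a `hill_fit` (evaluated on a fine log-spaced grid)
#'   or a data frame with `dose_uM` and `inhibition` columns.
#' @param dose_range Length-2 positive vector, min < max (uM).
#' @param n_grid Grid size for evaluating a `hill_fit`.
#' @return AUC in \[0, 1\].
#' @export
auc_from_curve <- function(curve, dose_range, n_grid = 401) {
  if (length(dose_range) != 2 || any(dose_range <= 0) ||
      dose_range[1] >= dose_range[2])
    stop("dose_range must be positive with min < max")
  lr <- log10(dose_range)
  if (inherits(curve, "hill_fit")) {
    lx <- seq(lr[1], lr[2], length.out = n_grid)
    frac <- predict(curve, 10^lx) / 100
  } else {
    keep <- curve$dose_uM >= dose_range[1] & curve$dose_uM <= dose_range[2]
    d <- curve[keep, , drop = FALSE]
    d <- d[order(d$dose_uM), , drop = FALSE]
    if (nrow(d) < 2) stop("fewer than 2 curve points inside dose range")
    lx <- log10(d$dose_uM)
    frac <- d$inhibition / 100
  }
  frac <- pmin(pmax(frac, 0), 1)
  sum(diff(lx) * (utils::head(frac, -1) + utils::tail(frac, -1)) / 2) /
    (lr[2] - lr[1])
}

#' Loewe additivity index for a fixed-ratio drug combination
#'
#' \deqn{index = x^1 / X^1_{LOEWE} + x^2 / X^2_{LOEWE}}
#' where X^1, X^2 are the monotherapy IC50s and x^1, x^2 the per-drug
#' concentrations at the combination's IC50.  The combination curve is
#' fitted against drug 1's concentration axis; its IC50 is split by the
#' declared mixing ratio (a 1:2 ratio means drug 2 is dosed at twice drug
#' 1's concentration in every combination well).  Values below 1 indicate
#' synergy.
#'
#' @param mono1,mono2 `hill_fit` objects for the monotherapy arms.
#' @param combo `hill_fit` for the combination arm on drug 1's dose axis.
#' @param ratio Length-2 numeric mixing ratio `c(drug1, drug2)`,
#'   default `c(1, 2)`.
#' @return A list of class `synergy_result`: component concentrations,
#'   monotherapy IC50s, `loewe_index` and logical `synergy`.
#' @export
loewe_index <- function(mono1, mono2, combo, ratio = c(1, 2)) {
  fits <- list(mono1 = mono1, mono2 = mono2, combo = combo)
  bad <- names(fits)[!vapply(fits, function(f) isTRUE(f$reliable), logical(1))]
  if (length(bad))
    stop("unreliable fit(s): ", paste(bad, collapse = ", "),
         "; no synergy index computed")
  if (length(ratio) != 2 || any(ratio <= 0)) stop("invalid mixing ratio")
  x1 <- combo$ic50
  x2 <- combo$ic50 * ratio[2] / ratio[1]
  idx <- x1 / mono1$ic50 + x2 / mono2$ic50
  structure(list(x1 = x1, x2 = x2,
                 X1_loewe = mono1$ic50, X2_loewe = mono2$ic50,
                 ratio = ratio, loewe_index = idx, synergy = idx < 1),
            class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf("<synergy_result> Loewe index = %.3f (%s)\n", x$loewe_index,
              if (x$synergy) "synergy" else "no synergy"))
  invisible(x)
}

#' Full plate-to-synergy analysis for a mono/mono/combo experiment
#'
#' Convenience wrapper: computes percent inhibition for each arm, fits
#' Hill curves, and scores Loewe additivity.
#'
#' @param plates Named list of plate tables: `drug1`, `drug2`, `combo`
#'   (combo doses on drug 1's axis).
#' @param ratio Mixing ratio `c(drug1, drug2)`.
#' @return List with per-arm `inhibition` tables, `fits`, and the
#'   `synergy_result`.
#' @export
analyze_synergy <- function(plates, ratio = c(1, 2)) {
  need <- c("drug1", "drug2", "combo")
  miss <- setdiff(need, names(plates))
  if (length(miss)) stop("missing plate(s): ", paste(miss, collapse = ", "))
  inh <- lapply(plates[need], percent_inhibition)
  fits <- lapply(inh, function(d) fit_hill(d$dose_uM, d$inhibition))
  list(inhibition = inh, fits = fits,
       synergy = loewe_index(fits$drug1, fits$drug2, fits$combo, ratio))
}
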