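# Degradation pharmacology: % inhibition, 4PL fits, DC50/Dmax/GI50, V/D ----

#' Percent inhibition relative to assay controls
#'
#' `%inhibition = (high_ctrl - sample) / (high_ctrl - low_ctrl) * 100`.
#' Values outside \[0, 100\] are reported as-is (not clipped); the result is
#' invariant under affine transforms applied jointly to sample and controls.
#'
#' @param sample Raw activity value(s).
#' @param high_ctrl Uninhibited (high) control.
#' @param low_ctrl Fully inhibited (low) control.
#' @return Percent inhibition, vectorized over `sample`.
#' @examples
#' percent_inhibition(25, high_ctrl = 100, low_ctrl = 0)  # 75
#' @export
percent_inhibition <- function(sample, high_ctrl, low_ctrl) {
  if (any(high_ctrl == low_ctrl)) {
    stop("high_ctrl and low_ctrl must differ")
  }
  (high_ctrl - sample) / (high_ctrl - low_ctrl) * 100
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `y = bottom + (top - bottom) / (1 + (x/ec50)^hill)`
#' by Levenberg-Marquardt, initialized from the data (plateau means at the
#' dose extremes, midpoint from the dose bracketing half-response). For
#' DMSO-normalized descending degradation data the derived quantities are
#' `rel_dc50` (= `ec50`, the curve midpoint), `abs_dc50` (the dose where the
#' fitted curve crosses 0.5, absent when 0.5 is outside the fitted
#' plateaus, solved analytically) and `dmax = 1 - bottom` (maximal fitted
#' degradation).
#'
#' @param doses Positive doses, at least 4 distinct values.
#' @param responses Responses (same length as `doses`).
#' @return Object of class `dose_response_fit` with fields `bottom`, `top`,
#'   `ec50`, `hill`, `rel_dc50`, `abs_dc50`, `dmax`, `rss`, `n`.
#' @examples
#' d <- simulate_dose_response(0.1, 1, ec50 = 0.09, hill = 1,
#'                             doses = 10^seq(-3, 1, length.out = 8))
#' fit_4pl(d$dose, d$response)
#' @export
fit_4pl <- function(doses, responses) {
  stopifnot(length(doses) == length(responses))
  keep <- is.finite(doses) & is.finite(responses)
  x <- doses[keep]; y <- responses[keep]
  if (any(x <= 0)) stop("doses must be positive")
  if (length(unique(x)) < 4L) {
    stop("need at least 4 distinct dose levels, got ", length(unique(x)))
  }
  xs <- sort(unique(x))
  mu <- vapply(xs, function(v) mean(y[x == v]), numeric(1))
  descending <- stats::cor(log(xs), mu) < 0
  lo_end <- mu[[1]]; hi_end <- mu[[length(mu)]]
  top0 <- if (descending) lo_end else hi_end
  bottom0 <- if (descending) hi_end else lo_end
  half <- (top0 + bottom0) / 2
  ec50_0 <- xs[which.min(abs(mu - half))]
  hill0 <- if (descending) 1 else -1
  fn <- function(p) y - (p[1] + (p[2] - p[1]) / (1 + (x / exp(p[3]))^p[4]))
  fit <- minpack.lm::nls.lm(
    par = c(bottom0, top0, log(ec50_0), hill0), fn = fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  if (!fit$info %in% 1:4) {
    stop("4PL fit failed to converge: ", fit$message,
         " (n = ", length(x), ", RSS = ", signif(fit$deviance, 4), ")")
  }
  bottom <- fit$par[1]; top <- fit$par[2]
  ec50 <- exp(fit$par[3]); hill <- fit$par[4]
  if (bottom > top) {  # same curve with plateaus swapped and slope negated
    tmp <- bottom; bottom <- top; top <- tmp; hill <- -hill
  }
  abs_dc50 <- if (bottom < 0.5 && top > 0.5) {
    ec50 * ((top - 0.5) / (0.5 - bottom))^(1 / hill)
  } else {
    NA_real_
  }
  structure(list(bottom = bottom, top = top, ec50 = ec50, hill = hill,
                 rel_dc50 = ec50, abs_dc50 = abs_dc50,
                 dmax = 1 - bottom,
                 rss = fit$deviance, n = length(x)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("dose_response_fit (n=%d): bottom=%.4g top=%.4g ec50=%.4g hill=%.3g\n",
              x$n, x$bottom, x$top, x$ec50, x$hill))
  cat(sprintf("  rel DC50=%.4g  abs DC50=%s  Dmax=%.3g  RSS=%.3g\n",
              x$rel_dc50,
              if (is.na(x$abs_dc50)) "absent" else sprintf("%.4g", x$abs_dc50),
              x$dmax, x$rss))
  invisible(x)
}

#' Predict from a fitted four-parameter logistic curve
#'
#' @param object A `dose_response_fit`.
#' @param doses Doses at which to evaluate the fitted curve.
#' @param ... Unused.
#' @return Fitted responses.
#' @export
predict.dose_response_fit <- function(object, doses, ...) {
  four_pl(doses, object$bottom, object$top, object$ec50, object$hill)
}

#' Ratiometric degradation from dual-fluorescence medians
#'
#' `degradation = 1 - ((gfp - bg_gfp)/(mch - bg_mch)) / dmso_ratio`, i.e.
#' the fractional loss of the background-subtracted GFP/mCherry ratio
#' relative to the untreated (DMSO) ratio. When technical replicates are
#' summarized upstream, medians are taken first and the ratio formed from
#' the medians. Wells with mCherry at or below background are undefined and
#' returned as `NA` with a warning.
#'
#' @param gfp,mch Median GFP and mCherry signals (vectorized).
#' @param bg_gfp,bg_mch Background fluorescence of the parental line.
#' @param dmso_ratio Background-subtracted ratio of the DMSO control;
#'   positive.
#' @return Fractional degradation (0 = no change, 1 = complete loss).
#' @export
ratiometric_degradation <- function(gfp, mch, bg_gfp, bg_mch, dmso_ratio) {
  stopifnot(dmso_ratio > 0)
  bad <- mch <= bg_mch
  if (any(bad)) {
    warning(sum(bad), " observation(s) with mCherry at or below background; ",
            "degradation undefined (NA)")
  }
  out <- 1 - ((gfp - bg_gfp) / (mch - bg_mch)) / dmso_ratio
  out[bad] <- NA_real_
  out
}

#' Relative viability from the viable-cell gate, with exclusion floor
#'
#' `rel_viability = (viable_count / total_count) / dmso_fraction`. Doses
#' whose relative viability falls below `floor` (default 25 percent of the
#' DMSO viable fraction) are flagged `excluded` and should not enter the
#' degradation fit: too few viable cells remain for a reliable ratiometric
#' readout.
#'
#' @param viable_count,total_count Cell counts inside / in total for the
#'   viable gate (vectorized); `total_count` must be positive.
#' @param dmso_fraction Viable-gate fraction of the DMSO control.
#' @param floor Minimal relative viability for inclusion.
#' @return Data frame with `rel_viability` and `excluded`.
#' @export
viability_from_gate <- function(viable_count, total_count, dmso_fraction,
                                floor = 0.25) {
  if (any(total_count <= 0)) stop("total_count must be positive")
  stopifnot(all(viable_count >= 0), dmso_fraction > 0)
  rel <- (viable_count / total_count) / dmso_fraction
  data.frame(rel_viability = rel, excluded = rel < floor)
}

#' Viability/degradation window (V/D) score
#'
#' `vd = GI50 / DC50`, the fold difference between the viability midpoint
#' and the degradation midpoint; values above 1 mean degradation occurs at
#' concentrations below toxicity. When either fit yielded no midpoint, the
#' top assessed dose substitutes for the missing value and the corresponding
#' fallback flag is set.
#'
#' @param gi50 Viability GI50, or `NA`/`NULL` when absent.
#' @param dc50 Degradation DC50, or `NA`/`NULL` when absent.
#' @param top_dose Highest dose assessed; positive.
#' @return Object of class `viability_window` with `vd_score`, the inputs
#'   used, and `gi50_fallback_used` / `dc50_fallback_used` flags.
#' @examples
#' vd_score(gi50 = 1.20, dc50 = 0.09, top_dose = 25)  # 13.3
#' @export
vd_score <- function(gi50, dc50, top_dose) {
  stopifnot(top_dose > 0)
  gi_absent <- is.null(gi50) || is.na(gi50)
  dc_absent <- is.null(dc50) || is.na(dc50)
  numerator <- if (gi_absent) top_dose else gi50
  denominator <- if (dc_absent) top_dose else dc50
  stopifnot(numerator > 0, denominator > 0)
  structure(list(gi50 = if (gi_absent) NA_real_ else gi50,
                 dc50 = if (dc_absent) NA_real_ else dc50,
                 top_dose = top_dose,
                 vd_score = numerator / denominator,
                 gi50_fallback_used = gi_absent,
                 dc50_fallback_used = dc_absent),
            class = "viability_window")
}

#' @export
print.viability_window <- function(x, ...) {
  cat(sprintf("viability_window: V/D = %.4g (GI50 %s%s / DC50 %s%s)\n",
              x$vd_score,
              if (x$gi50_fallback_used) "top dose " else "",
              if (x$gi50_fallback_used) x$top_dose else x$gi50,
              if (x$dc50_fallback_used) "top dose " else "",
              if (x$dc50_fallback_used) x$top_dose else x$dc50))
  invisible(x)
}

#' Dual-reporter signal ratio relative to the DMSO control
#'
#' `(hibit / firefly) / (dmso_hibit / dmso_firefly)`: the target-reporter
#' signal normalized for cell number, relative to untreated cells. 1 means
#' no change (full rescue); values near `1 - d` reflect degradation of a
#' fraction `d`.
#'
#' @param hibit,firefly Treated-well reporter signals; positive.
#' @param dmso_hibit,dmso_firefly Untreated (DMSO) reporter signals;
#'   positive.
#' @return Relative dual-reporter ratio, vectorized.
#' @export
dual_reporter_ratio <- function(hibit, firefly, dmso_hibit, dmso_firefly) {
  if (any(c(firefly, dmso_hibit, dmso_firefly) <= 0) || any(hibit <= 0)) {
    stop("all signals must be positive")
  }
  (hibit / firefly) / (dmso_hibit / dmso_firefly)
}
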