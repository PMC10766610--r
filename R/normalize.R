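# QC gate, plate-wise HiBiT~Firefly polynomial normalization, robust z ------

plate_key <- function(wells) paste(wells$plate_id, wells$replicate_id, sep = "/")

#' Firefly quality-control gate
#'
#' For each assay plate (plate x replicate), the Firefly reference is the
#' median Firefly signal of that plate's media-only and uninfected
#' (puromycin-killed) control wells. Each well's `firefly_log10_ratio` is
#' log10(firefly / reference); wells pass QC when the ratio exceeds
#' `min_log10_ratio` (default log10(1.25), i.e. at least 25 percent more
#' Firefly signal than background). Failing wells are excluded from all
#' downstream fitting and ranking.
#'
#' @param wells Plate-well data frame (see [read_plate_table()]).
#' @param min_log10_ratio QC threshold on the log10 Firefly ratio.
#' @return The input with columns `firefly_log10_ratio` and `qc_pass` added
#'   (`qc_reason` records why a well failed).
#' @export
firefly_qc <- function(wells, min_log10_ratio = log10(1.25)) {
  wells <- validate_plate_wells(wells)
  key <- plate_key(wells)
  is_bg <- wells$well_class %in% c("media_ctrl", "uninfected_ctrl")
  ref <- tapply(wells$firefly_rlu[is_bg], key[is_bg], stats::median)
  missing_ref <- setdiff(unique(key), names(ref))
  if (length(missing_ref) > 0L) {
    stop("plate(s) without media/uninfected control wells: ",
         paste(missing_ref, collapse = ", "))
  }
  reference <- unname(ref[key])
  ratio <- log10(wells$firefly_rlu / reference)
  wells$firefly_log10_ratio <- ratio
  wells$qc_pass <- is.finite(ratio) & ratio > min_log10_ratio
  wells$qc_reason <- ifelse(wells$qc_pass, "",
                            "firefly_below_threshold")
  wells
}

#' Fit the per-plate HiBiT~Firefly polynomial
#'
#' Ordinary least-squares degree-3 polynomial of HiBiT on Firefly over the
#' plate's QC-passing library wells. With `robustify = TRUE` (default) a
#' single re-fit pass removes points whose absolute residual exceeds 3
#' scaled-MADs of the residuals, so the rare strong-rescue wells do not bend
#' the plate baseline.
#'
#' @param wells Wells of one assay plate, after [firefly_qc()].
#' @param robustify Apply the one-pass robust re-fit.
#' @return An object of class `plate_polynomial`: plate/replicate
#'   identifiers, the 4 polynomial coefficients (intercept to cubic), the
#'   Firefly `fit_domain`, and `n_points_used`.
#' @export
fit_plate_polynomial <- function(wells, robustify = TRUE) {
  keys <- unique(plate_key(wells))
  if (length(keys) != 1L) {
    stop("fit_plate_polynomial expects wells of a single assay plate; got ",
         length(keys))
  }
  use <- wells$well_class == "library" & wells$qc_pass
  x <- wells$firefly_rlu[use]
  y <- wells$hibit_rlu[use]
  if (length(x) < 5L) {
    stop("too few QC-passing library wells to fit a cubic (", length(x),
         " < 5) on plate ", keys)
  }
  if (length(x) < 20L) {
    warning("only ", length(x), " QC-passing library wells on plate ", keys,
            "; cubic fit may be unstable")
  }
  if (length(unique(x)) < 4L) {
    stop("singular design: fewer than 4 distinct Firefly values on plate ",
         keys)
  }
  fit <- stats::lm(y ~ x + I(x^2) + I(x^3))
  kept <- rep(TRUE, length(x))
  if (robustify) {
    res <- stats::residuals(fit)
    s <- stats::mad(res)
    # engage only when residual scale is above numerical noise, so an exact
    # polynomial relation is never trimmed
    if (s > 1e-8 * stats::median(abs(y))) {
      kept <- abs(res) <= 3 * s
      if (sum(kept) >= 5L && length(unique(x[kept])) >= 4L && any(!kept)) {
        fit <- stats::lm(y[kept] ~ x[kept] + I(x[kept]^2) + I(x[kept]^3))
      } else {
        kept <- rep(TRUE, length(x))
      }
    }
  }
  structure(
    list(plate_id = wells$plate_id[1],
         replicate_id = wells$replicate_id[1],
         coefficients = unname(stats::coef(fit)),
         fit_domain = range(x[kept]),
         n_points_used = sum(kept)),
    class = "plate_polynomial")
}

#' @export
print.plate_polynomial <- function(x, ...) {
  cat(sprintf("plate_polynomial %s/%s: n=%d, domain=[%.4g, %.4g]\n",
              x$plate_id, x$replicate_id, x$n_points_used,
              x$fit_domain[1], x$fit_domain[2]))
  cat("  coefficients:", sprintf("%.6g", x$coefficients), "\n")
  invisible(x)
}

#' Fit HiBiT~Firefly polynomials for every assay plate
#'
#' @param wells Plate-well data frame after [firefly_qc()].
#' @param robustify Passed to [fit_plate_polynomial()].
#' @return Named list of `plate_polynomial` objects, keyed by
#'   `plate_id/replicate_id`.
#' @export
fit_plate_polynomials <- function(wells, robustify = TRUE) {
  key <- plate_key(wells)
  lapply(split(wells, key), fit_plate_polynomial, robustify = robustify)
}

predict_polynomial <- function(poly, firefly) {
  x <- pmin(pmax(firefly, poly$fit_domain[1]), poly$fit_domain[2])
  list(predicted = eval_cubic(poly$coefficients, x),
       clamped = firefly < poly$fit_domain[1] | firefly > poly$fit_domain[2])
}

#' Normalize wells against the plate polynomials
#'
#' Each QC-passing well's `predicted_hibit` is the plate polynomial evaluated
#' at its Firefly signal (values outside the fit domain are clamped to the
#' domain edge and flagged); `rel_change = hibit_rlu / predicted_hibit`
#' removes the Firefly-coupled (cell-number and plate) variation. Robust
#' z-scores of `rel_change` are computed among QC-passing library wells, per
#' assay plate by default.
#'
#' @param wells Plate-well data frame after [firefly_qc()].
#' @param polynomials Named list from [fit_plate_polynomials()].
#' @param z_scope `"plate"` (robust z within each assay plate, the default)
#'   or `"global"` (across the whole screen).
#' @return Normalized-well data frame with `predicted_hibit`, `rel_change`,
#'   `domain_clamped` and `robust_z` columns added. Wells with a
#'   non-positive prediction are flagged `qc_pass = FALSE` with reason
#'   `"nonpositive_prediction"`, not dropped.
#' @export
normalize_wells <- function(wells, polynomials,
                            z_scope = c("plate", "global")) {
  z_scope <- match.arg(z_scope)
  if (is.null(wells$qc_pass)) {
    stop("run firefly_qc() before normalize_wells()")
  }
  key <- plate_key(wells)
  missing <- setdiff(unique(key[wells$qc_pass]), names(polynomials))
  if (length(missing) > 0L) {
    stop("no plate polynomial for plate(s): ", paste(missing, collapse = ", "))
  }
  wells$predicted_hibit <- NA_real_
  wells$rel_change <- NA_real_
  wells$domain_clamped <- FALSE
  for (k in intersect(unique(key), names(polynomials))) {
    idx <- key == k & wells$qc_pass
    pr <- predict_polynomial(polynomials[[k]], wells$firefly_rlu[idx])
    wells$predicted_hibit[idx] <- pr$predicted
    wells$domain_clamped[idx] <- pr$clamped
    wells$rel_change[idx] <- wells$hibit_rlu[idx] / pr$predicted
  }
  bad <- wells$qc_pass & !is.na(wells$predicted_hibit) &
    wells$predicted_hibit <= 0
  if (any(bad)) {
    wells$qc_pass[bad] <- FALSE
    wells$qc_reason[bad] <- "nonpositive_prediction"
    wells$rel_change[bad] <- NA_real_
  }
  wells$robust_z <- NA_real_
  scorable <- wells$qc_pass & wells$well_class == "library" &
    is.finite(wells$rel_change)
  if (z_scope == "plate") {
    for (k in unique(key[scorable])) {
      idx <- scorable & key == k
      wells$robust_z[idx] <- robust_zscore(wells$rel_change[idx])
    }
  } else {
    wells$robust_z[scorable] <- robust_zscore(wells$rel_change[scorable])
  }
  wells
}

#' QC, fit and normalize in one step
#'
#' Convenience wrapper running [firefly_qc()], [fit_plate_polynomials()] and
#' [normalize_wells()].
#'
#' @inheritParams firefly_qc
#' @inheritParams normalize_wells
#' @param robustify Passed to [fit_plate_polynomials()].
#' @return List with `wells` (normalized-well data frame) and `polynomials`.
#' @export
normalize_screen <- function(wells, min_log10_ratio = log10(1.25),
                             robustify = TRUE,
                             z_scope = c("plate", "global")) {
  wells <- firefly_qc(wells, min_log10_ratio = min_log10_ratio)
  polys <- fit_plate_polynomials(wells, robustify = robustify)
  list(wells = normalize_wells(wells, polys, z_scope = match.arg(z_scope)),
       polynomials = polys)
}

#' Robust z-score
#'
#' `z = (x - median(x)) / (1.4826 * MAD)` where MAD is the raw median
#' absolute deviation. If the MAD is zero the scale falls back to the
#' standard deviation; if that is also zero all scores are zero.
#'
#' @param values Numeric vector with at least 5 finite values.
#' @return Numeric vector of robust z-scores (same length as the input).
#' @examples
#' robust_zscore(c(0, 1, 2, 3, 4))
#' @export
robust_zscore <- function(values) {
  x <- as.numeric(values)
  if (sum(is.finite(x)) < 5L) {
    stop("robust_zscore needs at least 5 finite values")
  }
  med <- stats::median(x, na.rm = TRUE)
  s <- stats::mad(x, center = med, na.rm = TRUE)  # 1.4826 * raw MAD
  if (s == 0) s <- stats::sd(x, na.rm = TRUE)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - med) / s
}
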