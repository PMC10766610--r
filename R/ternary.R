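# Ternary-complex biophysics: hook-effect isotherm, off-rate, cooperativity,
# initial velocities ---------------------------------------------------------

bell_model <- function(c_, kd1, kd2, rmax) {
  rmax * c_ / (kd1 + c_) * kd2 / (kd2 + c_)
}

#' Fit a bell-shaped (hook-effect) ternary-complex isotherm
#'
#' Least-squares fit of the product-of-hyperbolas model
#' `R(c) = rmax * c/(kd_rise + c) * kd_fall/(kd_fall + c)`: an ascending
#' transition with apparent K_D `kd_app_rise` (ternary assembly) and a
#' descending transition with apparent K_D `kd_app_fall` (binary complexes
#' outcompeting the ternary at saturating ligand). On a log concentration
#' axis the model shows exactly two separated sigmoidal transitions, and the
#' noise-free curve peaks at the geometric mean `sqrt(kd_rise * kd_fall)`.
#' Parameters are canonically ordered (`kd_app_rise <= kd_app_fall`, the
#' model is invariant under the swap with `rmax` rescaled). With
#' `free_hill = TRUE` both transitions get free Hill slopes.
#'
#' @param concentrations Positive analyte concentrations, at least 6,
#'   spanning the peak.
#' @param responses Steady-state responses.
#' @param free_hill Allow free Hill slopes on both transitions.
#' @return Object of class `ternary_fit`: `kd_app_rise`, `kd_app_fall`,
#'   `rmax`, `peak_conc`, optional `hill_rise`/`hill_fall`, `rss`, `n`.
#' @examples
#' iso <- simulate_ternary_isotherm(0.01, 1, rmax = 50,
#'                                  concentrations = 10^seq(-4, 2, 0.5))
#' fit_bell(iso$conc, iso$response)
#' @export
fit_bell <- function(concentrations, responses, free_hill = FALSE) {
  stopifnot(length(concentrations) == length(responses))
  keep <- is.finite(concentrations) & is.finite(responses)
  x <- concentrations[keep]; y <- responses[keep]
  if (any(x <= 0)) stop("concentrations must be positive")
  if (length(unique(x)) < 6L) stop("need at least 6 concentrations")
  xs <- sort(unique(x))
  ys <- vapply(xs, function(v) mean(y[x == v]), numeric(1))
  i_pk <- which.max(ys)
  if (i_pk <= 1L || i_pk >= length(ys) ||
      ys[length(ys)] > 0.9 * ys[i_pk]) {
    stop("no hook effect detected (response does not rise then fall); ",
         "consider a binary (single-site) binding model")
  }
  peak0 <- xs[i_pk]
  half <- ys[i_pk] / 2
  rise <- xs[xs < peak0]
  fall <- xs[xs > peak0]
  kd1_0 <- if (length(rise) > 0) {
    rise[which.min(abs(ys[xs < peak0] - half))]
  } else peak0 / 10
  kd2_0 <- if (length(fall) > 0) {
    fall[which.min(abs(ys[xs > peak0] - half))]
  } else peak0 * 10
  rmax0 <- ys[i_pk] / (peak0 / (kd1_0 + peak0) * kd2_0 / (kd2_0 + peak0))
  # K_Ds and rmax stay positive through the log parameterization
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                     ptol = 1e-14)
  if (!free_hill) {
    fn <- function(p) {
      y - exp(p[3]) * x / (exp(p[1]) + x) * exp(p[2]) / (exp(p[2]) + x)
    }
    fit <- minpack.lm::nls.lm(
      par = c(log(kd1_0), log(kd2_0), log(rmax0)), fn = fn, control = ctrl)
    h1 <- h2 <- 1
  } else {
    fn <- function(p) {
      k1 <- exp(p[1]); k2 <- exp(p[2])
      y - exp(p[3]) * x^p[4] / (k1^p[4] + x^p[4]) *
        k2^p[5] / (k2^p[5] + x^p[5])
    }
    fit <- minpack.lm::nls.lm(
      par = c(log(kd1_0), log(kd2_0), log(rmax0), 1, 1),
      fn = fn, control = ctrl)
  }
  if (!fit$info %in% 1:4) {
    stop("bell fit failed to converge: ", fit$message)
  }
  kd1 <- exp(fit$par[1]); kd2 <- exp(fit$par[2]); rmax <- exp(fit$par[3])
  if (free_hill) { h1 <- fit$par[4]; h2 <- fit$par[5] }
  if (kd1 > kd2) {
    if (!free_hill) {
      # swap invariance: R(c; a, b, r) == R(c; b, a, r * b / a)
      rmax <- rmax * kd2 / kd1
    }
    tmp <- kd1; kd1 <- kd2; kd2 <- tmp
    tmp <- h1; h1 <- h2; h2 <- tmp
  }
  structure(list(kd_app_rise = kd1, kd_app_fall = kd2, rmax = rmax,
                 peak_conc = sqrt(kd1 * kd2),
                 hill_rise = h1, hill_fall = h2,
                 rss = fit$deviance, n = length(x)),
            class = "ternary_fit")
}

#' @export
print.ternary_fit <- function(x, ...) {
  cat(sprintf("ternary_fit (n=%d): Kd(app, rise)=%.4g  Kd(app, fall)=%.4g\n",
              x$n, x$kd_app_rise, x$kd_app_fall))
  cat(sprintf("  rmax=%.4g  peak at %.4g  RSS=%.3g\n",
              x$rmax, x$peak_conc, x$rss))
  invisible(x)
}

#' Fit a restricted 1:1 dissociation trace
#'
#' Fits `R(t) = baseline + amplitude * exp(-koff * t)` to a dissociation
#' trace. By the ternary-complex convention, only traces from the analyte
#' concentrations contributing to the lower-concentration (ternary)
#' transition should be supplied. The residence time is reported as the
#' inversion of the off-rate (`1/koff`); `convention = "half_life"` instead
#' reports `ln(2)/koff` and flags it.
#'
#' @param time Strictly increasing time points (seconds).
#' @param response Response trace; must decay.
#' @param convention `"inverse"` (default) or `"half_life"`.
#' @return Object of class `dissociation_fit`: `koff` (1/s),
#'   `residence_time` (s), `amplitude`, `baseline`, `convention`, `rss`.
#' @export
fit_dissociation <- function(time, response,
                             convention = c("inverse", "half_life")) {
  convention <- match.arg(convention)
  stopifnot(length(time) == length(response), length(time) >= 4L)
  if (is.unsorted(time, strictly = TRUE)) {
    stop("time must be strictly increasing")
  }
  n <- length(time)
  head_mean <- mean(response[seq_len(max(2L, n %/% 5))])
  tail_mean <- mean(response[seq.int(n - max(2L, n %/% 5) + 1L, n)])
  amp0 <- head_mean - tail_mean
  if (!is.finite(amp0) || amp0 <= 0 ||
      amp0 < 0.02 * max(abs(response) + .Machine$double.eps)) {
    stop("trace does not decay; cannot fit a 1:1 dissociation model")
  }
  base0 <- tail_mean
  # crude rate from the time to lose half the amplitude
  half_idx <- which(response <= base0 + amp0 / 2)[1]
  k0 <- if (!is.na(half_idx) && time[half_idx] > time[1]) {
    log(2) / (time[half_idx] - time[1])
  } else {
    1 / (time[n] - time[1])
  }
  tt <- time - time[1]
  fn <- function(p) response - (p[1] + p[2] * exp(-exp(p[3]) * tt))
  fit <- minpack.lm::nls.lm(
    par = c(base0, amp0, log(k0)), fn = fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  if (!fit$info %in% 1:4) {
    stop("dissociation fit failed to converge: ", fit$message)
  }
  koff <- exp(fit$par[3])
  rt <- if (convention == "inverse") 1 / koff else log(2) / koff
  structure(list(koff = koff, residence_time = rt,
                 amplitude = fit$par[2],
                 baseline = fit$par[1],
                 convention = convention,
                 rss = fit$deviance, n = n),
            class = "dissociation_fit")
}

#' @export
print.dissociation_fit <- function(x, ...) {
  cat(sprintf("dissociation_fit (n=%d): koff=%.4g 1/s, residence time=%.4g s (%s)\n",
              x$n, x$koff, x$residence_time,
              if (x$convention == "inverse") "1/koff" else "ln(2)/koff"))
  invisible(x)
}

#' Cooperativity fold shift from paired IC50s
#'
#' `fold_shift = ic50_binary / ic50_ternary`: the apparent-affinity shift of
#' a bifunctional ligand when the partner protein is present at saturation.
#' Values above 1 indicate positive cooperativity.
#'
#' @param ic50_binary IC50 without partner protein; positive.
#' @param ic50_ternary IC50 with saturating partner protein; positive.
#' @return Object of class `cooperativity_shift`.
#' @examples
#' cooperativity_shift(100, 2)$fold_shift  # 50
#' @export
cooperativity_shift <- function(ic50_binary, ic50_ternary) {
  if (any(c(ic50_binary, ic50_ternary) <= 0)) {
    stop("IC50 values must be positive")
  }
  structure(list(ic50_binary = ic50_binary,
                 ic50_ternary = ic50_ternary,
                 fold_shift = ic50_binary / ic50_ternary),
            class = "cooperativity_shift")
}

#' @export
print.cooperativity_shift <- function(x, ...) {
  cat(sprintf("cooperativity_shift: %.3g / %.3g = %.3g-fold\n",
              x$ic50_binary, x$ic50_ternary, x$fold_shift))
  invisible(x)
}

#' Initial reaction velocity from a progress curve
#'
#' Ordinary least-squares slope over the earliest `window_fraction` of the
#' trace. If the window shows significant curvature (quadratic term with
#' p < 0.05), the window is halved and the fit repeated, down to a minimum
#' of 5 points, so saturating progress curves are evaluated near t = 0.
#'
#' @param time Time points (seconds), strictly increasing.
#' @param signal Signal trace.
#' @param window_fraction Initial fraction of the time span to use.
#' @param shrink Shrink the window on detected curvature.
#' @return List with `velocity` (signal units per second), `n_points`,
#'   `window` (time span used) and `shrunk`.
#' @export
initial_velocity <- function(time, signal, window_fraction = 0.2,
                             shrink = TRUE) {
  stopifnot(length(time) == length(signal),
            window_fraction > 0, window_fraction <= 1)
  if (is.unsorted(time, strictly = TRUE)) {
    stop("time must be strictly increasing")
  }
  span <- diff(range(time))
  frac <- window_fraction
  shrunk <- FALSE
  repeat {
    sel <- time <= time[1] + frac * span
    if (sum(sel) < 5L) {
      if (!shrunk && frac == window_fraction) {
        stop("fewer than 5 points in the initial window")
      }
      frac <- frac * 2  # restore the last admissible window
      sel <- time <= time[1] + frac * span
      break
    }
    if (!shrink) break
    ts <- time[sel]; ys <- signal[sel]
    if (diff(range(ys)) == 0) break
    lf <- stats::lm(ys ~ ts)
    qf <- stats::lm(ys ~ ts + I(ts^2))
    rss1 <- sum(stats::residuals(lf)^2)
    rss2 <- sum(stats::residuals(qf)^2)
    # curvature must be material (beyond numerical noise) and significant
    material <- (rss1 - rss2) > (1e-7 * diff(range(ys)))^2 * length(ys)
    if (!material) break
    pq <- stats::coef(summary(qf))
    p_curv <- if (nrow(pq) >= 3L) pq[3, "Pr(>|t|)"] else 1
    if (is.na(p_curv) || p_curv >= 0.05) break
    frac <- frac / 2
    shrunk <- TRUE
  }
  lfit <- stats::lm(signal[sel] ~ time[sel])
  list(velocity = unname(stats::coef(lfit)[2]),
       n_points = sum(sel),
       window = frac * span,
       shrunk = shrunk)
}
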