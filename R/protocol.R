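#' Charge-balanced biphasic stimulus pulse
#'
#' Rectangular biphasic pulse of unit amplitude: first phase on
#' `[0, PW]`, an interphase gap, then the opposite phase of equal width, so
#' the time integral of `a(t)` is zero. Cathodic-first by default (first
#' phase negative).
#'
#' @param pw_us pulse width of one phase, us (> 0).
#' @param interphase_ms interphase interval, ms (default 0.1).
#' @param polarity `"cathodic_first"` (default) or `"anodic_first"`.
#' @return object of class `pulse_spec`, including the sampler `a(t_ms)`.
#' @export
#' @examples
#' p <- make_pulse(495)
#' p$a(c(0.1, 0.55, 0.6))   # first phase, gap, second phase
make_pulse <- function(pw_us, interphase_ms = 0.1,
                       polarity = c("cathodic_first", "anodic_first")) {
  polarity <- match.arg(polarity)
  if (!is.numeric(pw_us) || length(pw_us) != 1 || pw_us <= 0)
    stop("pulse width must be a positive scalar")
  pw_ms <- pw_us / 1000
  sgn <- if (polarity == "cathodic_first") -1 else 1
  a <- function(t_ms) {
    out <- numeric(length(t_ms))
    out[t_ms > 0 & t_ms <= pw_ms] <- sgn
    out[t_ms > pw_ms + interphase_ms & t_ms <= 2 * pw_ms + interphase_ms] <- -sgn
    out
  }
  structure(list(pw_us = pw_us, interphase_ms = interphase_ms,
                 polarity = polarity, shape = "rectangular", amplitude = 1,
                 a = a), class = "pulse_spec")
}

#' Titrate the excitation threshold of an axon
#'
#' Finds the smallest scale factor T on the extracellular drive (computed at
#' the baseline current I) that elicits a propagating action potential:
#' geometric bracketing (doubling from `t_init`, capped at
#' `t_init * 2^max_doublings`) followed by bisection to a relative bracket
#' width of `tol`. The threshold current is `I_T = T * I` exactly.
#'
#' @param axon an `mrg_axon`.
#' @param drive `extracellular_drive` sampled at the baseline current.
#' @param pulse a `pulse_spec`.
#' @param baseline_mA the current at which `drive` was computed, mA. Defaults
#'   to the drive's recorded current context.
#' @param tol relative bracket width (default 0.01).
#' @param t_init initial factor for bracketing (default 0.1).
#' @param max_doublings bracket cap exponent (default 15).
#' @param duration_ms,dt_ms passed to [integrate_axon()].
#' @return object of class `titration_result` with `factor`, `baseline_mA`,
#'   `threshold_mA = factor * baseline_mA`, the bracketing `history` and `tol`.
#' @export
titrate <- function(axon, drive, pulse, baseline_mA = NULL, tol = 0.01,
                    t_init = 0.1, max_doublings = 15,
                    duration_ms = 3.5, dt_ms = 0.0025) {
  if (is.null(baseline_mA)) {
    baseline_mA <- if (inherits(drive, "extracellular_drive")) drive$current_mA else NA_real_
  }
  if (!is.finite(baseline_mA)) stop("baseline current unknown; pass baseline_mA")
  history <- data.frame(factor = numeric(0), spike = logical(0))
  spikes_at <- function(Tf) {
    tr <- integrate_axon(axon, drive, pulse, Tf, duration_ms, dt_ms)
    sp <- detect_ap(tr)$spike
    history[nrow(history) + 1, ] <<- list(Tf, sp)
    sp
  }
  lo <- NA_real_; hi <- NA_real_
  Tf <- t_init
  if (spikes_at(Tf)) {
    # shrink until silent to find the lower bracket
    while (Tf > t_init * 2^-30) {
      Tf <- Tf / 2
      if (!spikes_at(Tf)) { lo <- Tf; hi <- Tf * 2; break }
    }
    if (is.na(lo)) stop("degenerate drive: spike persists as the factor vanishes")
  } else {
    lo <- Tf
    for (k in seq_len(max_doublings)) {
      Tf <- Tf * 2
      if (spikes_at(Tf)) { hi <- Tf; break }
      lo <- Tf
    }
    if (is.na(hi))
      stop(sprintf("inexcitable under this montage: no spike up to factor %g",
                   t_init * 2^max_doublings))
  }
  while ((hi - lo) / hi > tol) {
    mid <- (lo + hi) / 2
    if (spikes_at(mid)) hi <- mid else lo <- mid
  }
  Tf <- (lo + hi) / 2
  structure(list(factor = Tf, baseline_mA = baseline_mA,
                 threshold_mA = Tf * baseline_mA, bracket = c(lo, hi),
                 tol = tol, pw_us = pulse$pw_us, history = history),
            class = "titration_result")
}

#' Threshold current from a titration factor
#'
#' The excitability threshold is the product of the titration factor and the
#' baseline current at which the drive was computed.
#'
#' @param factor unitless titration factor T.
#' @param baseline_mA baseline current I, mA.
#' @return threshold current `T * I`, mA.
#' @export
threshold_current <- function(factor, baseline_mA) factor * baseline_mA

#' Strength-duration curve by repeated titration
#'
#' Titrates the same axon/drive context at each pulse width, reusing the one
#' field solution (the drive is current-scaled, not re-solved).
#'
#' @param axon,drive,baseline_mA as in [titrate()].
#' @param pw_us vector of pulse widths (>= 2 values), us.
#' @param interphase_ms,polarity pulse settings, see [make_pulse()].
#' @param ... further arguments passed to [titrate()].
#' @return object of class `sd_curve`: data.frame columns `pw_us`, `factor`,
#'   `threshold_mA` plus metadata.
#' @export
sd_curve <- function(axon, drive, pw_us, baseline_mA = NULL,
                     interphase_ms = 0.1, polarity = "cathodic_first", ...) {
  if (length(pw_us) < 2) stop("need at least two pulse widths for a curve")
  rows <- lapply(pw_us, function(pw) {
    tryCatch({
      tt <- titrate(axon, drive, make_pulse(pw, interphase_ms, polarity),
                    baseline_mA, ...)
      data.frame(pw_us = pw, factor = tt$factor, threshold_mA = tt$threshold_mA)
    }, error = function(e) stop(sprintf("titration failed at %g us: %s",
                                        pw, conditionMessage(e)), call. = FALSE))
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab,
                 nerve = if (inherits(drive, "extracellular_drive")) drive$nerve else NA,
                 baseline_mA = baseline_mA), class = "sd_curve")
}

#' @export
print.sd_curve <- function(x, ...) {
  cat("<sd_curve>", if (!is.na(x$nerve)) paste0("nerve: ", x$nerve), "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Fit a strength-duration model
#'
#' Nonlinear least squares of threshold current against pulse width.
#' Weiss: `I = I_rh * (1 + c / PW)`; Lapicque: `I = I_rh / (1 - 2^(-PW / c))`.
#' In both parameterizations `c` is the chronaxie (the pulse width at which
#' the threshold is twice the rheobase `I_rh`); the Lapicque membrane time
#' constant is `c / ln 2`.
#'
#' @param curve an `sd_curve`, or a data.frame with columns `pw_us` and
#'   `threshold_mA`.
#' @param form `"weiss"` or `"lapicque"`.
#' @return object of class `sd_fit` with `rheobase_mA`, `chronaxie_us`,
#'   `residuals` and the `nls` fit.
#' @export
fit_sd <- function(curve, form = c("weiss", "lapicque")) {
  form <- match.arg(form)
  tab <- if (inherits(curve, "sd_curve")) curve$table else as.data.frame(curve)
  stopifnot(all(c("pw_us", "threshold_mA") %in% names(tab)))
  if (nrow(tab) < 2) stop("need at least two points")
  exact2 <- nrow(tab) == 2
  if (any(tab$threshold_mA <= 0)) stop("thresholds must be positive")
  irh0 <- min(tab$threshold_mA) * 0.9
  c0 <- max((tab$threshold_mA[which.min(tab$pw_us)] / irh0 - 1) *
              min(tab$pw_us), 10)
  fml <- switch(form,
    weiss = threshold_mA ~ irh * (1 + cx / pw_us),
    lapicque = threshold_mA ~ irh / (1 - 2^(-pw_us / cx)))
  fit <- tryCatch(
    nls(fml, data = tab, start = list(irh = irh0, cx = c0),
        algorithm = "port", lower = c(irh = 1e-12, cx = 1e-6),
        control = list(maxiter = 500, warnOnly = exact2)),
    error = function(e) stop("strength-duration fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  est <- coef(fit)
  structure(list(form = form, rheobase_mA = unname(est["irh"]),
                 chronaxie_us = unname(est["cx"]),
                 residuals = unname(resid(fit)), fit = fit,
                 exact_two_point = exact2, n = nrow(tab)),
            class = "sd_fit")
}

#' @export
print.sd_fit <- function(x, ...) {
  cat(sprintf("<sd_fit> %s: rheobase %.4g mA, chronaxie %.4g us (n = %d)\n",
              x$form, x$rheobase_mA, x$chronaxie_us, x$n))
  invisible(x)
}

#' Predict thresholds from a strength-duration fit
#' @param object an `sd_fit`.
#' @param pw_us pulse widths, us.
#' @param ... unused.
#' @export
predict.sd_fit <- function(object, pw_us, ...) {
  irh <- object$rheobase_mA; cx <- object$chronaxie_us
  switch(object$form,
         weiss = irh * (1 + cx / pw_us),
         lapicque = irh / (1 - 2^(-pw_us / cx)))
}
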