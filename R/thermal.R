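# Variable-temperature CD melt analysis: van't Hoff two-state and
# sequential three-state fits with linear baselines, transition
# detection, and pre/post spectral comparison. Temperatures are deg C
# at the interface and Kelvin internally. Because thermal unfolding of
# aggregation-prone serpins is rarely reversible, fitted van't Hoff
# parameters are apparent quantities.

# van't Hoff equilibrium constant; Tm, T in Kelvin, dH kcal/mol
.vh_K <- function(TK, TmK, dH) exp((dH / .R_KCAL) * (1 / TmK - 1 / TK))

# two-state melt signal; temperatures in deg C
.melt2_signal <- function(Tc, Tm, dH, aN, bN, aD, bD) {
  K <- .vh_K(Tc + 273.15, Tm + 273.15, dH)
  fU <- K / (1 + K)
  (aN + bN * Tc) * (1 - fU) + (aD + bD * Tc) * fU
}

# sequential three-state melt signal (N <-> I <-> U)
.melt3_signal <- function(Tc, Tm1, dH1, Tm2, dH2, aN, bN, aI, bI, aU, bU) {
  TK <- Tc + 273.15
  K1 <- .vh_K(TK, Tm1 + 273.15, dH1)
  K2 <- .vh_K(TK, Tm2 + 273.15, dH2)
  Z <- 1 + K1 + K1 * K2
  (aN + bN * Tc) / Z + (aI + bI * Tc) * K1 / Z + (aU + bU * Tc) * K1 * K2 / Z
}

#' Construct a thermal melt curve
#'
#' @param temperature Temperature in deg C, strictly increasing.
#' @param signal CD signal at 222 nm (mdeg or MRE).
#' @param solvent Free-text solvent note (e.g. `"2 M GuHCl"`).
#' @return A `melt_curve` object.
#' @export
melt_curve <- function(temperature, signal, solvent = "") {
  if (length(temperature) != length(signal))
    .stop2("temperature/signal length mismatch")
  o <- order(temperature)
  temperature <- temperature[o]; signal <- signal[o]
  if (length(temperature) < 20L) .stop2("melt curves need >= 20 points")
  if (diff(range(temperature)) < 30) .stop2("melt must span >= 30 deg C")
  structure(list(temperature = temperature, signal = signal,
                 solvent = solvent), class = "melt_curve")
}

#' Read a melt curve from CSV (columns temperature_C, signal)
#'
#' @param path CSV path.
#' @return A `melt_curve`.
#' @export
read_melt_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("temperature_C", "signal") %in% names(d)))
    .stop2("CSV must have columns temperature_C, signal")
  melt_curve(d$temperature_C, d$signal)
}

# Tm initial guess: extremum of the smoothed derivative. Returns the
# top `k` candidate temperatures. Edge points, where the smoothing
# window is incomplete and raw noise leaks through, are not eligible.
.tm_init <- function(Tc, y, k = 1L) {
  dy <- diff(y) / diff(Tc)
  mid <- (Tc[-1L] + Tc[-length(Tc)]) / 2
  sm <- as.numeric(stats::filter(dy, rep(1 / 5, 5), sides = 2))
  ok <- which(!is.na(sm))
  if (!length(ok)) { ok <- seq_along(dy); sm <- dy }
  o <- ok[order(abs(sm[ok]), decreasing = TRUE)]
  mid[o[seq_len(min(k, length(o)))]]
}

#' Fit a thermal melt curve
#'
#' `model = "two-state"` fits a van't Hoff transition with linear
#' folded/unfolded baselines; `model = "three-state"` fits two
#' sequential van't Hoff transitions sharing a middle (intermediate)
#' baseline. A transition whose fitted Tm lies within 5 deg C of, or
#' beyond, the scan maximum is reported with an `incomplete` flag and
#' is fitted with a fixed (zero-slope) post-transition baseline rather
#' than rejected; its parameters are extrapolations.
#'
#' @param curve A `melt_curve`.
#' @param model `"two-state"` or `"three-state"`.
#' @param incomplete_margin Tm closer than this to the scan maximum is
#'   flagged incomplete (deg C, default 5).
#' @return A `melt_fit` list: `model`, `Tm` (vector, deg C), `dH`
#'   (vector, kcal/mol, apparent van't Hoff), `incomplete` (logical
#'   vector per transition), baseline coefficients, `se` for Tm where
#'   available, `fitted`, `rss`.
#' @export
fit_melt <- function(curve, model = c("two-state", "three-state"),
                     incomplete_margin = 5) {
  model <- match.arg(model)
  Tc <- curve$temperature
  y <- curve$signal
  n <- length(Tc)
  Tmax <- max(Tc)
  n_end <- max(3L, n %/% 8)
  lo <- seq_len(n_end); hi <- seq(n - n_end + 1L, n)
  cN <- stats::coef(stats::lm(y[lo] ~ Tc[lo]))
  cU <- stats::coef(stats::lm(y[hi] ~ Tc[hi]))
  dat <- data.frame(Tc = Tc, y = y)

  if (model == "two-state") {
    Tm0 <- .tm_init(Tc, y, 1L)
    fit <- tryCatch(minpack.lm::nlsLM(
      y ~ .melt2_signal(Tc, Tm, dH, aN, bN, aD, bD), data = dat,
      start = list(Tm = Tm0, dH = 80, aN = unname(cN[1L]),
                   bN = unname(cN[2L]), aD = unname(cU[1L]),
                   bD = unname(cU[2L])),
      lower = c(Tm = min(Tc) - 20, dH = 1, aN = -Inf, bN = -Inf,
                aD = -Inf, bD = -Inf),
      upper = c(Tm = Tmax + 40, dH = 1000, aN = Inf, bN = Inf,
                aD = Inf, bD = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) .stop2("melt fit did not converge: ",
                                 conditionMessage(e)))
    cf <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) stats::setNames(rep(NA_real_, 6),
                                                       names(cf)))
    out <- list(model = model,
                Tm = unname(cf["Tm"]), dH = unname(cf["dH"]),
                incomplete = unname(cf["Tm"]) > Tmax - incomplete_margin,
                baselines = cf[c("aN", "bN", "aD", "bD")],
                se = c(Tm = unname(se["Tm"])),
                fitted = stats::fitted(fit),
                rss = sum(stats::resid(fit)^2))
    class(out) <- "melt_fit"
    return(out)
  }

  ## three-state: initial guesses -- main derivative peak for Tm1,
  ## second transition near or past the scan end
  Tm1_0 <- .tm_init(Tc, y, 1L)
  Tm2_0 <- Tmax + 2
  second_incomplete_guess <- TRUE
  # if a second distinct interior derivative peak exists, use it
  cand <- .tm_init(Tc, y, 4L)
  interior <- cand[cand > Tm1_0 + 10 & cand < Tmax - 10]
  if (length(interior)) {
    Tm2_0 <- interior[1L]
    second_incomplete_guess <- FALSE
  }
  # middle baseline: flat segment between the transitions
  aI0 <- stats::median(y[Tc > Tm1_0 + 5 & Tc < min(Tm2_0 - 5, Tmax)])
  if (!is.finite(aI0)) aI0 <- stats::median(y)
  start <- list(Tm1 = Tm1_0, dH1 = 80, Tm2 = Tm2_0, dH2 = 80,
                aN = unname(cN[1L]), bN = unname(cN[2L]),
                aI = aI0, bI = 0, aU = unname(cU[1L]))
  lower <- c(Tm1 = min(Tc) - 20, dH1 = 1,
             Tm2 = min(Tm1_0 + 5, Tm2_0 - 1), dH2 = 1,
             aN = -Inf, bN = -Inf, aI = -Inf, bI = -Inf, aU = -Inf)
  upper <- c(Tm1 = Tmax + 40, dH1 = 1000, Tm2 = Tmax + 60, dH2 = 1000,
             aN = Inf, bN = Inf, aI = Inf, bI = Inf, aU = Inf)
  # post-transition baseline slope is not identifiable when the second
  # transition is incomplete: fix bU = 0. The second transition's
  # initial position is poorly determined, so failed starts are
  # retried from alternative (Tm2, dH2) guesses.
  try_fit <- function(st) tryCatch(minpack.lm::nlsLM(
    y ~ .melt3_signal(Tc, Tm1, dH1, Tm2, dH2, aN, bN, aI, bI, aU, 0),
    data = dat, start = st, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  fit <- try_fit(start)
  if (inherits(fit, "error")) {
    for (alt in list(list(Tm2 = Tmax + 10, dH2 = 150),
                     list(Tm2 = Tmax + 5, dH2 = 250),
                     list(Tm2 = Tmax - 2, dH2 = 60))) {
      st <- utils::modifyList(start, alt)
      fit <- try_fit(st)
      if (!inherits(fit, "error")) break
    }
  }
  if (inherits(fit, "error"))
    .stop2("three-state melt fit did not converge: ",
           conditionMessage(fit))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, length(cf)),
                                                     names(cf)))
  out <- list(model = model,
              Tm = unname(cf[c("Tm1", "Tm2")]),
              dH = unname(cf[c("dH1", "dH2")]),
              incomplete = unname(cf[c("Tm1", "Tm2")]) > Tmax - incomplete_margin,
              baselines = cf[c("aN", "bN", "aI", "bI", "aU")],
              se = c(Tm1 = unname(se["Tm1"]), Tm2 = unname(se["Tm2"])),
              fitted = stats::fitted(fit),
              rss = sum(stats::resid(fit)^2))
  class(out) <- "melt_fit"
  out
}

#' @export
print.melt_fit <- function(x, ...) {
  flag <- ifelse(x$incomplete, " (incomplete)", "")
  cat("Melt fit (", x$model, "): Tm = ",
      paste0(sprintf("%.1f", x$Tm), " C", flag, collapse = ", "),
      "; apparent dH = ", paste(signif(x$dH, 3), collapse = ", "),
      " kcal/mol\n", sep = "")
  invisible(x)
}

#' Detect whether a melt curve contains an unfolding transition
#'
#' Compares a straight line against the two-state van't Hoff sigmoid
#' by corrected AIC; a transition is reported only when the sigmoid
#' wins by more than `delta_aicc`.
#'
#' @param curve A `melt_curve`.
#' @param delta_aicc AICc improvement required (default 10).
#' @return A list: `transition` (logical), `delta_aicc` (achieved
#'   improvement), `line_rss`, `sigmoid_rss`.
#' @export
detect_transition <- function(curve, delta_aicc = 10) {
  Tc <- curve$temperature
  y <- curve$signal
  n <- length(y)
  line <- stats::lm(y ~ Tc)
  rss_line <- sum(stats::resid(line)^2)
  aicc_line <- .aicc(rss_line, n, 2)
  rss_sig <- Inf
  fit <- tryCatch(fit_melt(curve, "two-state"), error = function(e) NULL)
  if (!is.null(fit)) rss_sig <- fit$rss
  aicc_sig <- .aicc(rss_sig, n, 6)
  achieved <- aicc_line - aicc_sig
  list(transition = is.finite(achieved) && achieved > delta_aicc,
       delta_aicc = achieved, line_rss = rss_line, sigmoid_rss = rss_sig)
}

#' Compare far-UV CD spectra before and after a thermal melt
#'
#' Interpolates both spectra onto a common wavelength grid and reports
#' the maximum absolute difference normalised by the maximum absolute
#' signal of the first spectrum. Verdict `"unchanged"` iff the
#' normalised deviation is below `tol` (default 5%).
#'
#' @param spectrum_before,spectrum_after Data frames (or lists) with
#'   elements `wavelength_nm` and `signal`.
#' @param tol Normalised deviation threshold (default 0.05).
#' @return A `spectral_change_report` list: `max_deviation`
#'   (normalised), `verdict`.
#' @export
spectral_change <- function(spectrum_before, spectrum_after, tol = 0.05) {
  w1 <- spectrum_before$wavelength_nm; y1 <- spectrum_before$signal
  w2 <- spectrum_after$wavelength_nm;  y2 <- spectrum_after$signal
  lo <- max(min(w1), min(w2)); hi <- min(max(w1), max(w2))
  if (hi - lo < 50)
    .stop2("spectra must overlap over at least 50 nm (got ",
           round(hi - lo, 1), " nm)")
  grid <- seq(lo, hi, length.out = 200)
  a <- stats::approx(w1, y1, xout = grid)$y
  b <- stats::approx(w2, y2, xout = grid)$y
  dev <- max(abs(a - b)) / max(abs(a))
  structure(list(max_deviation = dev,
                 verdict = if (dev < tol) "unchanged" else "changed"),
            class = "spectral_change_report")
}

#' @export
print.spectral_change_report <- function(x, ...) {
  cat(sprintf("Spectral comparison: %s (normalised max deviation %.3f)\n",
              x$verdict, x$max_deviation))
  invisible(x)
}
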