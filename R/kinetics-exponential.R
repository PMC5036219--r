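# Stopped-flow trace analysis: sums of exponentials with objective
# model selection. Rates are fitted on a log scale to enforce
# positivity; the number of phases is the smallest model that no
# larger candidate beats by more than `delta_aicc` corrected-AIC
# units.

#' Construct a kinetic trace
#'
#' @param time Time in seconds, strictly increasing, `time[1] >= 0`.
#' @param signal Signal (a.u.).
#' @param final_denaturant Final denaturant concentration (M).
#' @param scheme `"unfold-single"`, `"refold-single"` or
#'   `"refold-double"` (double-jump).
#' @param delay_time Delay between jumps (s), double-jump only.
#' @return A `kinetic_trace` object.
#' @export
kinetic_trace <- function(time, signal, final_denaturant,
                          scheme = c("unfold-single", "refold-single",
                                     "refold-double"),
                          delay_time = NA_real_) {
  scheme <- match.arg(scheme)
  if (length(time) != length(signal)) .stop2("time/signal length mismatch")
  if (length(time) < 50L) .stop2("kinetic traces need at least 50 points")
  if (time[1L] < 0 || any(diff(time) <= 0))
    .stop2("time must be non-negative and strictly increasing")
  structure(list(time = time, signal = signal,
                 final_denaturant = final_denaturant,
                 scheme = scheme, delay_time = delay_time),
            class = "kinetic_trace")
}

# Sum-of-exponentials model on log-rates.
.exp_model <- function(t, logk, amp, offset) {
  s <- rep(offset, length(t))
  for (i in seq_along(logk)) s <- s + amp[i] * exp(-exp(logk[i]) * t)
  s
}

# single nls.lm fit at fixed phase count; returns NULL on failure
.fit_nexp <- function(t, y, n_phases, logk0) {
  amp0 <- rep((y[1L] - y[length(y)]) / n_phases, n_phases)
  par0 <- c(logk0, amp0, y[length(y)])
  res_fun <- function(p) {
    lk <- p[seq_len(n_phases)]
    a <- p[n_phases + seq_len(n_phases)]
    off <- p[2L * n_phases + 1L]
    y - .exp_model(t, lk, a, off)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, fn = res_fun,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- fit$par
  list(logk = p[seq_len(n_phases)],
       amp = p[n_phases + seq_len(n_phases)],
       offset = p[2L * n_phases + 1L],
       rss = sum(fit$fvec^2),
       n_par = length(p))
}

# data-driven initial rate guess: time at which the decay towards the
# tail value is 1 - 1/e complete
.rate_init <- function(t, y) {
  n <- length(y)
  tail_val <- mean(y[seq(max(1L, n - max(3L, n %/% 20)), n)])
  a0 <- y[1L] - tail_val
  if (abs(a0) < .Machine$double.eps) return(1 / stats::median(t))
  target <- tail_val + a0 / exp(1)
  idx <- if (a0 > 0) which(y <= target) else which(y >= target)
  t63 <- if (length(idx)) t[idx[1L]] else stats::median(t)
  1 / max(t63, t[2L])
}

#' Fit a kinetic trace with 1-3 exponential phases
#'
#' Fits sums of `1..max_phases` exponentials plus an offset and selects
#' the smallest number of phases such that no larger model improves the
#' corrected AIC by more than `delta_aicc` (default 10). Rates within a
#' ratio of `merge_ratio` are considered degenerate and the simpler
#' model is preferred. The first `dead_time` seconds are excluded
#' (stopped-flow mixing artefact window).
#'
#' @param trace A `kinetic_trace` (or list with `time`/`signal`).
#' @param max_phases Maximum phases to consider (1-3, default 3).
#' @param dead_time Initial truncation in seconds (default 0.002).
#' @param delta_aicc AICc improvement required to accept an extra
#'   phase (default 10).
#' @param merge_ratio Minimum distinguishable rate ratio (default 1.05).
#' @return A `multi_exp_fit` list: `n_phases`, `rates` (s^-1,
#'   descending), `amplitudes` (matched order), `offset`,
#'   `selection_score` (AICc per candidate model), `rss`, `fitted`.
#' @export
fit_exponentials <- function(trace, max_phases = 3, dead_time = 0.002,
                             delta_aicc = 10, merge_ratio = 1.05) {
  stopifnot(max_phases >= 1, max_phases <= 3)
  keep <- trace$time >= dead_time
  t <- trace$time[keep]
  y <- trace$signal[keep]
  if (length(t) < 10L) .stop2("too few points after dead-time truncation")
  t <- t - t[1L]
  n <- length(t)
  k0 <- .rate_init(t, y)
  cand <- vector("list", max_phases)
  score <- rep(NA_real_, max_phases)
  for (np in seq_len(max_phases)) {
    # spread initial log-rates around the 1-exp estimate
    logk0 <- switch(np,
                    log(k0),
                    log(k0 * c(5, 0.2)),
                    log(k0 * c(20, 1, 0.05)))
    if (np >= 2L && !is.null(cand[[np - 1L]])) {
      prev <- sort(cand[[np - 1L]]$logk, decreasing = TRUE)
      logk0 <- c(prev[1L] + log(5), prev)
    }
    f <- .fit_nexp(t, y, np, logk0)
    if (is.null(f)) next
    # retry from a wider spread if a larger model failed to improve
    if (np >= 2L && !is.null(cand[[np - 1L]]) &&
        f$rss > 0.999 * cand[[np - 1L]]$rss) {
      f2 <- .fit_nexp(t, y, np, log(k0 * 10^seq(1, -2, length.out = np)))
      if (!is.null(f2) && f2$rss < f$rss) f <- f2
    }
    # degenerate rates: treat as unsupported model
    k <- sort(exp(f$logk), decreasing = TRUE)
    if (np >= 2L && any(k[-np] / k[-1L] < merge_ratio)) {
      cand[np] <- list(NULL)
      score[np] <- Inf
      next
    }
    cand[[np]] <- f
    score[np] <- .aicc(f$rss, n, f$n_par)
  }
  ok <- which(vapply(cand, Negate(is.null), logical(1)))
  if (!length(ok)) {
    .stop2("exponential fit failed to converge at every phase count; ",
           "residual span ", signif(diff(range(y)), 3))
  }
  # minimal model under the selection criterion
  best <- ok[1L]
  for (np in ok[-1L]) {
    if (score[np] < score[best] - delta_aicc) best <- np
  }
  f <- cand[[best]]
  o <- order(exp(f$logk), decreasing = TRUE)
  out <- list(n_phases = best,
              rates = exp(f$logk)[o],
              amplitudes = f$amp[o],
              offset = f$offset,
              selection_score = score,
              rss = f$rss,
              fitted = .exp_model(t, f$logk, f$amp, f$offset),
              time = t)
  class(out) <- "multi_exp_fit"
  out
}

#' @export
print.multi_exp_fit <- function(x, ...) {
  cat("Exponential fit: ", x$n_phases, " phase(s); rates (s^-1): ",
      paste(signif(x$rates, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}
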