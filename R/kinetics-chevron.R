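# Chevron-plot analysis. The observed fast refolding rate is modelled
# with a rapid pre-equilibrium between the denatured state D and a
# folding intermediate I1:
#
#   k_obs(D) = k_f(H2O) e^(-m_kf [D]) / (1 + K_DI([D])) + k_u(H2O) e^(+m_ku [D])
#   K_DI([D]) = exp(-(dG_DI + m_DI [D]) / RT)
#
# K_DI > 1 (I1 the ground state) at low denaturant suppresses the
# observed rate and, because m_DI/RT exceeds m_kf, produces the
# positive refolding limb; the ground state switches from I1 to D where
# K_DI = 1, i.e. at [D] = -dG_DI / m_DI ("crossover"). A second, slower
# limb (I2) is fitted in parallel with its own stability and, by
# default, the same kinetic folding m-value.

# --- model primitives (shared with the synthetic generator) ----------

.K_DI <- function(D, dG, m, RT) exp(-(dG + m * D) / RT)

# observed fast refolding + unfolding rate
.k_fast_obs <- function(D, ln_kf, m_kf, dG_DI, m_DI, ln_ku, m_ku, RT) {
  exp(ln_kf - m_kf * D) / (1 + .K_DI(D, dG_DI, m_DI, RT)) +
    exp(ln_ku + m_ku * D)
}

# slow (I2) refolding limb
.k_slow_obs <- function(D, ln_kf2, m_kf2, dG_DI2, m_DI2, RT) {
  exp(ln_kf2 - m_kf2 * D) / (1 + .K_DI(D, dG_DI2, m_DI2, RT))
}

# plain two-state chevron
.k_two_state <- function(D, ln_kf, m_kf, ln_ku, m_ku) {
  exp(ln_kf - m_kf * D) + exp(ln_ku + m_ku * D)
}

# --- chevron dataset assembly ----------------------------------------

#' Assemble a chevron dataset from per-denaturant exponential fits
#'
#' Collects observed rate constants as a function of final denaturant
#' and assigns phase labels. Unfolding-scheme traces feed the
#' `"unfolding"` limb. Refolding phases are labelled `"refold-fast"` /
#' `"refold-slow"` by continuity of ln k across adjacent
#' concentrations (each label's trajectory is extrapolated from its
#' previous two points and observed rates are matched to the nearest
#' prediction), not by rank at each concentration, so labels stay
#' continuous through a limb crossing. Points where two assignments
#' are nearly equally good are flagged.
#'
#' @param fits_by_denaturant A list of entries, each a list with
#'   elements `denaturant`, `scheme` (`"unfold"` or `"refold"`), and
#'   `fit` (a [fit_exponentials()] result). The helper
#'   [chevron_from_traces()] builds this from raw traces.
#' @param ambiguity_tol Flag a point when the best and swapped
#'   assignment costs differ by less than this (ln-rate units,
#'   default 0.1).
#' @return A `chevron_dataset`: data frame `points` with columns
#'   `denaturant`, `ln_k`, `phase`, `amplitude`, `flagged`.
#' @export
build_chevron <- function(fits_by_denaturant, ambiguity_tol = 0.1) {
  rows <- list()
  refold <- list()
  for (e in fits_by_denaturant) {
    f <- e$fit
    if (identical(e$scheme, "unfold")) {
      # dominant phase only: unfolding traces are single exponential
      i <- which.max(abs(f$amplitudes))
      rows[[length(rows) + 1L]] <-
        data.frame(denaturant = e$denaturant, ln_k = log(f$rates[i]),
                   phase = "unfolding", amplitude = f$amplitudes[i],
                   flagged = FALSE)
    } else {
      refold[[length(refold) + 1L]] <- e
    }
  }
  if (length(refold)) {
    ord <- order(vapply(refold, function(e) e$denaturant, numeric(1)))
    refold <- refold[ord]
    hist_fast <- data.frame(D = numeric(0), lnk = numeric(0),
                            amp = numeric(0))
    hist_slow <- data.frame(D = numeric(0), lnk = numeric(0),
                            amp = numeric(0))
    predict_next <- function(h, D) {
      n <- nrow(h)
      if (n == 0L) return(NA_real_)
      if (n == 1L) return(h$lnk[n])
      slope <- (h$lnk[n] - h$lnk[n - 1L]) / (h$D[n] - h$D[n - 1L])
      h$lnk[n] + slope * (D - h$D[n])
    }
    for (e in refold) {
      f <- e$fit
      lnk <- log(f$rates)
      amp <- f$amplitudes
      D <- e$denaturant
      if (f$n_phases == 1L) {
        # single detected phase: attach to the nearer predicted limb;
        # flag it when the other limb's prediction is also close (the
        # observed rate is then likely an unresolved blend of two
        # nearly degenerate phases)
        pf <- predict_next(hist_fast, D)
        ps <- predict_next(hist_slow, D)
        lab <- if (is.na(ps) || (!is.na(pf) &&
                                 abs(lnk - pf) <= abs(lnk - ps)))
          "refold-fast" else "refold-slow"
        other <- if (lab == "refold-fast") ps else pf
        h <- if (lab == "refold-fast") hist_fast else hist_slow
        amp_ref <- if (nrow(h)) stats::median(utils::tail(h$amp, 3L))
                   else NA_real_
        flag <- (!is.na(pf) && !is.na(ps) &&
                   abs(abs(lnk - pf) - abs(lnk - ps)) < ambiguity_tol) ||
          (!is.na(other) && abs(lnk - other) < 8 * ambiguity_tol) ||
          (!is.na(amp_ref) && abs(amp) > 1.15 * abs(amp_ref))
        rows[[length(rows) + 1L]] <-
          data.frame(denaturant = D, ln_k = lnk, phase = lab,
                     amplitude = amp, flagged = flag)
        # flagged (likely blended) rates would corrupt the limb
        # trajectories used for later assignments
        if (!flag) {
          if (lab == "refold-fast")
            hist_fast <- rbind(hist_fast,
                               data.frame(D = D, lnk = lnk, amp = amp))
          else hist_slow <- rbind(hist_slow,
                                  data.frame(D = D, lnk = lnk, amp = amp))
        }
      } else {
        # two (or more) phases: use the two largest-amplitude ones
        o <- order(abs(amp), decreasing = TRUE)[1:2]
        o <- o[order(lnk[o], decreasing = TRUE)]   # (higher, lower)
        pf <- predict_next(hist_fast, D)
        ps <- predict_next(hist_slow, D)
        if (is.na(pf) && is.na(ps)) {
          assign_fast <- 1L                         # first point: by rank
          flag <- FALSE
        } else {
          cost <- function(i_fast) {
            i_slow <- 3L - i_fast
            c1 <- if (is.na(pf)) 0 else abs(lnk[o[i_fast]] - pf)
            c2 <- if (is.na(ps)) 0 else abs(lnk[o[i_slow]] - ps)
            c1 + c2
          }
          c_keep <- cost(1L); c_swap <- cost(2L)
          assign_fast <- if (c_keep <= c_swap) 1L else 2L
          flag <- abs(c_keep - c_swap) < ambiguity_tol
        }
        i_fast <- o[assign_fast]; i_slow <- o[3L - assign_fast]
        rows[[length(rows) + 1L]] <-
          data.frame(denaturant = D,
                     ln_k = lnk[c(i_fast, i_slow)],
                     phase = c("refold-fast", "refold-slow"),
                     amplitude = amp[c(i_fast, i_slow)],
                     flagged = flag)
        hist_fast <- rbind(hist_fast,
                           data.frame(D = D, lnk = lnk[i_fast],
                                      amp = amp[i_fast]))
        hist_slow <- rbind(hist_slow,
                           data.frame(D = D, lnk = lnk[i_slow],
                                      amp = amp[i_slow]))
      }
    }
  }
  pts <- do.call(rbind, rows)
  pts <- pts[order(pts$phase, pts$denaturant), ]
  rownames(pts) <- NULL
  structure(list(points = pts), class = "chevron_dataset")
}

#' Fit exponentials to a set of traces and assemble the chevron
#'
#' Convenience wrapper: runs [fit_exponentials()] on every trace
#' (refolding traces may hold up to `max_phases_refold` phases,
#' unfolding traces one) and hands the results to [build_chevron()].
#'
#' @param traces List of `kinetic_trace` objects.
#' @param max_phases_refold Maximum phases for refolding traces
#'   (default 2; double-jump refolding is double-exponential).
#' @param dead_time Passed to [fit_exponentials()].
#' @return A `chevron_dataset`.
#' @export
chevron_from_traces <- function(traces, max_phases_refold = 2,
                                dead_time = 0.002) {
  fits <- lapply(traces, function(tr) {
    unfold <- identical(tr$scheme, "unfold-single")
    f <- fit_exponentials(tr,
                          max_phases = if (unfold) 1 else max_phases_refold,
                          dead_time = dead_time)
    list(denaturant = tr$final_denaturant,
         scheme = if (unfold) "unfold" else "refold",
         fit = f)
  })
  build_chevron(fits)
}

# --- chevron model fitting -------------------------------------------

#' Fit a chevron (ln k vs denaturant) model
#'
#' `model = "two-state"` fits
#' \eqn{k_{obs} = k_f e^{-m_{kf}[D]} + k_u e^{+m_{ku}[D]}} to all
#' points. `model = "ground-state-switch"` fits the unfolding and
#' fast-refolding points jointly to the rapid pre-equilibrium model
#' (see the header of this file) and the slow (I2) limb in parallel
#' with its own intermediate stability; by default the two refolding
#' limbs share the kinetic folding m-value (`share_m_kf = TRUE`,
#' reflecting their near-identical folding m-values).
#'
#' Residuals are minimised in ln k. The fit reports the I1/D
#' `crossover_conc` (where `K_DI = 1`, i.e. `-dG_DI/m_DI`), the I2
#' analogue `crossover_conc_slow`, and the `kinetic_midpoint` where
#' the observed fast refolding rate equals the unfolding rate.
#'
#' @param dataset A `chevron_dataset` from [build_chevron()].
#' @param model `"two-state"` or `"ground-state-switch"`.
#' @param temperature Temperature (K).
#' @param share_m_kf Share m_kf between fast and slow refolding limbs
#'   (ground-state-switch only; default TRUE).
#' @return A `chevron_fit` list with the limb parameters
#'   (`ln_kf`, `m_kf`, `dG_DI`, `m_DI`, `ln_ku`, `m_ku`, and for the
#'   slow limb `ln_kf2`, `m_kf2`, `dG_DI2`, `m_DI2`), derived
#'   landmarks `crossover_conc`, `crossover_conc_slow`,
#'   `kinetic_midpoint`, the residual sum of squares `rss`, and
#'   `lack_of_fit` diagnostics for a mismatched two-state request.
#' @export
fit_chevron <- function(dataset, model = c("ground-state-switch", "two-state"),
                        temperature = .T_DEFAULT, share_m_kf = TRUE,
                        use_flagged = FALSE) {
  model <- match.arg(model)
  pts <- dataset$points
  if (!use_flagged && "flagged" %in% names(pts)) pts <- pts[!pts$flagged, ]
  RT <- rt_kcal(temperature)
  unf <- pts[pts$phase == "unfolding", ]
  fast <- pts[pts$phase == "refold-fast", ]
  slow <- pts[pts$phase == "refold-slow", ]

  if (model == "two-state") {
    use <- pts[pts$phase %in% c("unfolding", "refold-fast"), ]
    # warn when a positive refolding slope betrays an intermediate
    warn_pos <- FALSE
    if (nrow(fast) >= 4L) {
      lowD <- fast[fast$denaturant <= stats::median(fast$denaturant), ]
      if (nrow(lowD) >= 3L &&
          stats::coef(stats::lm(ln_k ~ denaturant, lowD))[2L] > 0.2)
        warn_pos <- TRUE
    }
    if (warn_pos)
      warning("positive refolding slope detected; a two-state chevron ",
              "cannot describe a ground-state intermediate", call. = FALSE)
    m_ku0 <- 1; m_kf0 <- 1
    ln_ku0 <- if (nrow(unf)) min(unf$ln_k) - m_ku0 * min(unf$denaturant) else -2
    ln_kf0 <- max(use$ln_k) + m_kf0 * use$denaturant[which.max(use$ln_k)]
    res_fun <- function(p)
      use$ln_k - log(.k_two_state(use$denaturant, p[1L], p[2L], p[3L], p[4L]))
    fit <- minpack.lm::nls.lm(
      par = c(ln_kf0, m_kf0, ln_ku0, m_ku0), fn = res_fun,
      lower = c(-Inf, 0, -Inf, 0),
      control = minpack.lm::nls.lm.control(maxiter = 300))
    p <- fit$par
    mid <- (p[1L] - p[3L]) / (p[2L] + p[4L])
    out <- list(model = model,
                ln_kf = p[1L], m_kf = p[2L], ln_ku = p[3L], m_ku = p[4L],
                kinetic_midpoint = mid,
                rss = sum(fit$fvec^2),
                lack_of_fit = sum(fit$fvec^2) / max(1, nrow(use) - 4),
                temperature = temperature)
    class(out) <- "chevron_fit"
    return(out)
  }

  if (nrow(fast) < 4L || nrow(unf) < 4L)
    .stop2("ground-state-switch fit needs >= 4 unfolding and >= 4 ",
           "fast-refolding points")
  have_slow <- nrow(slow) >= 4L

  # --- initial guesses from the data ---
  ufit <- stats::lm(ln_k ~ denaturant, unf)
  ln_ku0 <- unname(stats::coef(ufit)[1L])
  m_ku0 <- max(unname(stats::coef(ufit)[2L]), 0.05)
  # crossover: the fast limb's maximum below the chevron minimum
  i_max <- which.max(fast$ln_k)
  cross0 <- fast$denaturant[i_max]
  m_DI0 <- 2
  dG_DI0 <- -m_DI0 * cross0
  # post-switch slope of the fast limb (between crossover and midpoint)
  post <- fast[fast$denaturant > cross0, ]
  m_kf0 <- if (nrow(post) >= 3L)
    max(-unname(stats::coef(stats::lm(ln_k ~ denaturant, post))[2L]), 0.2)
  else 1
  ln_kf0 <- fast$ln_k[i_max] + m_kf0 * cross0 + log(2)  # K_DI=1 at crossover
  p0 <- c(ln_kf0, m_kf0, dG_DI0, m_DI0, ln_ku0, m_ku0)
  lower <- c(-Inf, 0, -Inf, 0, -Inf, 0)
  if (have_slow) {
    i2 <- which.max(slow$ln_k)
    cross2_0 <- max(slow$denaturant[i2], cross0 + 0.2)
    m_DI2_0 <- 3
    dG_DI2_0 <- -m_DI2_0 * cross2_0
    ln_kf2_0 <- slow$ln_k[i2] + m_kf0 * cross2_0 + log(2)
    p0 <- c(p0, ln_kf2_0, dG_DI2_0, m_DI2_0)
    lower <- c(lower, -Inf, -Inf, 0)
    if (!share_m_kf) {
      p0 <- c(p0, m_kf0)
      lower <- c(lower, 0)
    }
  }
  res_fun <- function(p) {
    r_fast <- c(unf$ln_k, fast$ln_k) -
      log(.k_fast_obs(c(unf$denaturant, fast$denaturant),
                      p[1L], p[2L], p[3L], p[4L], p[5L], p[6L], RT))
    if (!have_slow) return(r_fast)
    m_kf2 <- if (share_m_kf) p[2L] else p[10L]
    r_slow <- slow$ln_k -
      log(.k_slow_obs(slow$denaturant, p[7L], m_kf2, p[8L], p[9L], RT))
    c(r_fast, r_slow)
  }
  fit <- minpack.lm::nls.lm(
    par = p0, fn = res_fun, lower = lower,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- fit$par
  # the midpoint lies above the ground-state switch; starting the root
  # search there avoids the spurious low-denaturant intersection of
  # the extrapolated unfolding rate with the I1-suppressed refolding
  # rate
  mid_lo <- max(-p[3L] / p[4L], min(pts$denaturant))
  mid <- tryCatch(stats::uniroot(function(D)
    log(exp(p[1L] - p[2L] * D) / (1 + .K_DI(D, p[3L], p[4L], RT))) -
      (p[5L] + p[6L] * D),
    interval = c(mid_lo, max(pts$denaturant) + 2))$root,
    error = function(e) NA_real_)
  out <- list(model = model,
              ln_kf = p[1L], m_kf = p[2L], dG_DI = p[3L], m_DI = p[4L],
              ln_ku = p[5L], m_ku = p[6L],
              ln_kf2 = if (have_slow) p[7L] else NA_real_,
              m_kf2 = if (!have_slow) NA_real_
                      else if (share_m_kf) p[2L] else p[10L],
              dG_DI2 = if (have_slow) p[8L] else NA_real_,
              m_DI2 = if (have_slow) p[9L] else NA_real_,
              crossover_conc = -p[3L] / p[4L],
              crossover_conc_slow = if (have_slow) -p[8L] / p[9L]
                                    else NA_real_,
              kinetic_midpoint = mid,
              rss = sum(fit$fvec^2),
              temperature = temperature)
  class(out) <- "chevron_fit"
  out
}

#' @export
print.chevron_fit <- function(x, ...) {
  if (x$model == "two-state") {
    cat(sprintf("Two-state chevron: ln kf = %.2f, m_kf = %.2f, ln ku = %.2f, m_ku = %.2f; midpoint %.2f M\n",
                x$ln_kf, x$m_kf, x$ln_ku, x$m_ku, x$kinetic_midpoint))
  } else {
    cat(sprintf("Ground-state-switch chevron: I1/D crossover %.2f M, kinetic midpoint %.2f M\n",
                x$crossover_conc, x$kinetic_midpoint))
  }
  invisible(x)
}

# --- phase-origin diagnostics ----------------------------------------

#' Diagnose the origin of two refolding phases
#'
#' Applies three tests to a chevron with two refolding limbs:
#' (i) do the two refolding rates cross within the observed range;
#' (ii) does the fast phase become kinetically invisible (vanishing
#' amplitude / absence) beyond the crossing, as a sequential
#' fast-then-slow mechanism would demand; (iii) is the amplitude ratio
#' of the two phases constant across denaturant, as two independent
#' probes of separate folding events would show. Verdict:
#' `"parallel-ground-states"` iff the rates cross, the fast phase
#' persists, and the amplitude ratio is not constant; `"sequential"`
#' when the fast phase vanishes past the crossing;
#' `"independent-probes"` when the amplitude ratio is constant;
#' otherwise `"inconclusive"`.
#'
#' @param chevron_fit A `chevron_fit` (used for context; may be NULL).
#' @param dataset A `chevron_dataset` with both refolding limbs and
#'   amplitudes. Flagged (ambiguous/merged) points are ignored.
#' @param vanish_frac Amplitude fraction of the pre-crossing median
#'   below which the fast phase counts as invisible (default 0.1).
#' @param ratio_fold_tol The amplitude ratio counts as constant when
#'   its regression-estimated systematic fold change across the
#'   observed range is below this (default 1.5).
#' @return A `phase_origin_diagnosis` list: `rates_cross`,
#'   `crossing_conc`, `fast_phase_vanishes_after_cross`,
#'   `amplitude_ratio_constant`, `amplitude_ratio_fold_change`,
#'   `amplitude_ratio_cv`, `verdict`.
#' @export
diagnose_phase_origin <- function(chevron_fit, dataset,
                                  vanish_frac = 0.1, ratio_fold_tol = 1.5) {
  pts0 <- dataset$points
  pts <- pts0
  if ("flagged" %in% names(pts)) pts <- pts[!pts$flagged, ]
  fast <- pts[pts$phase == "refold-fast", ]
  slow <- pts[pts$phase == "refold-slow", ]
  if (nrow(fast) < 3L || nrow(slow) < 3L)
    .stop2("diagnosis needs both refolding limbs")
  fast <- fast[order(fast$denaturant), ]
  slow <- slow[order(slow$denaturant), ]
  # rate crossing: sign change of ln k difference on the shared grid,
  # or -- when the crossing region itself is unresolved (merged
  # phases) or the fast phase disappears there -- intersection of the
  # two limbs' local linear trajectories
  shared <- intersect(fast$denaturant, slow$denaturant)
  crossing <- NA_real_
  rates_cross <- FALSE
  if (length(shared) >= 2L) {
    df <- fast$ln_k[match(shared, fast$denaturant)] -
      slow$ln_k[match(shared, slow$denaturant)]
    sc <- which(diff(sign(df)) != 0)
    if (length(sc)) {
      rates_cross <- TRUE
      i <- sc[1L]
      crossing <- shared[i] + (shared[i + 1L] - shared[i]) *
        df[i] / (df[i] - df[i + 1L])
    }
  }
  if (!rates_cross) {
    # trajectory intersection from the last three points of each limb
    # at or below the gap between them
    upto <- min(max(fast$denaturant), max(slow$denaturant))
    f3 <- utils::tail(fast[fast$denaturant <= upto + 1e-9, ], 3L)
    s3 <- utils::tail(slow[slow$denaturant <= upto + 1e-9, ], 3L)
    if (nrow(f3) >= 2L && nrow(s3) >= 2L) {
      cf <- stats::coef(stats::lm(ln_k ~ denaturant, f3))
      cs <- stats::coef(stats::lm(ln_k ~ denaturant, s3))
      if (abs(cf[2L] - cs[2L]) > 1e-9) {
        xint <- unname((cs[1L] - cf[1L]) / (cf[2L] - cs[2L]))
        Dmax_obs <- max(pts$denaturant[pts$phase != "unfolding"])
        if (xint > upto - 0.5 && xint <= Dmax_obs + 0.5) {
          rates_cross <- TRUE
          crossing <- xint
        }
      }
    }
  }
  # amplitude-ratio constancy: regression of log ratio on denaturant;
  # the systematic fold change across the observed range is compared
  # with ratio_fold_tol
  amp_missing <- anyNA(fast$amplitude) || anyNA(slow$amplitude)
  ratio_constant <- NA
  ratio_cv <- NA_real_
  fold <- NA_real_
  if (!amp_missing && length(shared) >= 3L) {
    # amplitude splitting is unreliable where the two rates are
    # barely resolved; use only concentrations with clear separation
    dk <- abs(fast$ln_k[match(shared, fast$denaturant)] -
                slow$ln_k[match(shared, slow$denaturant)])
    ok <- shared[dk > log(3)]
    if (length(ok) >= 3L) {
      r <- abs(fast$amplitude[match(ok, fast$denaturant)]) /
        abs(slow$amplitude[match(ok, slow$denaturant)])
      ratio_cv <- stats::sd(r) / mean(r)
      # Theil-Sen slope of log ratio vs denaturant: resistant to a
      # single unstable amplitude estimate
      lr <- log(r)
      ij <- utils::combn(seq_along(ok), 2L)
      sl <- stats::median((lr[ij[2L, ]] - lr[ij[1L, ]]) /
                            (ok[ij[2L, ]] - ok[ij[1L, ]]))
      fold <- exp(abs(sl) * diff(range(ok)))
      ratio_constant <- unname(fold < ratio_fold_tol)
    }
  }
  # does observable refolding persist between the crossing and the
  # unfolding region? When the fast phase becomes kinetically
  # invisible past the crossing (sequential mechanism) the refolding
  # signal disappears well before unfolding takes over, leaving a gap
  # in the observed concentrations. This test is label-independent,
  # so it is robust to tracking ambiguity around the crossing itself.
  vanishes <- FALSE
  if (rates_cross) {
    refold_D <- pts0$denaturant[pts0$phase != "unfolding"]
    unfold_D <- pts0$denaturant[pts0$phase == "unfolding"]
    if (length(unfold_D)) {
      all_D <- sort(unique(pts0$denaturant))
      spacing <- if (length(all_D) > 1L) stats::median(diff(all_D)) else 0.25
      gap <- min(unfold_D) - max(refold_D)
      vanishes <- gap > 1.5 * spacing
    } else {
      # no unfolding limb available: fall back to fast-phase presence
      # beyond the crossing
      post <- fast[fast$denaturant > crossing + 0.05, ]
      pre <- abs(fast$amplitude[fast$denaturant <= crossing])
      vanishes <- length(pre) > 0 &&
        !any(abs(post$amplitude) > vanish_frac * stats::median(pre))
    }
  }
  verdict <- if (isTRUE(ratio_constant)) "independent-probes"
  else if (rates_cross && vanishes) "sequential"
  else if (rates_cross && !vanishes && identical(ratio_constant, FALSE))
    "parallel-ground-states"
  else "inconclusive"
  structure(list(rates_cross = rates_cross, crossing_conc = crossing,
                 fast_phase_vanishes_after_cross = vanishes,
                 amplitude_ratio_constant = ratio_constant,
                 amplitude_ratio_fold_change = fold,
                 amplitude_ratio_cv = ratio_cv,
                 amplitudes_missing = amp_missing,
                 verdict = verdict),
            class = "phase_origin_diagnosis")
}

#' @export
print.phase_origin_diagnosis <- function(x, ...) {
  cat("Phase-origin diagnosis: ", x$verdict, "\n", sep = "")
  invisible(x)
}
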