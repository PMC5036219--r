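# Stopped-flow exponential fitting, chevron assembly and the
# ground-state-switch model.

log_times <- function(n = 200, lo = 1e-3, hi = 20)
  exp(seq(log(lo), log(hi), length.out = n))

test_that("noiseless exponential traces are recovered exactly", {
  tt <- log_times()
  f1 <- fit_exponentials(kinetic_trace(tt, 0.1 + 0.8 * exp(-5 * tt),
                                       1, "unfold-single"))
  expect_equal(f1$n_phases, 1L)
  expect_equal(f1$rates, 5, tolerance = 1e-4)
  f2 <- fit_exponentials(kinetic_trace(
    tt, 0.1 + 0.5 * exp(-10 * tt) + 0.4 * exp(-0.5 * tt),
    1, "refold-double"))
  expect_equal(f2$n_phases, 2L)
  expect_equal(f2$rates, c(10, 0.5), tolerance = 5e-3)
  # amplitudes are referenced to the start of the post-dead-time
  # window (2 ms), not to t = 0
  expect_equal(f2$amplitudes, c(0.5 * exp(-10 * 0.002), 0.4),
               tolerance = 5e-3)
})

test_that("model selection does not overfit phases at realistic noise", {
  correct <- vapply(1:30, function(s) {
    set.seed(s)
    tt <- log_times()
    y <- 0.1 + 0.5 * exp(-10 * tt) + 0.4 * exp(-0.5 * tt) +
      rnorm(length(tt), sd = 0.9 / 20)
    fit_exponentials(kinetic_trace(tt, y, 1, "refold-double"))$n_phases == 2L
  }, logical(1))
  expect_gte(mean(correct), 0.9)
})

test_that("double-jump refolds fit two phases, single-jump adds a third", {
  g2 <- make_chevron_traces(preset = "conserpin", seed = 9,
                            denaturant_grid = 1.0)
  f2 <- fit_exponentials(g2$traces[[1]], max_phases = 3)
  expect_equal(f2$n_phases, 2L)
  g3 <- make_chevron_traces(preset = "conserpin", seed = 9,
                            denaturant_grid = 1.0,
                            scheme = "refold-single")
  f3 <- fit_exponentials(g3$traces[[1]], max_phases = 3)
  expect_equal(f3$n_phases, 3L)
})

test_that("phase labels stay continuous through a limb crossing", {
  g <- make_chevron_traces(preset = "conserpin", snr = 20, seed = 2003)
  ds <- chevron_from_traces(g$traces)
  pts <- ds$points[!ds$points$flagged, ]
  fast <- pts[pts$phase == "refold-fast", ]
  tru <- g$truth$per_concentration
  # below the crossing the fast label must track the generator's fast
  # rate, not the rank at each concentration
  low <- fast[fast$denaturant <= 1.75, ]
  for (i in seq_len(nrow(low))) {
    k_true <- tru$k_fast[tru$denaturant == low$denaturant[i]]
    expect_lt(abs(low$ln_k[i] - log(k_true)), 0.4)
  }
  # past the crossing the (now slower) fast limb is still labelled fast
  post <- fast[fast$denaturant >= 2.5, ]
  expect_gte(nrow(post), 1)
  for (i in seq_len(nrow(post))) {
    k_true <- tru$k_fast[tru$denaturant == post$denaturant[i]]
    expect_lt(abs(post$ln_k[i] - log(k_true)), 0.4)
  }
})

test_that("chevron assembly is invariant to input order", {
  g <- make_chevron_traces(preset = "conserpin", snr = 20, seed = 77)
  ds1 <- chevron_from_traces(g$traces)
  set.seed(1)
  ds2 <- chevron_from_traces(sample(g$traces))
  o1 <- ds1$points[order(ds1$points$phase, ds1$points$denaturant), ]
  o2 <- ds2$points[order(ds2$points$phase, ds2$points$denaturant), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("a two-state chevron recovers its V shape and midpoint", {
  # synthetic two-state: ln k = ln(kf e^-mkf D + ku e^+mku D)
  D <- seq(0.25, 5, by = 0.25)
  lnk <- log(exp(5 - 1.7 * D) + exp(-3 + 1.7 * D))
  pts <- data.frame(denaturant = D, ln_k = lnk,
                    phase = ifelse(D < 2.35, "refold-fast", "unfolding"),
                    amplitude = 0.5, flagged = FALSE)
  ds <- structure(list(points = pts), class = "chevron_dataset")
  cf <- fit_chevron(ds, "two-state")
  expect_equal(cf$m_kf, 1.7, tolerance = 0.02)
  expect_equal(cf$m_ku, 1.7, tolerance = 0.02)
  expect_equal(cf$kinetic_midpoint, 8 / 3.4, tolerance = 0.02)
})

test_that("kinetic and equilibrium analyses agree for shared thermodynamics", {
  # two-state folder: m_DN = RT (m_kf + m_ku), D50 = kinetic midpoint
  m_kf <- 1.7; m_ku <- 1.7
  m_DN <- RT298 * (m_kf + m_ku)
  D50 <- 8 / 3.4
  D <- seq(0.25, 5, by = 0.25)
  lnk <- log(exp(5 - m_kf * D) + exp(-3 + m_ku * D))
  pts <- data.frame(denaturant = D, ln_k = lnk,
                    phase = ifelse(D < D50, "refold-fast", "unfolding"),
                    amplitude = 0.5, flagged = FALSE)
  cf <- fit_chevron(structure(list(points = pts),
                              class = "chevron_dataset"), "two-state")
  g <- make_equilibrium_curve(D50 = D50, m = m_DN, noise_sd = 0.005,
                              seed = 5)
  ef <- fit_two_state(g$curve)
  expect_lt(abs(RT298 * (cf$m_kf + cf$m_ku) - ef$m_DN) / ef$m_DN, 0.05)
  expect_lt(abs(cf$kinetic_midpoint - ef$D50), 0.1)
})

test_that("requesting two-state on ground-state-switch data warns", {
  g <- make_chevron_traces(preset = "conserpin", snr = 20, seed = 55)
  ds <- chevron_from_traces(g$traces)
  expect_warning(fit_chevron(ds, "two-state"), "positive refolding slope")
})

test_that("the refolding slope flips sign around the ground-state switch", {
  # analytic property of the model: positive limb when I1 is the
  # ground state (m_DI/RT > m_kf), negative once D takes over
  g <- make_chevron_traces(preset = "conserpin", snr = 20, seed = 60)
  p <- g$truth
  refold <- function(D) p$ln_kf - p$m_kf * D -
    log(1 + exp(-(p$dG_DI + p$m_DI * D) / RT298))
  slope <- function(D) (refold(D + 1e-4) - refold(D - 1e-4)) / 2e-4
  cross <- -p$dG_DI / p$m_DI
  expect_gt(slope(cross - 1.5), 0)
  expect_lt(slope(cross + 0.6), 0)
})

test_that("the ground-state-switch fit recovers noiseless landmarks exactly", {
  g <- make_chevron_traces(preset = "conserpin", snr = 20, seed = 70)
  tru <- g$truth$per_concentration
  keep_f <- tru$denaturant <= 2.75
  keep_s <- keep_f & tru$k_slow <= 600 & tru$k_slow >= 1e-3
  keep_u <- tru$denaturant > 2.75 & tru$k_fast <= 600
  pts <- rbind(
    data.frame(denaturant = tru$denaturant[keep_f],
               ln_k = log(tru$k_fast[keep_f]), phase = "refold-fast",
               amplitude = 0.6, flagged = FALSE),
    data.frame(denaturant = tru$denaturant[keep_s],
               ln_k = log(tru$k_slow[keep_s]), phase = "refold-slow",
               amplitude = 0.3, flagged = FALSE),
    data.frame(denaturant = tru$denaturant[keep_u],
               ln_k = log(tru$k_fast[keep_u]), phase = "unfolding",
               amplitude = -0.8, flagged = FALSE))
  cf <- fit_chevron(structure(list(points = pts),
                              class = "chevron_dataset"),
                    "ground-state-switch")
  expect_equal(cf$crossover_conc, 2.0, tolerance = 1e-4)
  expect_equal(cf$kinetic_midpoint, 2.75, tolerance = 1e-3)
  expect_equal(cf$crossover_conc_slow, 2.75, tolerance = 1e-3)
})

test_that("phase-origin diagnostics separate the three mechanisms", {
  verdicts <- function(preset, n = 6) vapply(seq_len(n), function(s) {
    g <- make_chevron_traces(preset = preset, snr = 20, seed = 8000 + s)
    diagnose_phase_origin(NULL, chevron_from_traces(g$traces))$verdict
  }, character(1))
  vp <- verdicts("conserpin")
  vs <- verdicts("sequential")
  vt <- verdicts("two-probe")
  expect_gte(mean(vp == "parallel-ground-states"), 5 / 6)
  expect_gte(mean(vs == "sequential"), 5 / 6)
  expect_gte(mean(vt == "independent-probes"), 5 / 6)
})
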