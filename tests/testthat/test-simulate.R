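# The synthetic-data generators: determinism, truth records, and
# fidelity of the planted signals.

test_that("generators are bitwise deterministic under a fixed seed", {
  expect_identical(make_msa(n_seq = 30, seed = 5),
                   make_msa(n_seq = 30, seed = 5))
  expect_identical(make_equilibrium_curve(preset = "conserpin", seed = 5),
                   make_equilibrium_curve(preset = "conserpin", seed = 5))
  expect_identical(make_chevron_traces(seed = 5),
                   make_chevron_traces(seed = 5))
  expect_identical(make_melt(preset = "alpha1at", seed = 5),
                   make_melt(preset = "alpha1at", seed = 5))
  expect_identical(make_si_titration(seed = 5), make_si_titration(seed = 5))
  expect_identical(make_toy_structure("hollow_sphere"),
                   make_toy_structure("hollow_sphere"))
})

test_that("changing the seed changes only the noise, not the truth", {
  a <- make_equilibrium_curve(preset = "conserpin", seed = 1)
  b <- make_equilibrium_curve(preset = "conserpin", seed = 2)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$curve$signal, b$curve$signal))
  expect_identical(a$curve$denaturant, b$curve$denaturant)
  m1 <- make_melt(preset = "alpha1at", seed = 1)
  m2 <- make_melt(preset = "alpha1at", seed = 2)
  expect_identical(m1$truth, m2$truth)
})

test_that("zero substitution rate reproduces the consensus exactly", {
  g <- make_msa(n_seq = 10, substitution_rate = 0, seed = 2)
  expect_true(all(g$alignment$seqs == g$truth$consensus))
  cs <- consensus(g$alignment)
  expect_equal(cs$consensus, g$truth$consensus)
})

test_that("an impossible substitution rate fails informatively", {
  expect_error(make_msa(n_seq = 4, substitution_rate = 0.5, seed = 1,
                        max_attempts = 2), "plurality")
  expect_error(make_msa(substitution_rate = 0.9), "substitution_rate")
})

test_that("noiseless equilibrium curves lie exactly on the model", {
  g <- make_equilibrium_curve(preset = "conserpin", noise_sd = 0, seed = 1)
  pred <- sb_oracle(g$curve$denaturant, 2.75, 8.45, 1, -0.02, 0.15, -0.01)
  expect_equal(g$curve$signal, pred, tolerance = 1e-12)
  # fraction folded is exactly one half at the midpoint
  f <- fit_two_state(g$curve)
  RT <- 1.987e-3 * 298.15
  frac_at_mid <- 1 / (1 + exp(f$m_DN * (f$D50 - f$D50) / RT))
  expect_identical(frac_at_mid, 0.5)
})

test_that("noiseless chevron trace decay rates equal the model rates", {
  g <- make_chevron_traces(preset = "conserpin", snr = 20, seed = 1,
                           denaturant_grid = c(1, 4))
  tru <- g$truth$per_concentration
  # refolding trace at 1 M: fit without noise by regenerating signal
  tr <- g$traces[[1]]
  k <- c(tru$k_fast[1], tru$k_slow[1])
  amps <- c(tru$amp_fast[1], tru$amp_slow[1])
  clean <- 0.1 + amps[1] * exp(-k[1] * tr$time) +
    amps[2] * exp(-k[2] * tr$time)
  f <- fit_exponentials(kinetic_trace(tr$time, clean, 1, "refold-double"))
  expect_equal(f$rates, sort(k, decreasing = TRUE), tolerance = 1e-3)
})

test_that("the chevron presets differ only in their amplitude patterns", {
  a <- make_chevron_traces(preset = "conserpin", seed = 3)
  b <- make_chevron_traces(preset = "sequential", seed = 3)
  cc <- make_chevron_traces(preset = "two-probe", seed = 3)
  # rate limbs are shared; compare on the concentrations every preset
  # observed (sequential loses late-refolding traces with its fast
  # phase)
  shared <- Reduce(intersect, list(a$truth$per_concentration$denaturant,
                                   b$truth$per_concentration$denaturant,
                                   cc$truth$per_concentration$denaturant))
  pick <- function(x) x$truth$per_concentration$k_fast[
    match(shared, x$truth$per_concentration$denaturant)]
  expect_equal(pick(a), pick(b))
  expect_equal(pick(a), pick(cc))
  ra <- a$truth$per_concentration$amp_fast / a$truth$per_concentration$amp_slow
  rc <- cc$truth$per_concentration$amp_fast / cc$truth$per_concentration$amp_slow
  expect_gt(max(ra) / min(ra), 1.5)      # drifting ratio
  expect_equal(max(rc), min(rc))         # constant ratio
  bf <- b$truth$per_concentration
  expect_lt(min(bf$amp_fast), 0.01)      # fast phase dies off
})

test_that("flat melt presets carry no transition", {
  g <- make_melt(preset = "conserpin-native", seed = 7)
  expect_equal(g$truth$model, "none")
  expect_false(detect_transition(g$curve)$transition)
  expect_equal(range(g$curve$temperature), c(20, 110))
})

test_that("melt Tm recovery is tight across replicates", {
  tms <- vapply(1:40, function(s)
    fit_melt(make_melt(preset = "zconserpin-2M",
                       seed = 6000 + s)$curve, "two-state")$Tm,
    numeric(1))
  expect_lt(abs(mean(tms) - 60.7), 0.3)
})

test_that("titrations start at full activity and recover their SI", {
  g <- make_si_titration(SI = 1.8, noise_sd = 0, seed = 1)
  expect_equal(g$titration$residual_activity[g$titration$ratio == 0], 1)
  expect_equal(stoichiometry(g$titration)$SI, 1.8, tolerance = 1e-8)
})

test_that("toy structures carry their planted features", {
  sb <- make_toy_structure("salt_bridge")
  expect_equal(salt_bridges(sb$model)$count, 1L)
  hb <- make_toy_structure("hbond")
  expect_equal(hydrogen_bonds(hb$model)$count, 1L)
  hs <- make_toy_structure("hollow_sphere", void_radius = 4)
  expect_equal(hs$truth$void_volume, 4 / 3 * pi * 64)
  hx <- make_toy_structure("helix", n_res = 10)
  expect_equal(nrow(hx$model$atoms), 40L)
})
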