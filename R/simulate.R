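# Deterministic synthetic-data generators. Every generator takes a
# seed, emits the same formats the analysis functions consume, and
# returns a machine-readable `truth` record holding the generating
# parameters, so parameter-recovery tests can compare fit against
# ground truth. Named presets carry the published biophysical
# parameters of the consensus-designed serpin ("conserpin"), its
# Z-variant, and alpha-1-antitrypsin; all other generator settings
# (baselines, enthalpies, limb slopes, grids) are documented defaults.

# --- preset tables ----------------------------------------------------

.EQ_PRESETS <- list(
  conserpin   = list(D50 = 2.75, m = 8.45),
  zconserpin  = list(D50 = 2.51, m = 5.18))

.MELT_PRESETS <- list(
  `zconserpin-2M` = list(model = "two-state", Tm = 60.7, dH = 110,
                         t_range = c(20, 95)),
  `conserpin-2M`  = list(model = "two-state", Tm = 72.5, dH = 130,
                         t_range = c(20, 95)),
  `conserpin-native` = list(model = "none", t_range = c(20, 110)),
  `alpha1at` = list(model = "three-state", Tm1 = 61.8, dH1 = 120,
                    Tm2 = 97, dH2 = 150, t_range = c(20, 95)))

# Chevron preset: rapid pre-equilibrium ground-state-switch model with
# an I1/D crossover at 2.00 M, a slow (I2) limb whose ground state
# switches at the denaturant midpoint 2.75 M, a limb crossing just
# above 2 M, and the observed fast refolding rate equal to the
# unfolding rate at 2.75 M. ln k_u is derived from that midpoint
# condition.
.chevron_preset <- function(name = "conserpin", temperature = .T_DEFAULT) {
  RT <- rt_kcal(temperature)
  p <- list(ln_kf = log(2000), m_kf = 1.5, dG_DI = -4.0, m_DI = 2.0,
            ln_kf2 = log(2.9e5), m_kf2 = 1.5, dG_DI2 = -12.375, m_DI2 = 4.5,
            m_ku = 0.9, midpoint = 2.75, temperature = temperature)
  p$ln_ku <- p$ln_kf - p$m_kf * p$midpoint -
    log(1 + .K_DI(p$midpoint, p$dG_DI, p$m_DI, RT)) - p$m_ku * p$midpoint
  p$crossover <- -p$dG_DI / p$m_DI
  p$crossover_slow <- -p$dG_DI2 / p$m_DI2
  p$mechanism <- switch(name,
                        conserpin = "parallel-ground-states",
                        sequential = "sequential",
                        `two-probe` = "independent-probes",
                        .stop2("unknown chevron preset: ", name))
  p
}

# --- MSA generator ----------------------------------------------------

#' Generate a protein MSA with a planted consensus
#'
#' Each sequence is the planted consensus with i.i.d. substitutions
#' (uniform over the 19 alternative residues). Redundant clusters are
#' near-copies (at most 2% divergence from a common cluster seed);
#' incomplete sequences are truncated to the first
#' `incomplete_coverage` fraction of columns, the remainder gapped.
#' After generation the planted residue is verified to be the strict
#' plurality in every column; otherwise the draw is repeated (up to
#' `max_attempts`) before failing.
#'
#' @param consensus_seq Planted consensus; default a random 420-residue
#'   sequence.
#' @param n_seq Total number of sequences (default 219).
#' @param substitution_rate Per-site substitution probability in
#'   \[0, 0.5\] (default 0.1).
#' @param n_redundant_clusters Number of near-duplicate clusters
#'   (default 0); each cluster contributes `cluster_size` members.
#' @param cluster_size Members per cluster (default 3).
#' @param incomplete_fraction Fraction of sequences emitted as
#'   incomplete fragments (default 0).
#' @param incomplete_coverage Non-gap coverage of the fragments
#'   (default 0.4).
#' @param seed Integer seed.
#' @param max_attempts Regeneration attempts when the consensus is not
#'   plurality at every column (default 5).
#' @return A list: `alignment` ([aligned_seqs]) and `truth`
#'   (`consensus`, `fragment_ids`, `cluster_ids`).
#' @export
make_msa <- function(consensus_seq = NULL, n_seq = 219,
                     substitution_rate = 0.1, n_redundant_clusters = 0,
                     cluster_size = 3, incomplete_fraction = 0,
                     incomplete_coverage = 0.4, seed = 1,
                     max_attempts = 5) {
  if (substitution_rate < 0 || substitution_rate > 0.5)
    .stop2("substitution_rate must be in [0, 0.5]")
  set.seed(seed)
  if (is.null(consensus_seq))
    consensus_seq <- paste(sample(.AA20, 420, replace = TRUE), collapse = "")
  cons <- strsplit(toupper(consensus_seq), "")[[1L]]
  L <- length(cons)
  mutate <- function(base, rate) {
    hit <- stats::runif(L) < rate
    if (any(hit)) {
      repl <- vapply(base[hit], function(aa)
        sample(setdiff(.AA20, aa), 1L), character(1))
      base[hit] <- repl
    }
    base
  }
  n_frag <- round(incomplete_fraction * n_seq)
  n_clustered <- n_redundant_clusters * cluster_size
  n_plain <- n_seq - n_frag - n_clustered
  if (n_plain < 1L) .stop2("no room for independent sequences")
  for (attempt in seq_len(max_attempts)) {
    rows <- character(n_seq)
    ids <- character(n_seq)
    cluster_ids <- rep(NA_integer_, n_seq)
    k <- 0L
    for (i in seq_len(n_plain)) {
      k <- k + 1L
      rows[k] <- paste(mutate(cons, substitution_rate), collapse = "")
      ids[k] <- sprintf("seq%03d", k)
    }
    for (cl in seq_len(n_redundant_clusters)) {
      seed_row <- mutate(cons, substitution_rate)
      for (j in seq_len(cluster_size)) {
        k <- k + 1L
        rows[k] <- paste(mutate(seed_row, 0.02), collapse = "")
        ids[k] <- sprintf("clu%02d_%d", cl, j)
        cluster_ids[k] <- cl
      }
    }
    n_keep <- floor(incomplete_coverage * L)
    for (i in seq_len(n_frag)) {
      k <- k + 1L
      frag <- mutate(cons, substitution_rate)
      frag[(n_keep + 1L):L] <- "-"
      rows[k] <- paste(frag, collapse = "")
      ids[k] <- sprintf("frag%02d", i)
    }
    aln <- aligned_seqs(ids, rows)
    # verify the planted residue is the strict plurality everywhere
    prof <- unclass(column_profiles(aln))
    winners_ok <- all(vapply(seq_len(L), function(j) {
      rc <- prof[.AA20, j]
      rc[cons[j]] > max(rc[setdiff(.AA20, cons[j])])
    }, logical(1)))
    if (winners_ok) {
      return(list(alignment = aln,
                  truth = list(consensus = consensus_seq,
                               fragment_ids = ids[grepl("^frag", ids)],
                               cluster_ids = cluster_ids)))
    }
  }
  .stop2("planted consensus not plurality after ", max_attempts,
         " attempts; lower substitution_rate")
}

# --- equilibrium curve generator --------------------------------------

#' Generate a two-state equilibrium denaturation curve
#'
#' Santoro-Bolen signal plus Gaussian noise expressed as a fraction of
#' the native-to-denatured signal span.
#'
#' @param preset `"conserpin"` (D50 2.75 M, m 8.45 kcal/mol/M) or
#'   `"zconserpin"` (2.51 M, 5.18), or `NULL` with explicit `D50`/`m`.
#' @param D50,m Generating midpoint (M) and m-value (kcal/mol/M) when
#'   no preset is used.
#' @param baselines List with `aN`, `bN`, `aD`, `bD` (defaults 1,
#'   -0.02, 0.15, -0.01: sloped fluorescence baselines).
#' @param denaturant Denaturant grid. The default (`NULL`) emulates a
#'   designed titration: 25 points spanning 0-6 M with 12 coarse
#'   baseline points and 13 fine points across the transition
#'   (midpoint +/- 0.9 M), since a uniform grid leaves a steep serpin
#'   transition essentially unsampled and the m-value unidentifiable.
#' @param noise_sd Gaussian noise as a fraction of span (default 0.02).
#' @param direction,probe Curve annotations.
#' @param temperature Temperature (K).
#' @param seed Integer seed.
#' @return A list: `curve` (`denaturation_curve`) and `truth`.
#' @export
make_equilibrium_curve <- function(preset = NULL, D50 = NULL, m = NULL,
                                   baselines = list(aN = 1, bN = -0.02,
                                                    aD = 0.15, bD = -0.01),
                                   denaturant = NULL,
                                   noise_sd = 0.02,
                                   direction = "unfolding",
                                   probe = "intrinsic-fluorescence",
                                   temperature = .T_DEFAULT, seed = 1) {
  if (!is.null(preset)) {
    p <- .EQ_PRESETS[[preset]]
    if (is.null(p)) .stop2("unknown equilibrium preset: ", preset)
    D50 <- p$D50; m <- p$m
  }
  if (is.null(D50) || is.null(m)) .stop2("supply a preset or D50 and m")
  if (is.null(denaturant))
    denaturant <- sort(c(seq(0, 6, length.out = 12),
                         seq(D50 - 0.9, D50 + 0.9, length.out = 13)))
  RT <- rt_kcal(temperature)
  if (min(denaturant) > D50 - 0.5 || max(denaturant) < D50 + 0.5)
    warning("denaturant grid barely spans the transition", call. = FALSE)
  set.seed(seed)
  y0 <- .sb_signal(denaturant, D50, m, baselines$aN, baselines$bN,
                   baselines$aD, baselines$bD, RT)
  span <- abs((baselines$aN + baselines$bN * D50) -
                (baselines$aD + baselines$bD * D50))
  y <- y0 + stats::rnorm(length(denaturant), sd = noise_sd * span)
  list(curve = denaturation_curve(denaturant, y, direction, probe),
       truth = list(D50 = D50, m = m, dG = -m * D50,
                    baselines = baselines, noise_sd = noise_sd,
                    temperature = temperature))
}

#' Generate a bis-ANS unfolding profile with an optional peak
#'
#' Flat (linearly sloping) baseline with a Gaussian intermediate peak,
#' emulating dye binding to exposed hydrophobic surface of a
#' transiently populated species.
#'
#' @param peak_position Peak centre (M); `NA` for no peak.
#' @param peak_height Peak height above baseline (a.u.).
#' @param peak_width Gaussian sigma (M).
#' @param denaturant Grid (default 0-6 M, 61 points).
#' @param baseline_level,baseline_slope Baseline (default 1, 0).
#' @param noise_sd Absolute Gaussian noise sd (default 0.01).
#' @param seed Integer seed.
#' @return A list: `curve` (bis-ANS `denaturation_curve`) and `truth`.
#' @export
make_ans_profile <- function(peak_position = 3.0, peak_height = 0.5,
                             peak_width = 0.25,
                             denaturant = seq(0, 6, by = 0.1),
                             baseline_level = 1, baseline_slope = 0,
                             noise_sd = 0.01, seed = 1) {
  set.seed(seed)
  y <- baseline_level + baseline_slope * denaturant
  if (!is.na(peak_position))
    y <- y + peak_height * exp(-(denaturant - peak_position)^2 /
                                 (2 * peak_width^2))
  y <- y + stats::rnorm(length(denaturant), sd = noise_sd)
  list(curve = denaturation_curve(denaturant, y, "unfolding", "bis-ANS"),
       truth = list(peak_position = peak_position,
                    peak_height = peak_height, peak_width = peak_width))
}

# --- chevron trace generator ------------------------------------------

# model rates and amplitudes at one denaturant for a chevron preset
.chevron_truth_at <- function(D, p) {
  RT <- rt_kcal(p$temperature)
  k_fast <- .k_fast_obs(D, p$ln_kf, p$m_kf, p$dG_DI, p$m_DI,
                        p$ln_ku, p$m_ku, RT)
  k_slow <- .k_slow_obs(D, p$ln_kf2, p$m_kf2, p$dG_DI2, p$m_DI2, RT)
  amp_fast <- switch(p$mechanism,
                     "parallel-ground-states" = 0.60,
                     "sequential" = 0.60 / (1 + exp((D - 2.05) / 0.03)),
                     "independent-probes" = 0.50)
  amp_slow <- switch(p$mechanism,
                     "parallel-ground-states" = 0.10 + 0.35 * D / 2.75,
                     "sequential" = 0.10 + 0.35 * D / 2.75,
                     "independent-probes" = 0.25)
  list(k_fast = k_fast, k_slow = k_slow,
       amp_fast = amp_fast, amp_slow = amp_slow)
}

#' Generate stopped-flow traces along a denaturant grid
#'
#' Produces, for every grid concentration, a refolding trace (final
#' denaturant at or below the midpoint; double-jump double-exponential
#' by default) or an unfolding trace (above the midpoint;
#' single-exponential). Rates follow the ground-state-switch chevron
#' of the preset; amplitudes follow the preset's mechanistic variant
#' (`"conserpin"`: two parallel structured ground states, fast phase
#' persists past the limb crossing and the amplitude ratio drifts;
#' `"sequential"`: the fast phase's amplitude vanishes past the
#' crossing; `"two-probe"`: constant amplitude ratio). Phases slower
#' than `rate_floor` fall outside the observation window and are
#' omitted from the trace. `scheme = "refold-single"` adds a slow
#' aggregation-contaminant third phase to refolding traces.
#'
#' @param preset `"conserpin"`, `"sequential"` or `"two-probe"`.
#' @param denaturant_grid Final denaturant concentrations (default
#'   0.25-6 M in 0.25 M steps).
#' @param snr Signal-to-noise ratio (span over noise sd); must exceed
#'   1 (default 20).
#' @param n_points Points per trace (default 200, log-spaced).
#' @param scheme Refolding scheme: `"refold-double"` (default) or
#'   `"refold-single"` (adds the contaminant phase).
#' @param rate_floor Slowest observable rate (s^-1, default 1e-3).
#' @param rate_ceiling Fastest observable rate (s^-1, default 600):
#'   phases lost in the instrument dead time are omitted, and a
#'   concentration whose phases are all unobservable yields no trace.
#' @param temperature Temperature (K).
#' @param seed Integer seed.
#' @return A list: `traces` (list of `kinetic_trace`) and `truth`
#'   (preset parameters plus per-concentration rates/amplitudes).
#' @export
make_chevron_traces <- function(preset = "conserpin",
                                denaturant_grid = seq(0.25, 6, by = 0.25),
                                snr = 20, n_points = 200,
                                scheme = c("refold-double", "refold-single"),
                                rate_floor = 1e-3, rate_ceiling = 600,
                                temperature = .T_DEFAULT, seed = 1) {
  scheme <- match.arg(scheme)
  if (snr <= 1) .stop2("snr must exceed 1")
  name <- if (preset == "two-probe") "two-probe" else preset
  p <- .chevron_preset(name, temperature)
  set.seed(seed)
  traces <- list()
  per_conc <- list()
  for (D in denaturant_grid) {
    tr_at <- .chevron_truth_at(D, p)
    if (D <= p$midpoint) {
      rates <- c(tr_at$k_fast, tr_at$k_slow)
      amps <- c(tr_at$amp_fast, tr_at$amp_slow)
      if (scheme == "refold-single") {
        rates <- c(rates, 0.05 * tr_at$k_slow)
        amps <- c(amps, 0.15)
      }
      keep <- rates >= rate_floor & rates <= rate_ceiling & amps > 1e-3
      rates <- rates[keep]; amps <- amps[keep]
      sch <- if (scheme == "refold-double") "refold-double"
             else "refold-single"
    } else {
      rates <- tr_at$k_fast          # unfolding-dominated observed rate
      amps <- -0.8
      if (rates > rate_ceiling || rates < rate_floor) rates <- numeric(0)
      sch <- "unfold-single"
    }
    if (!length(rates)) next
    t_end <- 5 / min(rates)
    t0 <- min(1e-3, 0.1 / max(rates))
    tt <- exp(seq(log(t0), log(t_end), length.out = n_points))
    y <- rep(0.1, n_points)
    for (i in seq_along(rates)) y <- y + amps[i] * exp(-rates[i] * tt)
    noise <- sum(abs(amps)) / snr
    y <- y + stats::rnorm(n_points, sd = noise)
    traces[[length(traces) + 1L]] <-
      kinetic_trace(tt, y, D, sch,
                    delay_time = if (sch == "refold-double") 5 else NA_real_)
    per_conc[[length(per_conc) + 1L]] <-
      data.frame(denaturant = D, k_fast = tr_at$k_fast,
                 k_slow = tr_at$k_slow, amp_fast = tr_at$amp_fast,
                 amp_slow = tr_at$amp_slow)
  }
  list(traces = traces,
       truth = c(p, list(per_concentration = do.call(rbind, per_conc),
                         snr = snr, scheme = scheme)))
}

# --- thermal melt generator -------------------------------------------

#' Generate a thermal melt curve
#'
#' Two-state or sequential three-state van't Hoff melts with linear
#' baselines (CD-at-222-nm-like negative signals), or a transitionless
#' scan, plus Gaussian noise as a fraction of signal span.
#'
#' @param preset One of `"zconserpin-2M"` (two-state, Tm 60.7 C),
#'   `"conserpin-2M"` (72.5 C), `"conserpin-native"` (no transition up
#'   to 110 C), `"alpha1at"` (three-state, Tm1 61.8 C, second
#'   transition starting near 90 C, incomplete within the scan), or
#'   `NULL` with explicit parameters.
#' @param model,Tm,dH,Tm2,dH2 Explicit model (`"none"`, `"two-state"`,
#'   `"three-state"`) and parameters when no preset is used.
#' @param t_range Scan range in deg C (preset default; else 20-95).
#' @param t_step Scan step (default 1 C).
#' @param noise_sd Noise as fraction of span (default 0.01).
#' @param seed Integer seed.
#' @return A list: `curve` (`melt_curve`) and `truth`.
#' @export
make_melt <- function(preset = NULL, model = "two-state", Tm = 60,
                      dH = 100, Tm2 = NA, dH2 = NA, t_range = NULL,
                      t_step = 1, noise_sd = 0.01, seed = 1) {
  if (!is.null(preset)) {
    p <- .MELT_PRESETS[[preset]]
    if (is.null(p)) .stop2("unknown melt preset: ", preset)
    model <- p$model
    if (model == "two-state") { Tm <- p$Tm; dH <- p$dH }
    if (model == "three-state") { Tm <- p$Tm1; dH <- p$dH1
                                  Tm2 <- p$Tm2; dH2 <- p$dH2 }
    if (is.null(t_range)) t_range <- p$t_range
  }
  if (is.null(t_range)) t_range <- c(20, 95)
  Tc <- seq(t_range[1L], t_range[2L], by = t_step)
  # CD222-like baselines: folded strongly negative, unfolded shallow
  aN <- -10; bN <- -0.01; aI <- -6; bI <- -0.005; aU <- -1.5; bU <- 0
  set.seed(seed)
  y0 <- switch(model,
               none = aN + bN * Tc,
               `two-state` = .melt2_signal(Tc, Tm, dH, aN, bN, aU, bU),
               `three-state` = .melt3_signal(Tc, Tm, dH, Tm2, dH2,
                                             aN, bN, aI, bI, aU, bU),
               .stop2("unknown melt model: ", model))
  span <- if (model == "none") abs(aN - aU) else diff(range(y0))
  y <- y0 + stats::rnorm(length(Tc), sd = noise_sd * span)
  list(curve = melt_curve(Tc, y),
       truth = list(model = model, Tm = Tm, dH = dH, Tm2 = Tm2,
                    dH2 = dH2, noise_sd = noise_sd, t_range = t_range))
}

#' Generate a pair of far-UV CD spectra
#'
#' Helix-like double-minimum spectra for before/after comparisons;
#' `scale` multiplies the after-spectrum to emulate structural loss.
#'
#' @param scale Multiplier applied to the second spectrum (default 1).
#' @param noise_sd Absolute noise sd (default 0.05).
#' @param seed Integer seed.
#' @return A list: `before`, `after` (data frames `wavelength_nm`,
#'   `signal`).
#' @export
make_spectra_pair <- function(scale = 1, noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  w <- seq(190, 260, by = 0.5)
  shape <- -8 * exp(-(w - 208)^2 / 50) - 8 * exp(-(w - 222)^2 / 60) +
    10 * exp(-(w - 192)^2 / 18)
  before <- shape + stats::rnorm(length(w), sd = noise_sd)
  after <- scale * shape + stats::rnorm(length(w), sd = noise_sd)
  list(before = data.frame(wavelength_nm = w, signal = before),
       after = data.frame(wavelength_nm = w, signal = after))
}

# --- SI titration generator -------------------------------------------

#' Generate a stoichiometry-of-inhibition titration
#'
#' Residual activity falls linearly with serpin:protease ratio,
#' reaching zero at the SI, then plateaus; Gaussian noise on activity.
#'
#' @param SI Generating stoichiometry (default 1.8).
#' @param ratios Molar ratio grid (default 0 to 1.6*SI in 9 steps).
#' @param noise_sd Activity noise sd (default 0.03).
#' @param seed Integer seed.
#' @return A list: `titration` (`si_titration`) and `truth`.
#' @export
make_si_titration <- function(SI = 1.8, ratios = NULL, noise_sd = 0.03,
                              seed = 1) {
  if (is.null(ratios)) ratios <- seq(0, 1.6 * SI, length.out = 9)
  set.seed(seed)
  act <- pmax(0, 1 - ratios / SI) + stats::rnorm(length(ratios),
                                                 sd = noise_sd)
  act <- pmin(pmax(act, 0), 1.1)
  list(titration = si_titration(ratios, act),
       truth = list(SI = SI, noise_sd = noise_sd))
}

# --- toy structure generator ------------------------------------------

.atom_row <- function(serial, name, element, resname, resno, chain,
                      x, y, z) {
  data.frame(serial = serial, name = name, element = element,
             resname = resname, resno = resno, insert = "",
             chain = chain, x = x, y = y, z = z, occupancy = 1,
             altloc = "", stringsAsFactors = FALSE)
}

# idealised alpha-helix backbone (N, CA, C, O per residue)
.helix_atoms <- function(n_res, resname = "ALA", chain = "A",
                         resno0 = 1L) {
  rows <- list()
  serial <- 0L
  for (i in seq_len(n_res)) {
    th <- (i - 1) * 100 * pi / 180
    z <- (i - 1) * 1.5
    add <- function(name, element, r, dth, dz) {
      serial <<- serial + 1L
      .atom_row(serial, name, element, resname, resno0 + i - 1L, chain,
                r * cos(th + dth), r * sin(th + dth), z + dz)
    }
    rows[[length(rows) + 1L]] <- add("N", "N", 1.60, -0.50, -0.90)
    rows[[length(rows) + 1L]] <- add("CA", "C", 2.30, 0.00, 0.00)
    rows[[length(rows) + 1L]] <- add("C", "C", 2.00, 0.45, 0.70)
    rows[[length(rows) + 1L]] <- add("O", "O", 2.55, 0.55, 1.00)
  }
  do.call(rbind, rows)
}

#' Generate toy coordinate sets with planted features
#'
#' Kinds: `"helix"` - an idealised poly-Ala alpha-helix backbone
#' (`n_res` residues); `"salt_bridge"` - a Lys and a Glu side chain
#' with the NZ-OE1 distance planted at `distance`; `"hbond"` - a
#' backbone N-H...O pair planted at `distance` with a 150 degree donor
#' angle; `"hollow_sphere"` - a sealed shell of carbon atoms enclosing
#' a solvent-inaccessible void of analytic radius `void_radius`
#' (atom centres sit at `void_radius` + vdW + probe so the interior
#' cavity boundary is exactly the requested sphere).
#'
#' @param kind One of `"helix"`, `"salt_bridge"`, `"hbond"`,
#'   `"hollow_sphere"`.
#' @param n_res Helix length (default 20).
#' @param distance Planted interaction distance (default 3.2 for the
#'   salt bridge, 2.9 for the H-bond).
#' @param void_radius Cavity radius for the hollow sphere (default 4).
#' @param probe_radius Probe radius assumed when sizing the shell
#'   (default 1.4).
#' @param seed Integer seed (used only for jitter-free determinism of
#'   downstream consumers; the geometry itself is deterministic).
#' @return A list: `model` (`structure_model`) and `truth`.
#' @export
make_toy_structure <- function(kind = c("helix", "salt_bridge", "hbond",
                                        "hollow_sphere"),
                               n_res = 20, distance = NULL,
                               void_radius = 4, probe_radius = 1.4,
                               seed = 1) {
  kind <- match.arg(kind)
  if (kind == "helix") {
    atoms <- .helix_atoms(n_res)
    return(list(model = structure_model(atoms),
                truth = list(kind = kind, n_res = n_res)))
  }
  if (kind == "salt_bridge") {
    d <- if (is.null(distance)) 3.2 else distance
    lys <- rbind(
      .atom_row(1L, "CA", "C", "LYS", 1L, "A", 0, 0, 0),
      .atom_row(2L, "CE", "C", "LYS", 1L, "A", 3.0, 0, 0),
      .atom_row(3L, "NZ", "N", "LYS", 1L, "A", 4.5, 0, 0))
    glu <- rbind(
      .atom_row(4L, "CA", "C", "GLU", 2L, "A", 4.5 + d + 2.5, 0, 0),
      .atom_row(5L, "CD", "C", "GLU", 2L, "A", 4.5 + d + 1.2, 0, 0),
      .atom_row(6L, "OE1", "O", "GLU", 2L, "A", 4.5 + d, 0, 0),
      .atom_row(7L, "OE2", "O", "GLU", 2L, "A", 4.5 + d + 1.0, 1.0, 0))
    return(list(model = structure_model(rbind(lys, glu)),
                truth = list(kind = kind, distance = d)))
  }
  if (kind == "hbond") {
    d <- if (is.null(distance)) 2.9 else distance
    ang <- 150 * pi / 180
    # donor N at origin, antecedent CA along -x, acceptor O placed so
    # the CA-N-O angle is 150 degrees
    don <- rbind(
      .atom_row(1L, "CA", "C", "GLY", 1L, "A", -1.46, 0, 0),
      .atom_row(2L, "N", "N", "GLY", 1L, "A", 0, 0, 0))
    acc <- .atom_row(3L, "O", "O", "SER", 5L, "A",
                     d * cos(pi - ang), d * sin(pi - ang), 0)
    return(list(model = structure_model(rbind(don, acc)),
                truth = list(kind = kind, distance = d, angle = 150)))
  }
  # hollow sphere: shell of C atoms at radius void + vdW(C) + probe
  shell_r <- void_radius + .VDW[["C"]] + probe_radius
  n_shell <- ceiling(4 * pi * shell_r^2 / 0.8^2)   # ~0.8 A spacing
  sp <- .sphere_points(n_shell) * shell_r
  atoms <- .atom_row(seq_len(n_shell), "C", "C", "UNK",
                     seq_len(n_shell), "A", sp[, 1L], sp[, 2L], sp[, 3L])
  list(model = structure_model(atoms),
       truth = list(kind = kind, void_radius = void_radius,
                    void_volume = 4 / 3 * pi * void_radius^3,
                    shell_radius = shell_r))
}
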