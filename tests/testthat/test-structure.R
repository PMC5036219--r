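# PDB I/O and structural metrics: H-bonds, salt bridges, ASA,
# cavities, superposition RMSD.

test_that("a minimal PDB file parses to its three atoms", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(minimal_pdb_lines(), tmp)
  m <- read_structure(tmp)
  expect_equal(nrow(m$atoms), 3L)
  expect_equal(m$atoms$name, c("N", "CA", "C"))
  expect_equal(m$sequence[["A"]], "A")
})

test_that("malformed coordinate lines are reported with their number", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  lines <- minimal_pdb_lines()
  lines[2] <- "ATOM      2  CA  ALA A   1      11.639   6.07x  -5.147  1.00"
  writeLines(lines, tmp)
  expect_error(read_structure(tmp), "line 2")
})

test_that("the highest-occupancy altloc wins, ties go to A", {
  mk <- function(occA, occB) {
    a <- rbind(
      data.frame(serial = 1, name = "CA", element = "C", resname = "ALA",
                 resno = 1, insert = "", chain = "A", x = 0, y = 0, z = 0,
                 occupancy = occA, altloc = "A"),
      data.frame(serial = 2, name = "CA", element = "C", resname = "ALA",
                 resno = 1, insert = "", chain = "A", x = 1, y = 0, z = 0,
                 occupancy = occB, altloc = "B"))
    structure_model(a)
  }
  m1 <- mk(0.6, 0.4)
  expect_equal(nrow(m1$atoms), 1L)
  expect_equal(m1$atoms$altloc, "A")
  m2 <- mk(0.4, 0.6)
  expect_equal(m2$atoms$altloc, "B")
  m3 <- mk(0.5, 0.5)
  expect_equal(m3$atoms$altloc, "A")
})

test_that("a 100-residue helix round-trips through PDB text", {
  hx <- make_toy_structure("helix", n_res = 100)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_structure(hx$model, tmp)
  m2 <- read_structure(tmp)
  expect_equal(nrow(m2$atoms), nrow(hx$model$atoms))
  # coordinates identical to the PDB format's 3-decimal precision
  expect_lt(max(abs(as.matrix(m2$atoms[, c("x", "y", "z")]) -
                      as.matrix(hx$model$atoms[, c("x", "y", "z")]))),
            5.1e-4)
})

test_that("hydrogen bonds obey the distance and angle criteria", {
  g <- make_toy_structure("hbond", distance = 2.9)
  hb <- hydrogen_bonds(g$model)
  expect_equal(hb$count, 1L)
  expect_equal(hb$bonds$distance, 2.9, tolerance = 1e-6)
  expect_gte(hb$bonds$angle, 120)
  # same geometry stretched beyond the cutoff
  far <- make_toy_structure("hbond", distance = 5)
  expect_equal(hydrogen_bonds(far$model)$count, 0L)
  # angle rejection: acceptor at 90 degrees from the antecedent
  a <- rbind(
    data.frame(serial = 1, name = "CA", element = "C", resname = "GLY",
               resno = 1, insert = "", chain = "A", x = -1.46, y = 0,
               z = 0, occupancy = 1, altloc = ""),
    data.frame(serial = 2, name = "N", element = "N", resname = "GLY",
               resno = 1, insert = "", chain = "A", x = 0, y = 0, z = 0,
               occupancy = 1, altloc = ""),
    data.frame(serial = 3, name = "O", element = "O", resname = "SER",
               resno = 5, insert = "", chain = "A", x = 0, y = 2.9, z = 0,
               occupancy = 1, altloc = ""))
  expect_equal(hydrogen_bonds(structure_model(a))$count, 0L)
  # every reported bond re-checks against its own cutoffs
  hx <- make_toy_structure("helix", n_res = 12)
  hb2 <- hydrogen_bonds(hx$model)
  if (hb2$count > 0) {
    expect_true(all(hb2$bonds$distance <= 3.5))
    expect_true(all(hb2$bonds$angle >= 120))
  }
})

test_that("salt bridges respect the cutoff and deduplicate atom pairs", {
  g <- make_toy_structure("salt_bridge", distance = 3.2)
  sb <- salt_bridges(g$model)
  expect_equal(sb$count, 1L)
  expect_equal(sb$bridges$distance, 3.2, tolerance = 1e-6)
  far <- make_toy_structure("salt_bridge", distance = 4.5)
  expect_equal(salt_bridges(far$model)$count, 0L)
  # an Arg with both NH1 and NH2 near one Asp counts once
  a <- rbind(
    data.frame(serial = 1, name = "NH1", element = "N", resname = "ARG",
               resno = 1, insert = "", chain = "A", x = 0, y = 0, z = 0,
               occupancy = 1, altloc = ""),
    data.frame(serial = 2, name = "NH2", element = "N", resname = "ARG",
               resno = 1, insert = "", chain = "A", x = 1, y = 0, z = 0,
               occupancy = 1, altloc = ""),
    data.frame(serial = 3, name = "OD1", element = "O", resname = "ASP",
               resno = 2, insert = "", chain = "A", x = 2.5, y = 0, z = 0,
               occupancy = 1, altloc = ""))
  sb2 <- salt_bridges(structure_model(a))
  expect_equal(sb2$count, 1L)
  expect_equal(sb2$bridges$distance, 1.5)  # minimum over atom pairs
})

test_that("isolated-atom ASA matches the analytic sphere for every element", {
  radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
  for (el in names(radii)) {
    m <- structure_model(data.frame(
      serial = 1, name = el, element = el, resname = "UNK", resno = 1,
      insert = "", chain = "A", x = 0, y = 0, z = 0, occupancy = 1,
      altloc = ""))
    asa <- accessible_surface_area(m)
    expect_equal(asa$total, 4 * pi * (radii[[el]] + 1.4)^2,
                 tolerance = 1e-6)
  }
})

test_that("fully overlapping atoms expose the surface of one", {
  a <- rbind(
    data.frame(serial = 1, name = "C1", element = "C", resname = "UNK",
               resno = 1, insert = "", chain = "A", x = 0, y = 0, z = 0,
               occupancy = 1, altloc = ""),
    data.frame(serial = 2, name = "C2", element = "C", resname = "UNK",
               resno = 2, insert = "", chain = "A", x = 0, y = 0, z = 0,
               occupancy = 1, altloc = ""))
  asa <- accessible_surface_area(structure_model(a))
  expect_equal(asa$total, 4 * pi * 3.1^2, tolerance = 0.02)
})

test_that("default sampling matches a dense-sampling oracle within 1%", {
  set.seed(42)
  xyz <- matrix(rnorm(30, sd = 2), 10, 3)
  a <- data.frame(serial = 1:10, name = "C", element = "C",
                  resname = "UNK", resno = 1:10, insert = "",
                  chain = "A", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                  occupancy = 1, altloc = "")
  m <- structure_model(a)
  coarse <- accessible_surface_area(m, n_points = 960)
  dense <- accessible_surface_area(m, n_points = 10000)
  expect_lt(abs(coarse$total - dense$total) / dense$total, 0.01)
})

test_that("ASA is invariant under rigid motion to sampling tolerance", {
  # sphere sample points have a fixed laboratory-frame orientation, so
  # rotating the molecule reshuffles which points sit exactly on
  # neighbour boundaries; agreement is to the sampling resolution
  g <- make_toy_structure("helix", n_res = 15)
  a1 <- accessible_surface_area(g$model)$total
  a2 <- accessible_surface_area(rigid_transform(g$model))$total
  expect_lt(abs(a1 - a2) / a1, 0.005)
})

test_that("cavity detection finds the hollow-sphere void, not slab space", {
  hs <- make_toy_structure("hollow_sphere", void_radius = 4)
  vols <- cavity_volumes(hs$model)
  expect_length(vols, 1)
  expect_lt(abs(vols[1] - hs$truth$void_volume) / hs$truth$void_volume,
            0.1)
  # a compact solid cluster has no interior cavity
  xyz <- as.matrix(expand.grid(x = seq(0, 3, 1.5), y = seq(0, 3, 1.5),
                               z = seq(0, 3, 1.5)))
  solid <- structure_model(data.frame(
    serial = seq_len(nrow(xyz)), name = "C", element = "C",
    resname = "UNK", resno = seq_len(nrow(xyz)), insert = "",
    chain = "A", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, altloc = ""))
  expect_length(cavity_volumes(solid), 0)
  expect_error(cavity_volumes(hs$model, grid_spacing = 2), "probe")
})

test_that("cavity volumes converge under grid refinement", {
  hs <- make_toy_structure("hollow_sphere", void_radius = 4)
  v1 <- cavity_volumes(hs$model, grid_spacing = 1.0)
  v2 <- cavity_volumes(hs$model, grid_spacing = 0.5)
  expect_lt(abs(v1[1] - v2[1]) / v2[1], 0.1)
})

test_that("superposition RMSD satisfies identity, symmetry and rigidity", {
  hx <- make_toy_structure("helix", n_res = 20)
  expect_equal(backbone_rmsd(hx$model, hx$model)$rmsd, 0)
  moved <- rigid_transform(hx$model)
  r <- backbone_rmsd(hx$model, moved, "backbone")
  expect_lt(r$rmsd, 1e-9)
  expect_equal(r$n_atoms_used, 80L)
  # symmetry under argument exchange
  set.seed(8)
  pert <- hx$model
  pert$atoms[, c("x", "y", "z")] <-
    pert$atoms[, c("x", "y", "z")] + rnorm(240, sd = 0.3)
  expect_equal(backbone_rmsd(hx$model, pert)$rmsd,
               backbone_rmsd(pert, hx$model)$rmsd, tolerance = 1e-9)
})

test_that("RMSD of an isotropic perturbation matches its expectation", {
  # per-coordinate sd s => E[RMSD^2] ~ 3 s^2 (minus what superposition
  # absorbs; negligible for many atoms)
  hx <- make_toy_structure("helix", n_res = 40)
  s <- 0.5 / sqrt(3)   # 0.5 A expected displacement per atom
  rmsds <- vapply(1:100, function(seed) {
    set.seed(seed)
    p <- hx$model
    p$atoms[, c("x", "y", "z")] <-
      p$atoms[, c("x", "y", "z")] + rnorm(480, sd = s)
    backbone_rmsd(hx$model, p, "backbone")$rmsd
  }, numeric(1))
  expect_lt(abs(sqrt(mean(rmsds^2)) - 0.5) / 0.5, 0.05)
})

test_that("superposition agrees with an independent implementation", {
  hx <- make_toy_structure("helix", n_res = 25)
  set.seed(12)
  pert <- rigid_transform(hx$model)
  pert$atoms[, c("x", "y", "z")] <-
    pert$atoms[, c("x", "y", "z")] + rnorm(300, sd = 0.4)
  ours <- backbone_rmsd(hx$model, pert, "backbone")$rmsd
  A <- as.matrix(hx$model$atoms[, c("x", "y", "z")])
  B <- as.matrix(pert$atoms[, c("x", "y", "z")])
  ref <- bio3d::rmsd(as.vector(t(A)), as.vector(t(B)), fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("interaction metrics are invariant under rigid motion", {
  g <- make_toy_structure("salt_bridge")
  m2 <- rigid_transform(g$model)
  expect_equal(salt_bridges(m2)$bridges$distance,
               salt_bridges(g$model)$bridges$distance, tolerance = 1e-9)
  h <- make_toy_structure("hbond")
  h2 <- rigid_transform(h$model)
  expect_equal(hydrogen_bonds(h2)$count, 1L)
})
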