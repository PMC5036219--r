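# Comparative structural metrics: hydrogen bonds, salt bridges,
# solvent accessible surface area (Shrake-Rupley), solvent-inaccessible
# cavity volumes (grid flood fill), and optimal-superposition RMSD
# (Kabsch). Heavy-atom geometric criteria are used throughout because
# deposited X-ray structures lack hydrogens.

# van der Waals radii (Angstrom) for ASA/cavity work
.VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
.vdw_radius <- function(element) {
  r <- .VDW[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

.coords <- function(model) as.matrix(model$atoms[, c("x", "y", "z")])

.atom_label <- function(a, i)
  paste(a$resname[i], a$resno[i], a$chain[i], a$name[i])

# donor atom -> antecedent heavy atom, per residue type ('*' = any)
.HB_DONORS <- list(
  c("*", "N", "CA"),
  c("SER", "OG", "CB"), c("THR", "OG1", "CB"), c("TYR", "OH", "CZ"),
  c("LYS", "NZ", "CE"), c("ARG", "NE", "CD"), c("ARG", "NH1", "CZ"),
  c("ARG", "NH2", "CZ"), c("HIS", "ND1", "CG"), c("HIS", "NE2", "CD2"),
  c("ASN", "ND2", "CG"), c("GLN", "NE2", "CD"), c("TRP", "NE1", "CD1"))

#' Hydrogen bonds by heavy-atom geometry
#'
#' A donor (N/O carrying a proton in the standard residue chemistry;
#' proline backbone N excluded) and an acceptor (any N/O) form a bond
#' when the donor-acceptor distance is at most `dist_cutoff` and the
#' antecedent-donor-acceptor angle is at least `angle_cutoff` degrees.
#' Intra-residue pairs are excluded.
#'
#' @param model A `structure_model`.
#' @param dist_cutoff Heavy-atom distance cutoff (Angstrom, default 3.5).
#' @param angle_cutoff Donor angle cutoff (degrees, default 120).
#' @return A list: `count` and `bonds` (data frame `donor`, `acceptor`,
#'   `distance`, `angle`).
#' @export
hydrogen_bonds <- function(model, dist_cutoff = 3.5, angle_cutoff = 120) {
  a <- model$atoms
  xyz <- .coords(model)
  rkey <- paste(a$chain, a$resno, a$insert)
  # enumerate donor atoms with their antecedents
  don_idx <- integer(0); ant_idx <- integer(0)
  for (d in .HB_DONORS) {
    sel <- which(a$name == d[2L] &
                   (d[1L] == "*" | a$resname == d[1L]))
    if (d[2L] == "N") sel <- sel[a$resname[sel] != "PRO"]
    for (i in sel) {
      j <- which(rkey == rkey[i] & a$name == d[3L])
      if (length(j)) {
        don_idx <- c(don_idx, i)
        ant_idx <- c(ant_idx, j[1L])
      }
    }
  }
  acc_idx <- which(a$element %in% c("N", "O"))
  bonds <- list()
  for (k in seq_along(don_idx)) {
    i <- don_idx[k]
    dvec <- xyz[acc_idx, , drop = FALSE] -
      matrix(xyz[i, ], length(acc_idx), 3, byrow = TRUE)
    dist <- sqrt(rowSums(dvec^2))
    near <- which(dist <= dist_cutoff & rkey[acc_idx] != rkey[i])
    for (q in near) {
      j <- acc_idx[q]
      v1 <- xyz[ant_idx[k], ] - xyz[i, ]
      v2 <- xyz[j, ] - xyz[i, ]
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                 (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
      if (ang >= angle_cutoff) {
        bonds[[length(bonds) + 1L]] <-
          data.frame(donor = .atom_label(a, i), acceptor = .atom_label(a, j),
                     distance = dist[q], angle = ang,
                     stringsAsFactors = FALSE)
      }
    }
  }
  bonds <- if (length(bonds)) do.call(rbind, bonds)
  else data.frame(donor = character(0), acceptor = character(0),
                  distance = numeric(0), angle = numeric(0))
  list(count = nrow(bonds), bonds = bonds)
}

#' Salt bridges by side-chain charge-group distance
#'
#' Any basic nitrogen (Lys NZ; Arg NE/NH1/NH2; His ND1/NE2) within
#' `cutoff` of any acidic carboxylate oxygen (Asp OD1/OD2; Glu
#' OE1/OE2) forms a bridge; multiple atom pairs between one residue
#' pair count once, at the minimum distance.
#'
#' @param model A `structure_model`.
#' @param cutoff Distance cutoff (Angstrom, default 4.0).
#' @return A list: `count` and `bridges` (data frame `basic`, `acidic`,
#'   `distance`).
#' @export
salt_bridges <- function(model, cutoff = 4.0) {
  a <- model$atoms
  xyz <- .coords(model)
  basic <- which((a$resname == "LYS" & a$name == "NZ") |
                   (a$resname == "ARG" & a$name %in% c("NE", "NH1", "NH2")) |
                   (a$resname == "HIS" & a$name %in% c("ND1", "NE2")))
  acidic <- which((a$resname == "ASP" & a$name %in% c("OD1", "OD2")) |
                    (a$resname == "GLU" & a$name %in% c("OE1", "OE2")))
  if (!length(basic) || !length(acidic))
    return(list(count = 0L,
                bridges = data.frame(basic = character(0),
                                     acidic = character(0),
                                     distance = numeric(0))))
  rkey <- paste(a$chain, a$resno, a$insert)
  best <- list()
  for (i in basic) {
    dvec <- xyz[acidic, , drop = FALSE] -
      matrix(xyz[i, ], length(acidic), 3, byrow = TRUE)
    dist <- sqrt(rowSums(dvec^2))
    for (q in which(dist <= cutoff)) {
      j <- acidic[q]
      key <- paste(rkey[i], rkey[j], sep = "::")
      if (is.null(best[[key]]) || dist[q] < best[[key]]$distance) {
        best[[key]] <- data.frame(
          basic = paste(a$resname[i], a$resno[i], a$chain[i]),
          acidic = paste(a$resname[j], a$resno[j], a$chain[j]),
          distance = dist[q], stringsAsFactors = FALSE)
      }
    }
  }
  bridges <- if (length(best)) do.call(rbind, c(best, make.row.names = FALSE))
  else data.frame(basic = character(0), acidic = character(0),
                  distance = numeric(0))
  list(count = nrow(bridges), bridges = bridges)
}

# quasi-uniform points on the unit sphere (golden-section spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent accessible surface area (Shrake-Rupley)
#'
#' Samples `n_points` quasi-uniform points on each atom's solvent-
#' expanded sphere (van der Waals radius + probe) and counts the
#' fraction not buried inside any neighbouring atom's expanded sphere.
#'
#' @param model A `structure_model`.
#' @param probe_radius Solvent probe radius (Angstrom, default 1.4).
#' @param n_points Sample points per atom (default 960).
#' @return A list: `total` (Angstrom^2) and `per_atom` (vector).
#' @export
accessible_surface_area <- function(model, probe_radius = 1.4,
                                    n_points = 960) {
  xyz <- .coords(model)
  n <- nrow(xyz)
  r <- .vdw_radius(model$atoms$element) + probe_radius
  # coincident atoms (degenerate input) would bury each other's test
  # points; count the surface once, on the first of each set
  dup <- duplicated(round(xyz, 6))
  sp <- .sphere_points(n_points)
  per_atom <- numeric(n)
  max_r <- max(r)
  for (i in which(!dup)) {
    d2 <- rowSums((xyz - matrix(xyz[i, ], n, 3, byrow = TRUE))^2)
    nb <- which(d2 < (r[i] + max_r)^2 & seq_len(n) != i & !dup)
    nb <- nb[d2[nb] < (r[i] + r[nb])^2 & d2[nb] > 1e-12]
    pts <- sp * r[i] + matrix(xyz[i, ], n_points, 3, byrow = TRUE)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj <- (pts[, 1L] - xyz[j, 1L])^2 + (pts[, 2L] - xyz[j, 2L])^2 +
        (pts[, 3L] - xyz[j, 3L])^2
      exposed <- exposed & dj > r[j]^2
    }
    per_atom[i] <- 4 * pi * r[i]^2 * mean(exposed)
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

#' Solvent-inaccessible cavity volumes by grid flood fill
#'
#' Fills the padded bounding box with a cubic grid; voxels within
#' (van der Waals + probe) of any atom are occupied. Free voxels
#' 6-connected to the box boundary are bulk solvent; the remaining
#' free voxels are solvent-inaccessible cavities, reported per
#' connected component as voxel count x spacing^3, largest first.
#'
#' @param model A `structure_model`.
#' @param grid_spacing Voxel edge (Angstrom, default 0.7); must not
#'   exceed the probe radius.
#' @param probe_radius Probe radius (Angstrom, default 1.4).
#' @return Numeric vector of cavity volumes (Angstrom^3), possibly
#'   empty.
#' @export
cavity_volumes <- function(model, grid_spacing = 0.7, probe_radius = 1.4) {
  if (grid_spacing > probe_radius)
    .stop2("grid spacing (", grid_spacing,
           ") must not exceed the probe radius (", probe_radius, ")")
  xyz <- .coords(model)
  r <- .vdw_radius(model$atoms$element) + probe_radius
  pad <- max(r) + 2 * grid_spacing
  gx <- seq(min(xyz[, 1L]) - pad, max(xyz[, 1L]) + pad, by = grid_spacing)
  gy <- seq(min(xyz[, 2L]) - pad, max(xyz[, 2L]) + pad, by = grid_spacing)
  gz <- seq(min(xyz[, 3L]) - pad, max(xyz[, 3L]) + pad, by = grid_spacing)
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  occ <- array(FALSE, c(nx, ny, nz))
  for (i in seq_len(nrow(xyz))) {
    ix <- which(abs(gx - xyz[i, 1L]) <= r[i])
    iy <- which(abs(gy - xyz[i, 2L]) <= r[i])
    iz <- which(abs(gz - xyz[i, 3L]) <= r[i])
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - xyz[i, 1L])^2
    dy2 <- (gy[iy] - xyz[i, 2L])^2
    dz2 <- (gz[iz] - xyz[i, 3L])^2
    sub <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r[i]^2
    occ[ix, iy, iz] <- occ[ix, iy, iz] | sub
  }
  free <- as.logical(occ) == FALSE     # linearised
  # label free voxels by connected component (6-connectivity) with a
  # preallocated stack flood fill on linear indices
  nxy <- nx * ny
  n_tot <- nx * ny * nz
  lab <- integer(n_tot)
  stack <- integer(n_tot)
  comp <- 0L
  comp_size <- integer(0)
  comp_touches <- logical(0)
  for (start in which(free)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    sp_top <- 1L
    stack[1L] <- start
    lab[start] <- comp
    size <- 0L
    touches <- FALSE
    while (sp_top > 0L) {
      v <- stack[sp_top]
      sp_top <- sp_top - 1L
      size <- size + 1L
      iz <- (v - 1L) %/% nxy
      rem <- (v - 1L) %% nxy
      iy <- rem %/% nx
      ix <- rem %% nx
      if (ix == 0L || ix == nx - 1L || iy == 0L || iy == ny - 1L ||
          iz == 0L || iz == nz - 1L) touches <- TRUE
      if (ix > 0L)      { w <- v - 1L;   if (free[w] && lab[w] == 0L) { lab[w] <- comp; sp_top <- sp_top + 1L; stack[sp_top] <- w } }
      if (ix < nx - 1L) { w <- v + 1L;   if (free[w] && lab[w] == 0L) { lab[w] <- comp; sp_top <- sp_top + 1L; stack[sp_top] <- w } }
      if (iy > 0L)      { w <- v - nx;   if (free[w] && lab[w] == 0L) { lab[w] <- comp; sp_top <- sp_top + 1L; stack[sp_top] <- w } }
      if (iy < ny - 1L) { w <- v + nx;   if (free[w] && lab[w] == 0L) { lab[w] <- comp; sp_top <- sp_top + 1L; stack[sp_top] <- w } }
      if (iz > 0L)      { w <- v - nxy;  if (free[w] && lab[w] == 0L) { lab[w] <- comp; sp_top <- sp_top + 1L; stack[sp_top] <- w } }
      if (iz < nz - 1L) { w <- v + nxy;  if (free[w] && lab[w] == 0L) { lab[w] <- comp; sp_top <- sp_top + 1L; stack[sp_top] <- w } }
    }
    comp_size <- c(comp_size, size)
    comp_touches <- c(comp_touches, touches)
  }
  vols <- comp_size[!comp_touches] * grid_spacing^3
  sort(vols, decreasing = TRUE)
}

#' Optimal superposition RMSD (Kabsch)
#'
#' Pairs atoms of the chosen selection by chain, residue number,
#' insertion code and atom name; residues whose names disagree between
#' the two models are excluded and flagged. The optimal least-squares
#' rigid transform is found in closed form (SVD of the covariance of
#' the centred coordinate sets) and the RMSD evaluated over the paired
#' selection.
#'
#' @param model_a,model_b `structure_model` objects.
#' @param selection `"CA"` (default) or `"backbone"` (N, CA, C, O).
#' @param residues Optional integer vector restricting the comparison
#'   to these residue numbers.
#' @return A `superposition_result` list: `rmsd` (Angstrom),
#'   `n_atoms_used`, `rotation` (3x3), `translation` (length 3; maps
#'   centred b onto a as `a ~ b %*% t(rotation) + translation`),
#'   `selection`, `mismatched_residues`.
#' @export
backbone_rmsd <- function(model_a, model_b, selection = c("CA", "backbone"),
                          residues = NULL) {
  selection <- match.arg(selection)
  names_sel <- if (selection == "CA") "CA" else c("N", "CA", "C", "O")
  pick <- function(m) {
    a <- m$atoms
    a <- a[a$name %in% names_sel & a$resname %in% names(.AA3), ]
    if (!is.null(residues)) a <- a[a$resno %in% residues, ]
    a$key <- paste(a$chain, a$resno, a$insert, a$name, sep = "|")
    a[!duplicated(a$key), ]
  }
  aa <- pick(model_a)
  bb <- pick(model_b)
  shared <- intersect(aa$key, bb$key)
  ia <- match(shared, aa$key)
  ib <- match(shared, bb$key)
  # exclude pairs whose residue identity differs; flag them
  mism <- aa$resname[ia] != bb$resname[ib]
  mismatched <- unique(paste(aa$chain[ia][mism], aa$resno[ia][mism]))
  ia <- ia[!mism]; ib <- ib[!mism]
  if (length(ia) < 3L) .stop2("fewer than 3 paired atoms for superposition")
  A <- as.matrix(aa[ia, c("x", "y", "z")])
  B <- as.matrix(bb[ib, c("x", "y", "z")])
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- crossprod(B0, A0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Bfit <- B0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((A0 - Bfit)^2)))
  structure(list(rmsd = rmsd, n_atoms_used = length(ia),
                 rotation = R, translation = ca - drop(cb %*% t(R)),
                 selection = selection,
                 mismatched_residues = mismatched),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("Superposition: RMSD = %.3f A over %d %s atoms\n",
              x$rmsd, x$n_atoms_used,
              if (x$selection == "CA") "CA" else "backbone"))
  invisible(x)
}

#' Full interaction report for one structure
#'
#' Convenience wrapper returning hydrogen bonds, salt bridges, total
#' ASA and cavity volumes in one list, suitable for side-by-side
#' serpin comparisons.
#'
#' @param model A `structure_model`.
#' @param probe_radius Probe radius for ASA and cavities (default 1.4).
#' @param grid_spacing Cavity grid spacing (default 0.7).
#' @return An `interaction_report` list: `hydrogen_bonds`,
#'   `salt_bridges`, `total_asa`, `cavity_volumes`.
#' @export
interaction_report <- function(model, probe_radius = 1.4,
                               grid_spacing = 0.7) {
  hb <- hydrogen_bonds(model)
  sb <- salt_bridges(model)
  asa <- accessible_surface_area(model, probe_radius)
  cav <- cavity_volumes(model, grid_spacing, probe_radius)
  structure(list(hydrogen_bonds = hb, salt_bridges = sb,
                 total_asa = asa$total, cavity_volumes = cav),
            class = "interaction_report")
}

#' @export
print.interaction_report <- function(x, ...) {
  cat("Interaction report: ", x$hydrogen_bonds$count, " H-bonds, ",
      x$salt_bridges$count, " salt bridges, ASA ",
      round(x$total_asa), " A^2, ",
      length(x$cavity_volumes), " cavity(ies)\n", sep = "")
  invisible(x)
}
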