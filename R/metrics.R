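# Internal vectorised geometry helpers --------------------------------------

.row_norm <- function(m) sqrt(rowSums(m^2))

# angle at vertex b (degrees) for point triples
.angle_deg <- function(a, b, cc) {
  u <- a - b; v <- cc - b
  cosang <- rowSums(u * v) / (.row_norm(u) * .row_norm(v))
  cosang <- pmin(1, pmax(-1, cosang))
  acos(cosang) * 180 / pi
}

# torsion angle (degrees, IUPAC sign) for rows of four points
.torsion_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cbind(b1[, 2] * b2[, 3] - b1[, 3] * b2[, 2],
              b1[, 3] * b2[, 1] - b1[, 1] * b2[, 3],
              b1[, 1] * b2[, 2] - b1[, 2] * b2[, 1])
  n2 <- cbind(b2[, 2] * b3[, 3] - b2[, 3] * b3[, 2],
              b2[, 3] * b3[, 1] - b2[, 1] * b3[, 3],
              b2[, 1] * b3[, 2] - b2[, 2] * b3[, 1])
  m1 <- cbind(n1[, 2] * b2[, 3] - n1[, 3] * b2[, 2],
              n1[, 3] * b2[, 1] - n1[, 1] * b2[, 3],
              n1[, 1] * b2[, 2] - n1[, 2] * b2[, 1]) / .row_norm(b2)
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  # half-open range (-180, 180]
  ang[!is.na(ang) & ang <= -180] <- 180
  ang
}

# Hydrogen bonds -------------------------------------------------------------

#' Geometric hydrogen-bond criterion
#'
#' A hydrogen bond exists when the hydrogen-acceptor distance is below
#' `max_ha_distance` and the donor-H-acceptor angle exceeds `min_dha_angle`.
#'
#' @param max_ha_distance Maximum H..acceptor distance in nm (default 0.25).
#' @param min_dha_angle Minimum donor-H-acceptor angle in degrees
#'   (default 120).
#' @return A list of class `hbond_criterion`.
#' @export
hbond_criterion <- function(max_ha_distance = 0.25, min_dha_angle = 120) {
  stopifnot(max_ha_distance > 0, min_dha_angle > 0, min_dha_angle < 180)
  structure(list(max_ha_distance = max_ha_distance,
                 min_dha_angle = min_dha_angle),
            class = "hbond_criterion")
}

# residue-level backbone donor/acceptor geometry for one coordinate set
.bb_hbond_geometry <- function(conf, xyz = NULL) {
  if (!is.null(xyz)) conf$xyz <- xyz
  bb <- .backbone_table(conf)
  h <- amide_h_positions(conf)
  list(N = bb$N, H = h, O = bb$O, C = bb$C, n = bb$n,
       resno = bb$resno, resid = bb$resid)
}

#' Detect backbone hydrogen bonds in a conformation
#'
#' Donors are backbone amide N-H groups (hydrogens are taken from the file or
#' constructed, see [amide_h_positions()]); acceptors are backbone carbonyl
#' oxygens. Bonds within a residue or with the directly bonded preceding
#' residue (the peptide-bond partner) are excluded as covalent contacts.
#'
#' @param conf A `conformation`.
#' @param crit An [hbond_criterion()].
#' @param donors,acceptors Optional 0-based residue-index selections
#'   restricting the donor/acceptor search (default: all residues).
#' @return A list with `bonds` (data.frame `donor_res`, `acceptor_res`
#'   0-based residue indices, `dist_nm`, `angle_deg`) and `count`.
#' @export
hydrogen_bonds <- function(conf, crit = hbond_criterion(),
                           donors = NULL, acceptors = NULL) {
  g <- .bb_hbond_geometry(conf)
  don <- which(!is.na(g$H[, 1]) & !is.na(g$N[, 1]))
  acc <- which(!is.na(g$O[, 1]))
  if (!is.null(donors)) don <- intersect(don, donors + 1L)
  if (!is.null(acceptors)) acc <- intersect(acc, acceptors + 1L)
  if (!length(don) || !length(acc)) {
    return(list(bonds = data.frame(donor_res = integer(),
                                   acceptor_res = integer(),
                                   dist_nm = numeric(), angle_deg = numeric()),
                count = 0L))
  }
  pairs <- expand.grid(d = don, a = acc)
  pairs <- pairs[pairs$d != pairs$a & pairs$d != pairs$a + 1L, , drop = FALSE]
  H <- g$H[pairs$d, , drop = FALSE]
  A <- g$O[pairs$a, , drop = FALSE]
  D <- g$N[pairs$d, , drop = FALSE]
  dist <- .row_norm(H - A)
  ang <- .angle_deg(D, H, A)
  hit <- dist < crit$max_ha_distance & ang > crit$min_dha_angle
  bonds <- data.frame(donor_res = pairs$d[hit] - 1L,
                      acceptor_res = pairs$a[hit] - 1L,
                      dist_nm = dist[hit], angle_deg = ang[hit])
  bonds <- bonds[order(bonds$donor_res, bonds$acceptor_res), , drop = FALSE]
  rownames(bonds) <- NULL
  list(bonds = bonds, count = nrow(bonds))
}

#' Retention of native backbone hydrogen bonds along an ensemble
#'
#' The native set is the list of backbone hydrogen bonds detected in the
#' experimental reference conformation; each frame is scored by how many of
#' those native donor-acceptor pairs still satisfy the geometric criterion.
#'
#' @param ens An `ensemble` sharing the reference topology.
#' @param reference A `conformation` (the experimental structure).
#' @param crit An [hbond_criterion()].
#' @return List with `native` (reference bond table), `per_frame` (integer
#'   counts) and `mean`.
#' @export
native_hbond_count <- function(ens, reference, crit = hbond_criterion()) {
  stopifnot(inherits(ens, "ensemble"), inherits(reference, "conformation"))
  if (!identical(ens$topology$atoms$name, reference$atoms$name) ||
      !identical(ens$topology$atoms$residue_index, reference$atoms$residue_index)) {
    stop("ensemble topology does not match the reference structure")
  }
  native <- hydrogen_bonds(reference, crit)$bonds
  if (nrow(native) == 0L) {
    return(list(native = native,
                per_frame = rep(0L, length(ens$frames)), mean = 0))
  }
  d_i <- native$donor_res + 1L
  a_i <- native$acceptor_res + 1L
  per_frame <- vapply(ens$frames, function(fr) {
    g <- .bb_hbond_geometry(ens$topology, xyz = fr)
    H <- g$H[d_i, , drop = FALSE]
    A <- g$O[a_i, , drop = FALSE]
    D <- g$N[d_i, , drop = FALSE]
    ok <- !is.na(H[, 1]) & !is.na(A[, 1])
    dist <- .row_norm(H - A)
    ang <- .angle_deg(D, H, A)
    sum(ok & dist < crit$max_ha_distance & ang > crit$min_dha_angle,
        na.rm = TRUE)
  }, integer(1))
  list(native = native, per_frame = per_frame, mean = mean(per_frame))
}

# SASA ------------------------------------------------------------------------

#' Configuration for solvent-accessible surface area
#'
#' Rolled-probe SASA is computed with the Shrake-Rupley sphere-point method.
#' The probe radius follows the SPC water convention (0.14 nm). Atom radii
#' are looked up by element; the shipped defaults are standard van der Waals
#' radii and can be overridden wholesale, e.g. with radii derived from the
#' Lennard-Jones minima of a specific force field.
#'
#' @param probe_radius Probe radius in nm (default 0.14).
#' @param atom_radii Named numeric vector, nm per element.
#' @param n_sphere_points Number of test points per atom (>= 32, default 960).
#' @return A list of class `sasa_config`.
#' @export
sasa_config <- function(probe_radius = 0.14,
                        atom_radii = c(H = 0.120, C = 0.172, N = 0.155,
                                       O = 0.152, S = 0.180, P = 0.180,
                                       SE = 0.190),
                        n_sphere_points = 960L) {
  stopifnot(probe_radius >= 0, all(atom_radii > 0), n_sphere_points >= 32L)
  structure(list(probe_radius = probe_radius, atom_radii = atom_radii,
                 n_sphere_points = as.integer(n_sphere_points)),
            class = "sasa_config")
}

# deterministic quasi-uniform points on the unit sphere (golden spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' @param conf A `conformation`.
#' @param cfg A [sasa_config()].
#' @param polarity_mapping Passed to [residue_polarity()] for nonstandard
#'   residues when splitting totals.
#' @return List of class `sasa`: `per_atom` (nm^2), `total`, `polar`,
#'   `nonpolar` (totals split by the polarity of the owning residue).
#' @export
sasa <- function(conf, cfg = sasa_config(), polarity_mapping = NULL) {
  elem <- toupper(conf$atoms$element)
  r <- cfg$atom_radii[elem]
  if (any(is.na(r))) {
    stop("no SASA radius configured for atom type(s): ",
         paste(unique(elem[is.na(r)]), collapse = ", "))
  }
  r <- unname(r)
  p <- cfg$probe_radius
  xyz <- conf$xyz
  n <- nrow(xyz)
  pts <- .sphere_points(cfg$n_sphere_points)
  ext <- r + p
  per_atom <- numeric(n)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    neigh <- which(d2[i, ] < (ext[i] + ext)^2 & seq_len(n) != i)
    sp <- pts * ext[i]
    sp <- sweep(sp, 2, xyz[i, ], "+")
    acc <- rep(TRUE, nrow(sp))
    for (j in neigh) {
      if (!any(acc)) break
      dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 > ext[j]^2
    }
    per_atom[i] <- mean(acc) * 4 * pi * ext[i]^2
  }
  pol <- residue_polarity(conf$atoms$resid, mapping = polarity_mapping)
  structure(list(per_atom = per_atom,
                 total = sum(per_atom),
                 polar = sum(per_atom[pol == "polar"]),
                 nonpolar = sum(per_atom[pol == "nonpolar"])),
            class = "sasa")
}

# Size and shape metrics -------------------------------------------------------

#' Mass-weighted radius of gyration
#'
#' \eqn{R_{gyr} = \sqrt{\sum_i m_i |r_i - r_{com}|^2 / M}} with the
#' mass-weighted centre of mass \eqn{r_{com}}.
#'
#' @param conf A `conformation`.
#' @return Radius of gyration in nm.
#' @export
radius_of_gyration <- function(conf) {
  m <- conf$atoms$mass
  M <- sum(m)
  if (M <= 0) stop("total mass must be positive")
  com <- colSums(conf$xyz * m) / M
  d2 <- rowSums(sweep(conf$xyz, 2, com)^2)
  sqrt(sum(m * d2) / M)
}

#' Positional RMSD after least-squares superposition
#'
#' Performs an optimal rigid-body fit of `conf` onto `reference` over the
#' given atom selection (conventionally the backbone heavy atoms excluding
#' the first and last residue, see [select_backbone()]) and returns the RMSD
#' over the same selection.
#'
#' @param conf,reference `conformation`s with identical atom ordering.
#' @param selection Integer atom indices used for fitting and scoring.
#' @return RMSD in nm.
#' @export
fit_rmsd <- function(conf, reference,
                     selection = select_backbone(reference)) {
  if (length(selection) < 3L) stop("need at least 3 atoms to fit")
  a <- conf$xyz[selection, , drop = FALSE]
  b <- reference$xyz[selection, , drop = FALSE]
  # collinearity guard: rank of the centred reference must exceed 1
  s <- svd(sweep(b, 2, colMeans(b)))$d
  if (s[2] < 1e-8 * max(s[1], 1e-12)) {
    stop("selection is collinear; superposition is ill-defined")
  }
  ci <- seq_len(3L * nrow(b))
  fitted <- bio3d::fit.xyz(fixed = as.vector(t(b)), mobile = as.vector(t(a)),
                           fixed.inds = ci, mobile.inds = ci)
  sqrt(mean((fitted - as.vector(t(b)))^2) * 3)
}

#' Size-normalised RMSD (RMSD100)
#'
#' Carugo-Pongor normalisation of a positional RMSD to the value expected for
#' a 100-residue protein: \eqn{RMSD / (1 + \ln\sqrt{N/100})}. The
#' normalisation is not validated for small proteins, so values for chains of
#' 40 residues or fewer are returned unchanged.
#'
#' @param rmsd RMSD in nm (>= 0).
#' @param n_residues Number of residues (>= 1).
#' @return Normalised RMSD in nm.
#' @examples
#' rmsd100(0.2, 100)  # unchanged
#' rmsd100(0.2, 200)  # shrunk
#' @export
rmsd100 <- function(rmsd, n_residues) {
  stopifnot(all(rmsd >= 0), all(n_residues >= 1))
  ifelse(n_residues <= 40, rmsd, rmsd / (1 + log(sqrt(n_residues / 100))))
}

# Dihedral angles ---------------------------------------------------------------

#' Backbone phi/psi dihedral angles
#'
#' phi(i) is the torsion C(i-1)-N(i)-CA(i)-C(i); psi(i) is
#' N(i)-CA(i)-C(i)-N(i+1). Angles are reported in degrees in (-180, 180];
#' terminal residues (and residues with missing flanking atoms) yield `NA`.
#'
#' @param conf A `conformation`.
#' @return `data.frame` with `residue_index`, `resno`, `resid`, `phi`, `psi`.
#' @export
backbone_dihedrals <- function(conf) {
  bb <- .backbone_table(conf)
  n <- bb$n
  na_row <- matrix(NA_real_, 1, 3)
  prevC <- rbind(na_row, bb$C[-n, , drop = FALSE])
  nextN <- rbind(bb$N[-1, , drop = FALSE], na_row)
  phi <- .torsion_deg(prevC, bb$N, bb$CA, bb$C)
  psi <- .torsion_deg(bb$N, bb$CA, bb$C, nextN)
  data.frame(residue_index = seq_len(n) - 1L, resno = bb$resno,
             resid = bb$resid, phi = phi, psi = psi,
             stringsAsFactors = FALSE)
}

#' Pool backbone dihedrals over ensembles
#'
#' @param ensembles A list of `ensemble` objects (or a single one).
#' @return `data.frame` with `resid`, `phi`, `psi`, one row per residue per
#'   frame (NA torsions dropped).
#' @export
pool_dihedrals <- function(ensembles) {
  if (inherits(ensembles, "ensemble")) ensembles <- list(ensembles)
  out <- lapply(ensembles, function(ens) {
    conf <- ens$topology
    do.call(rbind, lapply(ens$frames, function(fr) {
      conf$xyz <- fr
      d <- backbone_dihedrals(conf)
      d[, c("resid", "phi", "psi")]
    }))
  })
  out <- do.call(rbind, out)
  out[!is.na(out$phi) | !is.na(out$psi), , drop = FALSE]
}

#' Normalised dihedral-angle histograms
#'
#' Builds 1D phi and psi histograms (default bin 5 degrees) and a 2D
#' Ramachandran density (default bin 0.5 degrees) from pooled backbone
#' dihedrals; optionally one set per residue type. All densities are
#' normalised to sum to 1.
#'
#' @param dihedrals `data.frame` as returned by [pool_dihedrals()].
#' @param bin_1d,bin_2d Bin widths in degrees; must divide 360 evenly.
#' @param by_residue If `TRUE`, return per-residue-type histogram sets.
#' @return List with `phi`, `psi` (named density vectors over bin centres)
#'   and `ramachandran` (density matrix, phi rows x psi columns); with
#'   `by_residue = TRUE`, a named list of such lists.
#' @export
dihedral_histograms <- function(dihedrals, bin_1d = 5, bin_2d = 0.5,
                                by_residue = FALSE) {
  for (b in c(bin_1d, bin_2d)) {
    if (abs(360 / b - round(360 / b)) > 1e-9) {
      stop("bin size ", b, " does not divide 360 evenly")
    }
  }
  hist1 <- function(x, bin) {
    breaks <- seq(-180, 180, by = bin)
    x <- x[!is.na(x)]
    cnt <- table(cut(x, breaks, include.lowest = TRUE))
    dens <- as.numeric(cnt)
    if (sum(dens) > 0) dens <- dens / sum(dens)
    stats::setNames(dens, sprintf("%g", breaks[-1] - bin / 2))
  }
  build <- function(d) {
    breaks <- seq(-180, 180, by = bin_2d)
    ok <- !is.na(d$phi) & !is.na(d$psi)
    m <- table(cut(d$phi[ok], breaks, include.lowest = TRUE),
               cut(d$psi[ok], breaks, include.lowest = TRUE))
    m <- unclass(m)
    if (sum(m) > 0) m <- m / sum(m)
    list(phi = hist1(d$phi, bin_1d), psi = hist1(d$psi, bin_1d),
         ramachandran = m)
  }
  if (by_residue) {
    lapply(split(dihedrals, dihedrals$resid), build)
  } else {
    build(dihedrals)
  }
}

# Deviation scoring -----------------------------------------------------------

#' Percentage deviation from the experimental reference value
#'
#' \eqn{\Delta q\% = 100 (q_{sim} - q_{ref}) / q_{ref}}, where `sim_mean` is
#' the average of the quantity over the analysis window of one replicate and
#' `ref_value` its value in the experimental structure.
#'
#' @param sim_mean Simulation average of the quantity.
#' @param ref_value Reference value (nonzero).
#' @return Percent deviation (signed).
#' @export
delta_q_percent <- function(sim_mean, ref_value) {
  if (any(ref_value == 0)) {
    stop("percentage deviation is undefined for a zero reference value")
  }
  100 * (sim_mean - ref_value) / ref_value
}
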