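# Back-calculation of NMR observables from conformational ensembles.

#' Karplus parameters for 3J coupling back-calculation
#'
#' \eqn{J(\theta) = A\cos^2\theta + B\cos\theta + C} with
#' \eqn{\theta = \phi + \mathrm{phase\_offset}}. For the backbone
#' \eqn{^3J(H_N\!-\!H_\alpha)} coupling with phi defined over the heavy atoms
#' C-N-CA-C, the phase offset is -60 degrees. The shipped default
#' coefficients are the widely used Pardi set (A = 6.4, B = -1.4, C = 1.9
#' Hz); alternative empirical calibrations can be supplied, as different
#' studies fit A, B, C against different reference data.
#'
#' @param A,B,C Karplus coefficients in Hz.
#' @param phase_offset Offset added to phi to obtain theta, degrees.
#' @return List of class `karplus_params`.
#' @export
karplus_params <- function(A = 6.4, B = -1.4, C = 1.9, phase_offset = -60) {
  stopifnot(is.finite(A), is.finite(B), is.finite(C), is.finite(phase_offset))
  structure(list(A = A, B = B, C = C, phase_offset = phase_offset),
            class = "karplus_params")
}

#' Karplus relation
#'
#' @param phi Backbone phi dihedral(s), degrees.
#' @param params A [karplus_params()].
#' @return Coupling constant(s) in Hz.
#' @examples
#' karplus_j(150)   # theta = 90 degrees: J = C
#' @export
karplus_j <- function(phi, params = karplus_params()) {
  theta <- (phi + params$phase_offset) * pi / 180
  params$A * cos(theta)^2 + params$B * cos(theta) + params$C
}

#' RMSD between back-calculated and experimental 3J couplings
#'
#' For each experimental residue, the coupling is back-calculated from the
#' frame phi dihedral via the Karplus relation and averaged over all pooled
#' frames (frames of all replicates weighted equally); the result is the
#' root-mean-square deviation of these averages from the experimental values.
#'
#' @param ensembles A list of `ensemble` objects (or one `ensemble`) sharing
#'   a topology.
#' @param experimental `data.frame` with columns `resno` (author residue
#'   number) and `j_exp` (Hz).
#' @param params A [karplus_params()].
#' @return List: `rmsd_hz`, `per_residue` (data.frame `resno`, `j_calc`,
#'   `j_exp`).
#' @export
j_rmsd <- function(ensembles, experimental, params = karplus_params()) {
  if (inherits(ensembles, "ensemble")) ensembles <- list(ensembles)
  stopifnot(all(c("resno", "j_exp") %in% names(experimental)))
  conf <- ensembles[[1L]]$topology
  # per-frame phi per residue, J per frame, then mean over pooled frames
  j_sum <- NULL; n_frames <- 0L
  for (ens in ensembles) {
    for (fr in ens$frames) {
      conf$xyz <- fr
      d <- backbone_dihedrals(conf)
      j <- karplus_j(d$phi, params)
      if (is.null(j_sum)) j_sum <- stats::setNames(rep(0, nrow(d)), d$resno)
      j_sum <- j_sum + j
      n_frames <- n_frames + 1L
    }
  }
  d0 <- backbone_dihedrals(conf)
  j_mean <- j_sum / n_frames
  idx <- match(experimental$resno, d0$resno)
  j_calc <- j_mean[idx]
  drop <- is.na(idx) | is.na(j_calc)
  if (any(drop)) {
    warning("residue(s) without a defined phi excluded from J-coupling RMSD: ",
            paste(experimental$resno[drop], collapse = ", "))
  }
  per <- data.frame(resno = experimental$resno[!drop],
                    j_calc = unname(j_calc[!drop]),
                    j_exp = experimental$j_exp[!drop])
  list(rmsd_hz = sqrt(mean((per$j_calc - per$j_exp)^2)), per_residue = per)
}

#' NOE-style ensemble-averaged distance
#'
#' \eqn{\langle r^{-3} \rangle^{-1/3}} averaging of an interproton distance
#' series over pooled frames, the convention for comparing short simulations
#' to NOE-derived upper distance bounds.
#'
#' @param distances_per_frame Numeric vector of distances in nm (> 0).
#' @return Averaged distance in nm (never exceeds the arithmetic mean).
#' @examples
#' noe_average_distance(c(0.2, 0.4))  # 0.2423 nm
#' @export
noe_average_distance <- function(distances_per_frame) {
  if (any(!is.finite(distances_per_frame)) || any(distances_per_frame <= 0)) {
    stop("distances must be positive and finite")
  }
  mean(distances_per_frame^-3)^(-1 / 3)
}

#' NOE restraint list
#'
#' Reads a plain tab-separated restraint table: columns `resno1`, `atom1`,
#' `resno2`, `atom2`, `upper_nm` and optionally `lower_nm`,
#' `prior_correction_nm` (a bound correction already included in `upper_nm`,
#' to be removed before applying pseudoatom corrections) and `ambiguous`
#' (flag for restraints with doubtful assignments).
#'
#' @param path Path to the TSV file.
#' @return `data.frame` of class `noe_restraints`.
#' @export
read_restraints <- function(path) {
  r <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  needed <- c("resno1", "atom1", "resno2", "atom2", "upper_nm")
  missing_cols <- setdiff(needed, names(r))
  if (length(missing_cols)) {
    stop("restraint table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(r$lower_nm)) r$lower_nm <- NA_real_
  if (is.null(r$prior_correction_nm)) r$prior_correction_nm <- 0
  if (is.null(r$ambiguous)) r$ambiguous <- FALSE
  noe_restraints(r)
}

#' @rdname read_restraints
#' @param x A data.frame with the restraint columns.
#' @export
noe_restraints <- function(x) {
  if (any(x$upper_nm <= 0)) stop("upper bounds must be positive")
  if (any(!is.na(x$lower_nm) & x$lower_nm >= x$upper_nm)) {
    stop("lower bounds must be below the corresponding upper bounds")
  }
  class(x) <- c("noe_restraints", "data.frame")
  x
}

#' Standard pseudoatom bound corrections
#'
#' Distance-bound corrections (nm) added when an ambiguously assigned proton
#' group is replaced by a single pseudoatom at its geometric centre:
#' methylene and methyl groups, aromatic ring CH pairs, and isopropyl
#' double-methyl groups. Values are the literature-standard magnitudes and
#' can be overridden.
#'
#' @return Named numeric vector of corrections in nm.
#' @export
pseudoatom_corrections <- function() {
  c(methylene = 0.10, methyl = 0.10, aromatic = 0.20, isopropyl = 0.24)
}

# classify a pseudoatom name (Q*/M* convention) for a residue type
.pseudo_class <- function(atom, resid) {
  if (grepl("^QQ", atom)) return("isopropyl")
  if (grepl("^M", atom)) return("methyl")
  if (resid %in% c("PHE", "TYR") && atom %in% c("QD", "QE", "QR")) {
    return("aromatic")
  }
  if (grepl("^Q", atom)) {
    # QB on ALA is a methyl, elsewhere Q<x> is typically a methylene;
    # branched-chain terminal groups (QG1/QG2, QD1/QD2 on ILE/LEU/VAL/THR)
    # are methyls
    if (resid == "ALA" && atom == "QB") return("methyl")
    if (resid %in% c("ILE", "LEU", "VAL", "THR") &&
        grepl("^Q[GD][12]$", atom)) {
      return("methyl")
    }
    return("methylene")
  }
  NA_character_
}

# resolve an atom spec to member atom indices (possibly several for a
# pseudoatom); united-atom topologies fall back to the carrier heavy atom
.resolve_atom <- function(conf, resno, atom, restraint_label = "") {
  a <- conf$atoms
  in_res <- which(a$resno == resno)
  if (!length(in_res)) {
    stop("restraint ", restraint_label, ": residue ", resno,
         " not found in topology")
  }
  direct <- in_res[a$name[in_res] == atom]
  if (length(direct)) return(direct)
  if (grepl("^[QM]", atom)) {
    stem <- sub("^(QQ|Q|M)", "", atom)
    members <- in_res[grepl(paste0("^[0-9]?H", stem), a$name[in_res])]
    if (length(members)) return(members)
    carrier <- in_res[a$name[in_res] %in% paste0(c("C", "N"), stem)]
    if (length(carrier)) return(carrier)
  }
  stop("restraint ", restraint_label, ": cannot resolve atom '", atom,
       "' in residue ", resno, " (", a$resid[in_res[1L]], ")")
}

#' Apply pseudoatom bound corrections to NOE restraints
#'
#' Restraints whose atoms are pseudoatoms (Q/M naming convention) get their
#' upper bound adjusted: any prior correction recorded in
#' `prior_correction_nm` is first removed, then the pseudoatom correction for
#' the group class is added. The pseudoatom position used later in distance
#' evaluation is the geometric centre of the member protons (or the carrier
#' heavy atom in united-atom topologies).
#'
#' @param restraints A `noe_restraints` table.
#' @param topology A `conformation` used to resolve atom specs.
#' @param corrections Named corrections in nm, see [pseudoatom_corrections()].
#' @return The corrected `noe_restraints` table (columns
#'   `pseudoatom_correction_nm` and updated `upper_nm`).
#' @export
apply_pseudoatom_correction <- function(restraints, topology,
                                        corrections = pseudoatom_corrections()) {
  res <- restraints
  res$pseudoatom_correction_nm <- 0
  a <- topology$atoms
  for (k in seq_len(nrow(res))) {
    corr <- 0
    for (side in 1:2) {
      atom <- res[[paste0("atom", side)]][k]
      resno <- res[[paste0("resno", side)]][k]
      # validate resolvability early so errors name the restraint
      .resolve_atom(topology, resno, atom, restraint_label = k)
      resid <- a$resid[which(a$resno == resno)[1L]]
      cls <- .pseudo_class(atom, resid)
      if (!is.na(cls)) corr <- corr + corrections[[cls]]
    }
    res$pseudoatom_correction_nm[k] <- corr
    res$upper_nm[k] <- res$upper_nm[k] - res$prior_correction_nm[k] + corr
  }
  res$prior_correction_nm <- 0
  res
}

#' NOE distance violations over pooled replicates
#'
#' For every restraint, the interatomic (or pseudoatom-centre) distance is
#' evaluated in each frame of the pooled replicates, averaged as
#' \eqn{\langle r^{-3}\rangle^{-1/3}}, and compared to the upper bound. The
#' average violation divides the summed violations by the total number of
#' restraints (satisfied restraints count zero but stay in the denominator).
#'
#' @param ensembles A list of `ensemble`s (or one `ensemble`); replicates are
#'   pooled with equal frame weights.
#' @param restraints A `noe_restraints` table.
#' @return List: `per_restraint` (data.frame with `avg_dist_nm`,
#'   `upper_nm`, `violation_nm`), `average_violation_nm`.
#' @export
noe_violations <- function(ensembles, restraints) {
  if (inherits(ensembles, "ensemble")) ensembles <- list(ensembles)
  topo <- ensembles[[1L]]$topology
  m1 <- lapply(seq_len(nrow(restraints)), function(k) {
    .resolve_atom(topo, restraints$resno1[k], restraints$atom1[k], k)
  })
  m2 <- lapply(seq_len(nrow(restraints)), function(k) {
    .resolve_atom(topo, restraints$resno2[k], restraints$atom2[k], k)
  })
  frames <- do.call(c, lapply(ensembles, `[[`, "frames"))
  avg <- vapply(seq_len(nrow(restraints)), function(k) {
    d <- vapply(frames, function(fr) {
      p1 <- colMeans(fr[m1[[k]], , drop = FALSE])
      p2 <- colMeans(fr[m2[[k]], , drop = FALSE])
      sqrt(sum((p1 - p2)^2))
    }, numeric(1))
    noe_average_distance(d)
  }, numeric(1))
  viol <- pmax(0, avg - restraints$upper_nm)
  per <- data.frame(resno1 = restraints$resno1, atom1 = restraints$atom1,
                    resno2 = restraints$resno2, atom2 = restraints$atom2,
                    avg_dist_nm = avg, upper_nm = restraints$upper_nm,
                    violation_nm = viol)
  list(per_restraint = per,
       average_violation_nm = sum(viol) / nrow(restraints))
}
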