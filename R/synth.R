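# Synthetic-data generators: every generator is a pure function of its
# arguments including the seed (the global RNG state is restored on exit).

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate a long-format metric table with nested variability
#'
#' Emulates the three-level variance structure of a replicated multi-protein
#' force-field study: a fixed parameter-set offset per metric, a Gaussian
#' protein random effect, a Gaussian replicate-within-protein random effect,
#' and Gaussian residual noise:
#' \eqn{y = \mathrm{offset}(set, metric) + b_{protein} + b_{replicate} +
#' \epsilon}. Protein and replicate effects are shared across parameter sets,
#' matching the nesting assumed by the mixed models. A lognormal option
#' exponentiates the linear predictor to exercise the Box-Cox path.
#'
#' @param n_proteins,n_replicates Design size (defaults 40 proteins, 3
#'   replicates, the size of the fully covered benchmark design).
#' @param parameter_sets Parameter-set names, oldest first.
#' @param metrics Metric names.
#' @param ff_offsets Matrix of fixed effects (`parameter_sets` rows x
#'   `metrics` columns), a named vector recycled across metrics, or a single
#'   number for all cells. Default 0.
#' @param sd_protein,sd_replicate,sd_residual Standard deviations of the
#'   random components (scalars or per-metric named vectors).
#' @param missing_pattern Optional list `list(proteins =, keep_sets =)`
#'   dropping all but `keep_sets` for the named proteins (unbalanced
#'   designs).
#' @param family `"gaussian"` (default) or `"lognormal"`.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A `metric_table`.
#' @export
gen_metric_table <- function(n_proteins = 40L, n_replicates = 3L,
                             parameter_sets = parameter_set_order(),
                             metrics = "metric1",
                             ff_offsets = 0,
                             sd_protein = 2, sd_replicate = 0.5,
                             sd_residual = 0.3,
                             missing_pattern = NULL,
                             family = c("gaussian", "lognormal"),
                             seed = 1L) {
  family <- match.arg(family)
  stopifnot(n_proteins >= 1L, n_replicates >= 1L,
            all(c(sd_protein, sd_replicate, sd_residual) >= 0))
  ns <- length(parameter_sets); nm <- length(metrics)
  off <- matrix(0, ns, nm, dimnames = list(parameter_sets, metrics))
  if (is.matrix(ff_offsets)) {
    off[rownames(ff_offsets), colnames(ff_offsets)] <- ff_offsets
  } else if (!is.null(names(ff_offsets))) {
    off[names(ff_offsets), ] <- ff_offsets
  } else {
    off[] <- ff_offsets
  }
  per_metric <- function(x) {
    if (!is.null(names(x))) x[metrics] else rep(x, length.out = nm)
  }
  sd_p <- per_metric(sd_protein); sd_r <- per_metric(sd_replicate)
  sd_e <- per_metric(sd_residual)

  proteins <- sprintf("P%02d", seq_len(n_proteins))
  .with_seed(seed, {
    b_prot <- matrix(stats::rnorm(n_proteins * nm), n_proteins, nm) *
      rep(sd_p, each = n_proteins)
    b_rep <- array(stats::rnorm(n_proteins * n_replicates * nm),
                   c(n_proteins, n_replicates, nm)) *
      rep(sd_r, each = n_proteins * n_replicates)
    grid <- expand.grid(parameter_set = parameter_sets, protein = proteins,
                        replicate = seq_len(n_replicates), metric = metrics,
                        stringsAsFactors = FALSE)
    ip <- match(grid$protein, proteins)
    im <- match(grid$metric, metrics)
    is_ <- match(grid$parameter_set, parameter_sets)
    eps <- stats::rnorm(nrow(grid)) * sd_e[im]
    y <- off[cbind(is_, im)] + b_prot[cbind(ip, im)] +
      b_rep[cbind(ip, grid$replicate, im)] + eps
    if (family == "lognormal") y <- exp(y)
    d <- metric_table(grid$parameter_set, grid$protein, grid$replicate,
                      grid$metric, y)
    if (!is.null(missing_pattern)) {
      drop <- d$protein %in% missing_pattern$proteins &
        !(d$parameter_set %in% missing_pattern$keep_sets)
      d <- d[!drop, , drop = FALSE]
      class(d) <- c("metric_table", "data.frame")
    }
    rownames(d) <- NULL
    d
  })
}

# NeRF-style internal-coordinate atom placement: position d with |c-d| =
# bond, angle(b,c,d) = angle_deg and torsion(a,b,c,d) = torsion_deg
.place_atom <- function(a, b, cc, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  bc <- cc - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d_local <- bond * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  cc + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

# build a poly-alanine backbone from per-residue (phi, psi) with trans
# peptide bonds; standard bond lengths (nm) and angles (degrees)
.build_backbone <- function(phi, psi, include_h = TRUE) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 2L)
  bN_CA <- 0.1458; bCA_C <- 0.1525; bC_N <- 0.1329; bC_O <- 0.1231
  aN_CA_C <- 111.2; aCA_C_N <- 116.2; aC_N_CA <- 121.7; aCA_C_O <- 120.8
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(bN_CA, 0, 0)
  C[1, ] <- .place_atom(c(0, -1, 0), N[1, ], CA[1, ], bCA_C, aN_CA_C, 120)
  for (i in 2:n) {
    N[i, ] <- .place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], bC_N,
                          aCA_C_N, psi[i - 1])
    CA[i, ] <- .place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], bN_CA,
                           aC_N_CA, 180)
    C[i, ] <- .place_atom(C[i - 1, ], N[i, ], CA[i, ], bCA_C, aN_CA_C,
                          phi[i])
    O[i - 1, ] <- .place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], bC_O,
                              aCA_C_O, psi[i - 1] + 180)
  }
  O[n, ] <- .place_atom(N[n, ], CA[n, ], C[n, ], bC_O, aCA_C_O, psi[n] + 180)

  names_per <- c("N", "CA", "C", "O")
  elem_per <- c("N", "C", "C", "O")
  rows <- list(); xyz <- list()
  for (i in seq_len(n)) {
    nm <- names_per; el <- elem_per
    co <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    if (include_h && i > 1L) {
      u <- C[i - 1, ] - O[i - 1, ]
      u <- u / sqrt(sum(u^2))
      nm <- c(nm, "H"); el <- c(el, "H")
      co <- rbind(co, N[i, ] + 0.1 * u)
    }
    rows[[i]] <- data.frame(name = nm, resid = "ALA", chain = "A",
                            resno = i, residue_index = i - 1L, element = el,
                            stringsAsFactors = FALSE)
    xyz[[i]] <- co
  }
  atoms <- do.call(rbind, rows)
  atoms$mass <- .element_mass(atoms$element)
  conformation(atoms, do.call(rbind, xyz))
}

#' Ideal poly-alanine secondary-structure fixtures
#'
#' `build_ideal_helix()` places `n_residues` alanines at canonical
#' alpha-helical torsions (phi = -57, psi = -47), producing the i -> i+4
#' amide hydrogen-bond ladder; `build_ideal_hairpin()` builds two
#' antiparallel strands joined by a two-residue turn. Amide hydrogens are
#' included so the hydrogen-bond and secondary-structure operators can run
#' without reconstruction.
#'
#' @param n_residues Number of residues (>= 4; hairpins need >= 8).
#' @param phi,psi Backbone torsions in degrees (helix only).
#' @param include_h Include amide hydrogens (default `TRUE`).
#' @return A `conformation`.
#' @export
build_ideal_helix <- function(n_residues, phi = -57, psi = -47,
                              include_h = TRUE) {
  stopifnot(n_residues >= 4L)
  .build_backbone(rep(phi, n_residues), rep(psi, n_residues),
                  include_h = include_h)
}

#' @rdname build_ideal_helix
#' @export
build_ideal_hairpin <- function(n_residues, include_h = TRUE) {
  stopifnot(n_residues >= 8L)
  ns <- (n_residues - 2L) %/% 2L         # residues per strand
  n2 <- n_residues - 2L - ns
  phi_s <- -139; psi_s <- 135            # antiparallel beta
  phi <- c(rep(phi_s, ns), 57, 78, rep(phi_s, n2))   # type I' turn
  psi <- c(rep(psi_s, ns), 47, 6, rep(psi_s, n2))
  .build_backbone(phi, psi, include_h = include_h)
}

#' Simulate a jittered conformational ensemble
#'
#' Adds i.i.d. Gaussian displacement (`jitter_sd` per coordinate) to every
#' atom of the base conformation in every frame: a minimal stand-in for
#' thermal fluctuation around a reference structure.
#'
#' @param base A `conformation`.
#' @param jitter_sd Per-coordinate displacement SD in nm (>= 0).
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer seed.
#' @param include_base Make frame 1 the unperturbed base structure.
#' @param replicate_id Replicate label for the resulting ensemble.
#' @return An `ensemble`.
#' @export
gen_ensemble <- function(base, jitter_sd, n_frames, seed = 1L,
                         include_base = FALSE, replicate_id = 1L) {
  stopifnot(inherits(base, "conformation"), jitter_sd >= 0, n_frames >= 1L)
  na <- nrow(base$xyz)
  .with_seed(seed, {
    frames <- lapply(seq_len(n_frames), function(i) {
      if (include_base && i == 1L) return(base$xyz)
      base$xyz + matrix(stats::rnorm(na * 3, sd = jitter_sd), na, 3)
    })
    read_ensemble(base, frames, replicate_id = replicate_id)
  })
}

#' Generate an NOE restraint set satisfied by a base structure
#'
#' Samples random proton pairs (hydrogens on different residues) and sets
#' each upper bound to the base-structure distance plus `slack`, so that a
#' nonnegative slack guarantees zero violations on the base conformation.
#'
#' @param base A `conformation` containing hydrogen atoms.
#' @param n_restraints Number of restraints (at most the number of available
#'   proton pairs).
#' @param slack Bound slack in nm (may be negative to force violations).
#' @param seed Integer seed.
#' @return A `noe_restraints` table.
#' @export
gen_noe_set <- function(base, n_restraints, slack = 0.1, seed = 1L) {
  h <- which(base$atoms$element == "H")
  if (length(h) < 2L) stop("base structure contains fewer than two protons")
  pairs <- utils::combn(h, 2L)
  keep <- base$atoms$residue_index[pairs[1L, ]] !=
    base$atoms$residue_index[pairs[2L, ]]
  pairs <- pairs[, keep, drop = FALSE]
  if (n_restraints > ncol(pairs)) {
    stop("requested ", n_restraints, " restraints but only ", ncol(pairs),
         " distinct-residue proton pairs exist")
  }
  .with_seed(seed, {
    sel <- pairs[, sample.int(ncol(pairs), n_restraints), drop = FALSE]
    d <- .row_norm(base$xyz[sel[1L, ], , drop = FALSE] -
                     base$xyz[sel[2L, ], , drop = FALSE])
    noe_restraints(data.frame(
      resno1 = base$atoms$resno[sel[1L, ]],
      atom1 = base$atoms$name[sel[1L, ]],
      resno2 = base$atoms$resno[sel[2L, ]],
      atom2 = base$atoms$name[sel[2L, ]],
      upper_nm = d + slack,
      lower_nm = NA_real_,
      prior_correction_nm = 0,
      ambiguous = FALSE,
      stringsAsFactors = FALSE
    ))
  })
}
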