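#' Conformation objects
#'
#' A conformation is the package's in-memory representation of one set of
#' atomic coordinates: an atom table plus an `n x 3` coordinate matrix in
#' nanometres. All internal geometry uses nm, atomic masses in amu and angles
#' in degrees; PDB ingestion converts from Angstroms.
#'
#' @param atoms `data.frame` with columns `name`, `resid` (3-letter residue
#'   code), `chain`, `resno` (author residue numbering), `residue_index`
#'   (0-based internal index, nondecreasing), `element`, `mass` (amu).
#' @param xyz Numeric matrix, one row per atom, columns x/y/z in nm.
#' @param source_model Model number the coordinates came from (PDB `MODEL`).
#' @return An object of class `conformation`.
#' @export
conformation <- function(atoms, xyz, source_model = 1L) {
  stopifnot(is.data.frame(atoms), is.matrix(xyz), ncol(xyz) == 3,
            nrow(atoms) == nrow(xyz))
  needed <- c("name", "resid", "chain", "resno", "residue_index", "element", "mass")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols)) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("conformation must contain at least one atom")
  if (any(!is.finite(xyz))) stop("coordinates must be finite")
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0)) {
    stop("atom masses must be positive")
  }
  if (is.unsorted(atoms$residue_index)) {
    stop("residue_index must be nondecreasing")
  }
  structure(list(atoms = atoms, xyz = unname(xyz),
                 source_model = as.integer(source_model)),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("<conformation> %d atoms, %d residues (model %d)\n",
              nrow(x$atoms), n_residues(x), x$source_model))
  invisible(x)
}

#' Number of residues in a conformation
#' @param conf A `conformation`.
#' @return Integer count.
#' @export
n_residues <- function(conf) length(unique(conf$atoms$residue_index))

# Standard atomic masses (amu)
.element_masses <- stats::setNames(
  c(1.008, 12.011, 14.007, 15.999, 32.06, 30.974, 78.971, 55.845,
    65.38, 24.305, 40.078, 22.990, 35.45, 39.098, 54.938, 63.546),
  c("H", "C", "N", "O", "S", "P", "SE", "FE",
    "ZN", "MG", "CA", "NA", "CL", "K", "MN", "CU"))

.standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

.guess_element <- function(name) {
  nm <- toupper(gsub("[0-9' ]", "", name))
  two <- substr(nm, 1, 2)
  ifelse(two %in% c("FE", "ZN", "MG", "CL", "SE", "MN", "CU", "BR"),
         two, substr(nm, 1, 1))
}

.element_mass <- function(element) {
  m <- .element_masses[match(toupper(element), names(.element_masses))]
  unname(m)
}

#' Read a protein structure from a PDB file
#'
#' Only the first `MODEL` is retained. Alternate locations are resolved to the
#' highest-occupancy conformer (ties broken by the lexicographically first
#' altloc identifier). Analysis is restricted to the first protein chain;
#' waters and other heteroatoms are kept in a separate `het` table, not in the
#' protein topology. Coordinates are converted from Angstroms to nm.
#'
#' @param source Path to a PDB file.
#' @return A `conformation` with an additional `het` element (data.frame of
#'   excluded HETATM/water records with coordinates in nm).
#' @export
read_structure <- function(source) {
  # multi = FALSE keeps only the first MODEL; rm.alt = FALSE retains all
  # altloc records so the occupancy rule below can resolve them
  pdb <- bio3d::read.pdb(source, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0L || !any(at$type == "ATOM")) {
    stop("no ATOM records found in '", source, "'")
  }
  coords <- cbind(at$x, at$y, at$z)

  prot <- at$type == "ATOM"
  het <- data.frame(name = at$elety[!prot], resid = at$resid[!prot],
                    chain = at$chain[!prot], resno = at$resno[!prot],
                    stringsAsFactors = FALSE)
  if (nrow(het)) het <- cbind(het, setNames(as.data.frame(coords[!prot, , drop = FALSE] / 10), c("x", "y", "z")))

  keep <- which(prot)
  chain1 <- at$chain[keep[1L]]
  keep <- keep[at$chain[keep] %in% chain1 | is.na(at$chain[keep])]

  # resolve altlocs: highest occupancy, ties to first altloc id
  alt <- at$alt[keep]
  occ <- at$o[keep]
  occ[is.na(occ)] <- 1
  has_alt <- !is.na(alt) & nzchar(alt) & alt != " "
  if (any(has_alt)) {
    key <- paste(at$chain[keep], at$resno[keep], at$insert[keep], at$elety[keep])
    drop <- logical(length(keep))
    for (k in unique(key[has_alt])) {
      idx <- which(key == k)
      if (length(idx) > 1L) {
        ord <- order(-occ[idx], alt[idx])
        drop[idx[-ord[1L]]] <- TRUE
      }
    }
    keep <- keep[!drop]
  }

  resid <- at$resid[keep]
  unknown <- setdiff(unique(resid), .standard_aa)
  if (length(unknown)) {
    warning("unknown residue name(s) ", paste(unknown, collapse = ", "),
            "; classified generically")
  }

  elem <- at$elesy[keep]
  bad_e <- is.na(elem) | !nzchar(trimws(elem))
  elem[bad_e] <- .guess_element(at$elety[keep][bad_e])
  elem <- trimws(elem)
  mass <- .element_mass(elem)
  if (any(is.na(mass))) {
    warning("unrecognised element(s) ",
            paste(unique(elem[is.na(mass)]), collapse = ", "),
            "; assigned carbon mass")
    mass[is.na(mass)] <- .element_masses[["C"]]
  }

  rk <- paste(at$chain[keep], at$resno[keep], at$insert[keep])
  ridx <- as.integer(factor(rk, levels = unique(rk))) - 1L
  atoms <- data.frame(name = trimws(at$elety[keep]), resid = resid,
                      chain = at$chain[keep], resno = at$resno[keep],
                      residue_index = ridx, element = elem, mass = mass,
                      stringsAsFactors = FALSE)
  conf <- conformation(atoms, coords[keep, , drop = FALSE] / 10, source_model = 1L)
  conf$het <- het
  conf
}

#' Write a conformation to a PDB file
#'
#' Coordinates are converted back from nm to Angstroms. Together with
#' [read_structure()] this round-trips names, residues and coordinates to
#' better than 0.001 nm (PDB precision).
#'
#' @param conf A `conformation`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_structure <- function(conf, file) {
  a <- conf$atoms
  bio3d::write.pdb(file = file,
                   xyz = as.vector(t(conf$xyz * 10)),
                   resno = a$resno, resid = a$resid,
                   chain = ifelse(is.na(a$chain), "A", a$chain),
                   elety = a$name, eleno = seq_len(nrow(a)),
                   elesy = a$element)
  invisible(file)
}

#' Read a GROMACS .gro coordinate file
#'
#' Minimal fixed-column reader for single-frame `.gro` files (positions are
#' already in nm). Velocities, if present, are ignored.
#'
#' @param source Path to a `.gro` file.
#' @return A `conformation`.
#' @export
read_gro <- function(source) {
  lines <- readLines(source)
  if (length(lines) < 3L) stop("not a valid .gro file: '", source, "'")
  natoms <- as.integer(trimws(lines[2L]))
  if (is.na(natoms) || length(lines) < 2L + natoms) {
    stop("atom count in '", source, "' does not match file length")
  }
  rows <- lines[3:(2 + natoms)]
  resno <- as.integer(substr(rows, 1, 5))
  resid <- trimws(substr(rows, 6, 10))
  name <- trimws(substr(rows, 11, 15))
  x <- as.numeric(substr(rows, 21, 28))
  y <- as.numeric(substr(rows, 29, 36))
  z <- as.numeric(substr(rows, 37, 44))
  elem <- .guess_element(name)
  mass <- .element_mass(elem)
  mass[is.na(mass)] <- .element_masses[["C"]]
  ridx <- as.integer(factor(resno, levels = unique(resno))) - 1L
  atoms <- data.frame(name = name, resid = resid, chain = "A", resno = resno,
                      residue_index = ridx, element = elem, mass = mass,
                      stringsAsFactors = FALSE)
  conformation(atoms, cbind(x, y, z))
}

#' Assemble an ensemble of conformations
#'
#' Collects trajectory frames that share the topology of `topology` into an
#' ensemble, optionally restricted to the final `last_ns` nanoseconds of the
#' run (production analyses conventionally use the last 5 ns, with frames
#' written every picosecond).
#'
#' @param topology A `conformation` defining the atom ordering.
#' @param trajectory One of: a list of `n_atoms x 3` coordinate matrices in
#'   nm; a path to a multi-model PDB file; or a path to a DCD trajectory
#'   (coordinates in Angstroms, converted on read).
#' @param last_ns Keep only frames within the final `last_ns` ns. Requires
#'   frame times; if times are unknown all frames are kept with a warning.
#' @param frame_times_ps Optional numeric vector of frame times in ps. For
#'   file-based trajectories without time information, supply it here.
#' @param replicate_id Integer label of the replicate this ensemble came from.
#' @return An object of class `ensemble`: list with `topology`, `frames`
#'   (list of coordinate matrices, nm), `frame_times_ps`, `replicate_id`.
#' @export
read_ensemble <- function(topology, trajectory, last_ns = NULL,
                          frame_times_ps = NULL, replicate_id = 1L) {
  stopifnot(inherits(topology, "conformation"))
  na <- nrow(topology$atoms)

  if (is.character(trajectory) && length(trajectory) == 1L) {
    if (grepl("\\.dcd$", trajectory, ignore.case = TRUE)) {
      m <- bio3d::read.dcd(trajectory, verbose = FALSE)
      frames <- lapply(seq_len(nrow(m)), function(i) {
        matrix(m[i, ], ncol = 3, byrow = TRUE) / 10
      })
    } else {
      pdb <- bio3d::read.pdb(trajectory, multi = TRUE, verbose = FALSE)
      xyz <- pdb$xyz
      if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
      keep <- pdb$atom$type == "ATOM"
      frames <- lapply(seq_len(nrow(xyz)), function(i) {
        matrix(xyz[i, ], ncol = 3, byrow = TRUE)[keep, , drop = FALSE] / 10
      })
    }
  } else if (is.list(trajectory)) {
    frames <- lapply(trajectory, function(f) {
      stopifnot(is.matrix(f), ncol(f) == 3)
      unname(f)
    })
  } else {
    stop("trajectory must be a file path or a list of coordinate matrices")
  }

  bad <- which(vapply(frames, nrow, integer(1)) != na)
  if (length(bad)) {
    stop("trajectory frame ", bad[1L], " has ",
         nrow(frames[[bad[1L]]]), " atoms but the topology has ", na)
  }

  if (!is.null(frame_times_ps) && length(frame_times_ps) != length(frames)) {
    stop("frame_times_ps must have one entry per frame")
  }

  if (!is.null(last_ns)) {
    if (is.null(frame_times_ps)) {
      warning("frame times unknown; keeping all frames")
    } else {
      span_ps <- max(frame_times_ps) - min(frame_times_ps)
      if (last_ns * 1000 > span_ps) {
        warning("requested window exceeds trajectory span; keeping all frames")
      } else {
        keep <- frame_times_ps > max(frame_times_ps) - last_ns * 1000
        frames <- frames[keep]
        frame_times_ps <- frame_times_ps[keep]
      }
    }
  }

  structure(list(topology = topology, frames = frames,
                 frame_times_ps = frame_times_ps,
                 replicate_id = as.integer(replicate_id)),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d frames x %d atoms (replicate %d)\n",
              length(x$frames), nrow(x$topology$atoms), x$replicate_id))
  invisible(x)
}

#' Select backbone heavy atoms
#'
#' Returns the atom indices of the backbone heavy atoms (N, CA, C and, by
#' default, O). The least-squares superposition convention used for
#' positional RMSD excludes the first and last residue of the chain.
#'
#' @param conf A `conformation`.
#' @param exclude_termini Drop the first and last residue (default `TRUE`).
#' @param include_o Include the carbonyl O (default `TRUE`).
#' @return Integer vector of atom indices.
#' @export
select_backbone <- function(conf, exclude_termini = TRUE, include_o = TRUE) {
  wanted <- c("N", "CA", "C", if (include_o) "O")
  a <- conf$atoms
  res <- sort(unique(a$residue_index))
  if (exclude_termini) {
    if (length(res) < 3L) {
      stop("terminal exclusion needs at least 3 residues, got ", length(res))
    }
    res <- res[-c(1L, length(res))]
  }
  sel <- which(a$residue_index %in% res & a$name %in% wanted)
  # warn if some residue is missing one of the wanted atoms
  found <- table(factor(a$residue_index[sel], levels = res))
  if (any(found < length(wanted))) {
    short <- names(found)[found < length(wanted)]
    warning("residue(s) ", paste(short, collapse = ", "),
            " lack one or more backbone atoms; returning the atoms present")
  }
  sel
}

#' Polar/nonpolar residue classification
#'
#' Partition of the 20 standard amino acids used to split the
#' solvent-accessible surface area: arginine, aspartate, asparagine,
#' glutamate, glutamine, glycine, histidine, lysine, serine, threonine and
#' proline are polar; alanine, cysteine, isoleucine, leucine, methionine,
#' phenylalanine, tryptophan, tyrosine and valine are nonpolar.
#'
#' @param residue_name Character vector of 3-letter residue codes.
#' @param mapping Optional named character vector overriding or extending the
#'   default classification (values `"polar"`/`"nonpolar"`).
#' @return Character vector of `"polar"`/`"nonpolar"`.
#' @examples
#' residue_polarity(c("ARG", "ALA"))
#' @export
residue_polarity <- function(residue_name, mapping = NULL) {
  polar <- c("ARG", "ASP", "ASN", "GLU", "GLN", "GLY", "HIS", "LYS",
             "SER", "THR", "PRO")
  nonpolar <- c("ALA", "CYS", "ILE", "LEU", "MET", "PHE", "TRP", "TYR", "VAL")
  tab <- c(setNames(rep("polar", length(polar)), polar),
           setNames(rep("nonpolar", length(nonpolar)), nonpolar))
  if (!is.null(mapping)) tab[names(mapping)] <- mapping
  code <- toupper(residue_name)
  out <- tab[code]
  if (any(is.na(out))) {
    stop("no polarity classification for residue(s): ",
         paste(unique(code[is.na(out)]), collapse = ", "),
         " (supply a 'mapping' to classify nonstandard residues)")
  }
  unname(out)
}

# Backbone atom coordinates per residue: matrices N, CA, C, O (NA where absent)
.backbone_table <- function(conf) {
  a <- conf$atoms
  res <- sort(unique(a$residue_index))
  nr <- length(res)
  out <- list()
  for (nm in c("N", "CA", "C", "O", "H")) {
    m <- matrix(NA_real_, nr, 3)
    idx <- which(a$name == nm | (nm == "H" & a$name %in% c("HN", "H1")))
    if (length(idx)) {
      r <- match(a$residue_index[idx], res)
      first <- !duplicated(r)
      m[r[first], ] <- conf$xyz[idx[first], , drop = FALSE]
    }
    out[[nm]] <- m
  }
  out$resid <- a$resid[match(res, a$residue_index)]
  out$resno <- a$resno[match(res, a$residue_index)]
  out$n <- nr
  out
}

#' Amide hydrogen positions
#'
#' Returns one H position per residue, taken from the file when an explicit
#' amide hydrogen (`H`/`HN`) is present and otherwise constructed 0.1 nm from
#' N, anti-parallel to the preceding residue's carbonyl C=O bond (the
#' Kabsch-Sander convention). The chain's first residue and prolines have no
#' amide hydrogen and yield `NA` rows.
#'
#' @param conf A `conformation`.
#' @return `n_residues x 3` matrix of positions in nm (rows of `NA` where no
#'   amide H exists).
#' @export
amide_h_positions <- function(conf) {
  bb <- .backbone_table(conf)
  h <- bb$H
  build <- which(is.na(h[, 1]))
  for (i in build) {
    if (i == 1L || bb$resid[i] == "PRO") next
    C <- bb$C[i - 1L, ]; O <- bb$O[i - 1L, ]; N <- bb$N[i, ]
    if (any(is.na(C)) || any(is.na(O)) || any(is.na(N))) next
    u <- C - O
    u <- u / sqrt(sum(u^2))
    h[i, ] <- N + 0.1 * u
  }
  h[bb$resid == "PRO", ] <- NA_real_
  h
}
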