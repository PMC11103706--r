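# Shared fixtures and independent oracles used across the test files.

# minimal conformation from bare coordinates
mkconf <- function(xyz, name = NULL, resid = "ALA", element = "C",
                   residue_index = NULL, mass = NULL) {
  n <- nrow(xyz)
  if (is.null(name)) name <- paste0("X", seq_len(n))
  if (is.null(residue_index)) residue_index <- seq_len(n) - 1L
  element <- rep_len(element, n)
  if (is.null(mass)) {
    mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
              S = 32.06)[element]
    mass[is.na(mass)] <- 12
  }
  atoms <- data.frame(name = rep_len(name, n), resid = rep_len(resid, n),
                      chain = "A", resno = residue_index + 1L,
                      residue_index = residue_index, element = element,
                      mass = unname(rep_len(mass, n)),
                      stringsAsFactors = FALSE)
  conformation(atoms, xyz)
}

# rigid motion: rotate about z by theta (radians) and translate
rigid_move <- function(xyz, theta = 0.9, shift = c(1, -2, 0.5)) {
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  sweep(xyz %*% t(R), 2, shift, "+")
}

# hand-rolled PDB writer with full control over models/altlocs/HETATM
pdb_line <- function(record, serial, name, alt, resid, chain, resno,
                     x, y, z, occ = 1, elem = substr(name, 1, 1)) {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          alt, resid, chain, resno, x, y, z, occ, 0, elem)
}

write_two_model_pdb <- function(path) {
  lines <- c(
    "MODEL        1",
    pdb_line("ATOM", 1, "N",  " ", "ALA", "A", 1, 0.0, 0.0, 0.0, elem = "N"),
    pdb_line("ATOM", 2, "CA", " ", "ALA", "A", 1, 1.0, 2.0, 3.0),
    pdb_line("ATOM", 3, "C",  " ", "ALA", "A", 1, 2.4, 0.2, 0.0),
    pdb_line("ATOM", 4, "O",  " ", "ALA", "A", 1, 3.1, 1.2, 0.1, elem = "O"),
    pdb_line("ATOM", 5, "CB", "A", "ALA", "A", 1, 1.0, -1.4, 0.3, occ = 0.6),
    pdb_line("ATOM", 6, "CB", "B", "ALA", "A", 1, 1.1, -1.5, 0.4, occ = 0.4),
    pdb_line("HETATM", 7, "O", " ", "HOH", "A", 2, 5.0, 5.0, 5.0, elem = "O"),
    "ENDMDL",
    "MODEL        2",
    pdb_line("ATOM", 1, "N",  " ", "ALA", "A", 1, 9.0, 9.0, 9.0, elem = "N"),
    pdb_line("ATOM", 2, "CA", " ", "ALA", "A", 1, 9.0, 9.0, 8.0),
    pdb_line("ATOM", 3, "C",  " ", "ALA", "A", 1, 9.0, 8.0, 9.0),
    pdb_line("ATOM", 4, "O",  " ", "ALA", "A", 1, 8.0, 9.0, 9.0, elem = "O"),
    pdb_line("ATOM", 5, "CB", "A", "ALA", "A", 1, 7.0, 9.0, 9.0, occ = 0.6),
    pdb_line("ATOM", 6, "CB", "B", "ALA", "A", 1, 7.0, 9.0, 8.0, occ = 0.4),
    "ENDMDL",
    "END")
  writeLines(lines, path)
  path
}

# O(n^2) brute-force backbone hydrogen-bond scan, written independently of
# the package implementation (explicit loops, no shared helpers)
brute_force_hbonds <- function(conf, max_d = 0.25, min_ang = 120) {
  a <- conf$atoms
  res <- sort(unique(a$residue_index))
  get1 <- function(ri, nm) {
    i <- which(a$residue_index == ri & a$name == nm)[1]
    if (is.na(i)) NULL else conf$xyz[i, ]
  }
  h_of <- function(ri) {
    h <- get1(ri, "H")
    if (!is.null(h)) return(h)
    if (ri == min(res) || a$resid[a$residue_index == ri][1] == "PRO") return(NULL)
    Cp <- get1(ri - 1L, "C"); Op <- get1(ri - 1L, "O"); N <- get1(ri, "N")
    if (is.null(Cp) || is.null(Op) || is.null(N)) return(NULL)
    u <- (Cp - Op) / sqrt(sum((Cp - Op)^2))
    N + 0.1 * u
  }
  out <- NULL
  for (di in res) {
    H <- h_of(di); D <- get1(di, "N")
    if (is.null(H) || is.null(D)) next
    for (ai in res) {
      if (ai == di || ai == di - 1L) next
      A <- get1(ai, "O")
      if (is.null(A)) next
      dHA <- sqrt(sum((H - A)^2))
      v1 <- D - H; v2 <- A - H
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (dHA < max_d && ang > min_ang) {
        out <- rbind(out, c(donor = di, acceptor = ai))
      }
    }
  }
  out
}

# dense-grid numerical SASA oracle: latitude/longitude quadrature per atom
grid_sasa_oracle <- function(xyz, radii, probe, n_lat = 180L) {
  total <- 0
  ext <- radii + probe
  for (i in seq_len(nrow(xyz))) {
    R <- ext[i]
    lat <- (seq_len(n_lat) - 0.5) / n_lat * pi   # polar angle
    area_i <- 0
    for (k in seq_len(n_lat)) {
      n_lon <- max(1L, round(2 * n_lat * sin(lat[k])))
      lon <- (seq_len(n_lon) - 0.5) / n_lon * 2 * pi
      pts <- cbind(R * sin(lat[k]) * cos(lon),
                   R * sin(lat[k]) * sin(lon),
                   rep(R * cos(lat[k]), n_lon))
      pts <- sweep(pts, 2, xyz[i, ], "+")
      patch <- R^2 * sin(lat[k]) * (pi / n_lat) * (2 * pi / n_lon)
      free <- rep(TRUE, n_lon)
      for (j in seq_len(nrow(xyz))) {
        if (j == i) next
        d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
          (pts[, 3] - xyz[j, 3])^2
        free <- free & d2 > ext[j]^2
      }
      area_i <- area_i + sum(free) * patch
    }
    total <- total + area_i
  }
  total
}

# multivariate normal log-density via Cholesky (closed-form likelihood oracle)
mvn_logdens <- function(x, S) {
  L <- chol(S)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(L))) +
            sum(backsolve(L, x, transpose = TRUE)^2))
}

# rotation-search RMSD oracle: coarse Euler-angle grid plus local polish,
# independent of the SVD-based superposition
rotation_search_rmsd <- function(a, b) {
  ca <- sweep(a, 2, colMeans(a)); cb <- sweep(b, 2, colMeans(b))
  rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((ca %*% t(rot(ang)) - cb)^2)))
  grid <- seq(-pi, pi, length.out = 13)
  best <- c(0, 0, 0); best_v <- obj(best)
  for (a1 in grid) for (a2 in grid) for (a3 in grid) {
    v <- obj(c(a1, a2, a3))
    if (v < best_v) { best <- c(a1, a2, a3); best_v <- v }
  }
  stats::optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))$value
}
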