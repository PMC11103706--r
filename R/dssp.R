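# Kabsch-Sander secondary-structure assignment.
#
# The electrostatic hydrogen-bond model places partial charges on the C=O
# (+0.42e/-0.42e) and N-H (-0.20e/+0.20e) groups and accepts a bond when
#   E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)  <  -0.5 kcal/mol
# (r in Angstroms). Patterns of these bonds define turns, helices and
# bridges; ladders of consecutive bridges (including beta bulges) form
# strands. Priority of assignment: H > E/B > G > I > T > S.

.KS_COUPLING <- 0.084 * 332  # kcal/mol * Angstrom

# boolean donor x acceptor matrix: HB[d, a] == NH(d) donates to CO(a)
.ks_hbond_matrix <- function(bb, h, cutoff = -0.5) {
  n <- bb$n
  HB <- matrix(FALSE, n, n)
  donors <- which(!is.na(h[, 1]) & !is.na(bb$N[, 1]))
  acceptors <- which(!is.na(bb$O[, 1]) & !is.na(bb$C[, 1]))
  if (!length(donors) || !length(acceptors)) return(HB)
  for (d in donors) {
    a <- acceptors[abs(acceptors - d) >= 3L]
    # CA proximity prefilter (9 Angstrom = 0.9 nm) as in the reference method
    if (!is.na(bb$CA[d, 1])) {
      ca_ok <- !is.na(bb$CA[a, 1]) &
        .row_norm(sweep(bb$CA[a, , drop = FALSE], 2, bb$CA[d, ])) < 0.9
      a <- a[ca_ok]
    }
    if (!length(a)) next
    rON <- .row_norm(sweep(bb$O[a, , drop = FALSE], 2, bb$N[d, ])) * 10
    rOH <- .row_norm(sweep(bb$O[a, , drop = FALSE], 2, h[d, ])) * 10
    rCN <- .row_norm(sweep(bb$C[a, , drop = FALSE], 2, bb$N[d, ])) * 10
    rCH <- .row_norm(sweep(bb$C[a, , drop = FALSE], 2, h[d, ])) * 10
    # atoms closer than 0.5 A indicate a clash, not a hydrogen bond
    ok <- pmin(rON, rOH, rCN, rCH) > 0.5
    E <- .KS_COUPLING * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
    HB[d, a[ok & E < cutoff]] <- TRUE
  }
  HB
}

#' Secondary-structure assignment (Kabsch-Sander / DSSP criteria)
#'
#' Assigns one of the codes H (alpha-helix), G (3-10 helix), I (pi-helix),
#' E (beta-strand), B (isolated beta-bridge), T (turn), S (bend) or C (coil)
#' to every residue from backbone geometry, using the Kabsch-Sander
#' electrostatic hydrogen-bond energy with the standard -0.5 kcal/mol cutoff
#' and carbonyl-based amide-hydrogen placement. Reported percentages merge
#' strand and bridge (`pct_beta = E + B`), matching the convention of the
#' packaged test-set table.
#'
#' @param conf A `conformation` with backbone N, CA, C, O atoms.
#' @return List of class `dssp`: `codes` (character per residue),
#'   `percentages` (named vector: `pct_310`, `pct_alpha`, `pct_pi`,
#'   `pct_beta`, `pct_turn`, `pct_bend`), and the logical hydrogen-bond
#'   matrix `hbonds` (donor rows, acceptor columns).
#' @export
assign_dssp <- function(conf) {
  bb <- .backbone_table(conf)
  n <- bb$n
  codes <- rep("C", n)
  if (n < 3L) {
    return(.dssp_result(codes, matrix(FALSE, n, n)))
  }
  h <- amide_h_positions(conf)
  HB <- .ks_hbond_matrix(bb, h)

  turn_at <- function(k) {
    # n-turn at i: NH(i+k) donates to CO(i)
    v <- logical(n)
    if (n > k) {
      idx <- seq_len(n - k)
      v[idx] <- HB[cbind(idx + k, idx)]
    }
    v
  }
  T3 <- turn_at(3L); T4 <- turn_at(4L); T5 <- turn_at(5L)

  assigned <- rep(FALSE, n)  # claimed by a structure class (not T/S)
  mark <- function(idx, code) {
    idx <- idx[idx >= 1L & idx <= n & !assigned[idx]]
    codes[idx] <<- code
    assigned[idx] <<- TRUE
  }

  # alpha helices first (highest priority)
  h4_start <- which(T4 & c(FALSE, T4[-n]))
  for (i in h4_start) mark(i:(i + 3L), "H")

  # beta bridges and ladders
  br_i <- integer(); br_j <- integer(); br_type <- character()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i < 3L) next
      par <- (i > 1L && HB[j, i - 1L] && i < n && HB[i + 1L, j]) ||
             (j > 1L && HB[i, j - 1L] && j < n && HB[j + 1L, i])
      anti <- (HB[j, i] && HB[i, j]) ||
              (i > 1L && j < n && HB[j + 1L, i - 1L] &&
               i < n && j > 1L && HB[i + 1L, j - 1L])
      if (par || anti) {
        br_i <- c(br_i, i); br_j <- c(br_j, j)
        br_type <- c(br_type, if (anti) "A" else "P")
      }
    }
  }
  if (length(br_i)) {
    nb <- length(br_i)
    # group bridges into ladders, allowing beta bulges: same type, and the
    # gap between consecutive bridges at most 2 on one strand and 5 on the
    # other (one/four extra residues)
    comp <- seq_len(nb)
    for (a in seq_len(nb)) {
      for (b in seq_len(nb)) {
        if (a >= b || br_type[a] != br_type[b]) next
        di <- abs(br_i[b] - br_i[a]); dj <- abs(br_j[b] - br_j[a])
        if ((di <= 2L && dj <= 5L) || (di <= 5L && dj <= 2L)) {
          old <- comp[b]; comp[comp == old] <- comp[a]
        }
      }
    }
    for (cid in unique(comp)) {
      members <- which(comp == cid)
      if (length(members) == 1L) {
        mark(br_i[members], "B"); mark(br_j[members], "B")
      } else {
        ri <- range(br_i[members]); rj <- range(br_j[members])
        mark(ri[1]:ri[2], "E"); mark(rj[1]:rj[2], "E")
      }
    }
  }

  # shorter/longer helices
  g_start <- which(T3 & c(FALSE, T3[-n]))
  for (i in g_start) mark(i:(i + 2L), "G")
  i_start <- which(T5 & c(FALSE, T5[-n]))
  for (i in i_start) mark(i:(i + 4L), "I")

  # hydrogen-bonded turns
  for (k in list(c(3L, "T3"), c(4L, "T4"), c(5L, "T5"))) {
    kk <- as.integer(k[1])
    tv <- switch(k[2], T3 = T3, T4 = T4, T5 = T5)
    for (i in which(tv)) {
      idx <- (i + 1L):(i + kk - 1L)
      idx <- idx[idx <= n & !assigned[idx]]
      codes[idx] <- "T"
      assigned[idx] <- TRUE
    }
  }

  # bends: backbone direction change (kappa) above 70 degrees
  if (n >= 5L) {
    for (i in 3:(n - 2L)) {
      if (assigned[i]) next
      u <- bb$CA[i, ] - bb$CA[i - 2L, ]
      v <- bb$CA[i + 2L, ] - bb$CA[i, ]
      if (any(is.na(u)) || any(is.na(v))) next
      kappa <- acos(pmin(1, pmax(-1, sum(u * v) /
                                   sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
      if (kappa > 70) codes[i] <- "S"
    }
  }

  .dssp_result(codes, HB)
}

.dssp_result <- function(codes, HB) {
  n <- length(codes)
  pct <- function(...) 100 * sum(codes %in% c(...)) / n
  structure(list(
    codes = codes,
    percentages = c(pct_310 = pct("G"), pct_alpha = pct("H"),
                    pct_pi = pct("I"), pct_beta = pct("E", "B"),
                    pct_turn = pct("T"), pct_bend = pct("S")),
    hbonds = HB
  ), class = "dssp")
}

#' @export
print.dssp <- function(x, ...) {
  cat("<dssp>", paste(x$codes, collapse = ""), "\n")
  p <- x$percentages
  cat(sprintf("  3-10 %.0f%%  alpha %.0f%%  pi %.0f%%  beta %.0f%%\n",
              p["pct_310"], p["pct_alpha"], p["pct_pi"], p["pct_beta"]))
  invisible(x)
}
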