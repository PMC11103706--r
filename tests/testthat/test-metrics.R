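test_that("hydrogen-bond thresholds act on distance and angle", {
  # hand-built donor/acceptor geometry: residue 1 provides the carbonyl that
  # orients residue 3's amide H towards residue 1... instead construct
  # directly: N-H of residue 4 pointing at O of residue 1
  mk <- function(d_ha, angle_deg) {
    # donor N at origin-ish, H 0.1 nm away, acceptor O placed at distance
    # d_ha from H with the requested D-H-A angle
    N <- c(0, 0, 0)
    H <- c(0.1, 0, 0)
    th <- angle_deg * pi / 180
    A <- H + d_ha * c(cos(pi - th), sin(pi - th), 0)
    # residues: 1 = acceptor (needs C and O), 4 = donor (N + explicit H)
    xyz <- rbind(A + c(0.12, 0, 0), A,           # C, O of residue 1
                 c(2, 2, 2), c(2.1, 2, 2),       # spacer residues 2, 3
                 N, H)                           # N, H of residue 4
    mkconf(xyz, name = c("C", "O", "CA", "CA", "N", "H"),
           element = c("C", "O", "C", "C", "N", "H"),
           residue_index = c(0L, 0L, 1L, 2L, 3L, 3L))
  }
  expect_equal(hydrogen_bonds(mk(0.20, 170))$count, 1L)
  expect_equal(hydrogen_bonds(mk(0.26, 170))$count, 0L)  # distance boundary
  expect_equal(hydrogen_bonds(mk(0.20, 110))$count, 0L)  # angle boundary
  # measured geometry is reported
  b <- hydrogen_bonds(mk(0.20, 170))$bonds
  expect_equal(b$dist_nm, 0.20, tolerance = 1e-9)
  expect_equal(b$angle_deg, 170, tolerance = 1e-6)
})

test_that("hydrogen-bond detector matches an O(n^2) brute-force scan", {
  for (builder in list(function() build_ideal_helix(14),
                       function() build_ideal_hairpin(14),
                       function() build_ideal_helix(20, phi = -49, psi = -26))) {
    conf <- builder()
    got <- hydrogen_bonds(conf)$bonds
    ref <- brute_force_hbonds(conf)
    got_k <- paste(got$donor_res, got$acceptor_res)
    ref_k <- if (is.null(ref)) character() else paste(ref[, 1], ref[, 2])
    expect_setequal(got_k, ref_k)
  }
})

test_that("native hydrogen-bond retention tracks broken bonds", {
  h <- build_ideal_helix(14)
  ens <- read_ensemble(h, list(h$xyz, h$xyz, h$xyz))
  ref_count <- hydrogen_bonds(h)$count
  nat <- native_hbond_count(ens, h)
  expect_equal(nat$per_frame, rep(ref_count, 3))
  expect_equal(nat$mean, ref_count)

  # unwind one turn in one frame: displace the amide H/N of residues 5-6
  # far from their acceptors
  broken <- h$xyz
  idx <- which(h$atoms$residue_index %in% 4:5 &
                 h$atoms$name %in% c("N", "H"))
  broken[idx, ] <- broken[idx, ] + 1.0
  ens2 <- read_ensemble(h, list(h$xyz, broken))
  nat2 <- native_hbond_count(ens2, h)
  # frame 2 loses exactly the native bonds donated by residues 4 and 5
  lost <- sum(nat$native$donor_res %in% 4:5)
  expect_gt(lost, 0)
  expect_equal(nat2$per_frame[2], ref_count - lost)

  # zero-bond reference gives zero everywhere
  stretched <- mkconf(matrix(seq(0, 30, length.out = 12), 4, 3),
                      name = rep(c("N", "CA", "C", "O"), 1),
                      element = c("N", "C", "C", "O"),
                      residue_index = rep(0:0, 4))
  # reference with no detectable bonds: use a 3-residue extended chain
  ext <- build_ideal_helix(4, phi = 180, psi = 180)
  expect_equal(hydrogen_bonds(ext)$count, 0L)
  ens3 <- read_ensemble(ext, list(ext$xyz, ext$xyz))
  expect_equal(native_hbond_count(ens3, ext)$per_frame, c(0L, 0L))

  h2 <- build_ideal_helix(10)
  expect_error(native_hbond_count(ens2, h2), "topology")
})

test_that("SASA reproduces closed forms and a dense-grid oracle", {
  cfg <- sasa_config()
  # isolated atom: full extended sphere
  one <- mkconf(matrix(0, 1, 3))
  expect_equal(sasa(one, cfg)$total, 4 * pi * (0.172 + 0.14)^2,
               tolerance = 1e-9)
  # two atoms beyond contact: additive
  two <- mkconf(rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(sasa(two, cfg)$total, 2 * 4 * pi * 0.312^2, tolerance = 1e-9)
  # overlapping systems against the latitude-grid integration oracle
  sets <- list(rbind(c(0, 0, 0), c(0.25, 0, 0)),
               rbind(c(0, 0, 0), c(0.3, 0, 0), c(0.15, 0.25, 0)),
               rbind(c(0, 0, 0), c(0.2, 0.2, 0.2), c(0.4, 0, 0),
                     c(0.2, -0.2, 0.1), c(0, 0.4, 0.3)))
  for (xyz in sets) {
    conf <- mkconf(xyz)
    got <- sasa(conf, cfg)$total
    oracle <- grid_sasa_oracle(xyz, rep(0.172, nrow(xyz)), 0.14)
    expect_lt(abs(got - oracle) / oracle, 0.02)
  }
  # polar + nonpolar = total, and missing radii are reported by name
  h <- build_ideal_helix(8)
  s <- sasa(h, cfg)
  expect_equal(s$polar + s$nonpolar, s$total, tolerance = 1e-12)
  expect_equal(s$total, sum(s$per_atom), tolerance = 1e-12)
  odd <- mkconf(matrix(0, 1, 3), element = "ZZ")
  expect_error(sasa(odd, cfg), "ZZ")
})

test_that("radius of gyration follows the mass-weighted definition", {
  expect_equal(radius_of_gyration(mkconf(matrix(5, 1, 3))), 0)
  # two equal masses distance d apart -> d/2
  two <- mkconf(rbind(c(0, 0, 0), c(0.3, 0, 0)))
  expect_equal(radius_of_gyration(two), 0.15, tolerance = 1e-12)
  # four unit-mass atoms on a 0.1 nm square: direct summation oracle
  xyz <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(0, 0.1, 0), c(0.1, 0.1, 0))
  sq <- mkconf(xyz, mass = 1)
  com <- colMeans(xyz)
  oracle <- sqrt(sum(sweep(xyz, 2, com)^2) / 4)
  expect_equal(radius_of_gyration(sq), oracle, tolerance = 1e-12)
  # mass weighting: heavy atom pulls the centre
  uneq <- mkconf(rbind(c(0, 0, 0), c(0.3, 0, 0)), mass = c(3, 1))
  oracle2 <- sqrt((3 * 0.075^2 + 1 * 0.225^2) / 4)
  expect_equal(radius_of_gyration(uneq), oracle2, tolerance = 1e-12)
  # linear scaling under coordinate scaling
  h <- build_ideal_helix(9)
  h2 <- h; h2$xyz <- h$xyz * 2.5
  expect_equal(radius_of_gyration(h2), 2.5 * radius_of_gyration(h),
               tolerance = 1e-12)
})

test_that("superposition RMSD is zero under rigid motion and matches a
           rotation-search oracle", {
  h <- build_ideal_helix(8)
  sel <- select_backbone(h)
  expect_equal(fit_rmsd(h, h, sel), 0, tolerance = 1e-12)
  h2 <- h
  h2$xyz <- rigid_move(h$xyz, theta = 1.2, shift = c(0.4, -1, 2))
  expect_lt(fit_rmsd(h2, h, sel), 1e-6)

  # four atoms, one displaced: compare to brute-force rotation search
  base <- rbind(c(0, 0, 0), c(0.4, 0, 0), c(0, 0.4, 0), c(0, 0, 0.4))
  moved <- base
  moved[4, ] <- moved[4, ] + c(0.2, 0, 0)
  ca <- mkconf(base); cb <- mkconf(moved)
  got <- fit_rmsd(cb, ca, 1:4)
  oracle <- rotation_search_rmsd(moved, base)
  expect_equal(got, oracle, tolerance = 1e-3)

  degenerate <- mkconf(rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.2, 0, 0)))
  expect_error(fit_rmsd(degenerate, degenerate, 1:3), "collinear")
  expect_error(fit_rmsd(ca, ca, 1:2), "3 atoms")
})

test_that("RMSD100 normalisation has the documented fixed points", {
  expect_equal(rmsd100(0.2, 100), 0.2)
  expect_equal(rmsd100(0.2, 35), 0.2)     # small proteins pass through
  expect_equal(rmsd100(0.2, 40), 0.2)
  expect_equal(rmsd100(0.2, 200), 0.2 / (1 + log(sqrt(2))))
  # monotonicity of the normaliser around N = 100
  for (n in c(45, 60, 99)) expect_gt(rmsd100(0.2, n), 0.2)
  for (n in c(101, 150, 300)) expect_lt(rmsd100(0.2, n), 0.2)
})

test_that("backbone dihedrals recover canonical values", {
  # planar zigzag: phi = psi = 180
  ext <- build_ideal_helix(6, phi = 180, psi = 180)
  d <- backbone_dihedrals(ext)
  expect_true(all(abs(abs(d$phi[2:5]) - 180) < 1e-6))
  expect_true(all(abs(abs(d$psi[2:5]) - 180) < 1e-6))
  h <- build_ideal_helix(8)
  dh <- backbone_dihedrals(h)
  expect_equal(dh$phi[2:7], rep(-57, 6), tolerance = 1e-6)
  expect_equal(dh$psi[2:7], rep(-47, 6), tolerance = 1e-6)
  expect_true(is.na(dh$phi[1]))  # no predecessor
  expect_true(is.na(dh$psi[8]))  # no successor
})

test_that("dihedral histograms are normalised and validated", {
  h <- build_ideal_helix(6)
  ens <- read_ensemble(h, list(h$xyz))
  d <- pool_dihedrals(ens)
  hist <- dihedral_histograms(d)
  expect_equal(sum(hist$phi), 1)
  expect_equal(sum(hist$psi), 1)
  expect_equal(sum(hist$ramachandran), 1)
  # a single ideal conformation puts all phi mass in one bin
  expect_equal(sum(hist$phi > 0), 1L)
  expect_error(dihedral_histograms(d, bin_1d = 7), "divide 360")

  # uniform angles give a flat histogram within multinomial error
  set.seed(11)
  n <- 20000
  u <- data.frame(resid = "ALA", phi = runif(n, -180, 180),
                  psi = runif(n, -180, 180))
  hu <- dihedral_histograms(u, bin_1d = 30)
  p0 <- 1 / 12
  ci <- 3 * sqrt(p0 * (1 - p0) / n)
  expect_true(all(abs(hu$phi - p0) < ci))

  # per-residue-type mode pools by 3-letter code
  u2 <- rbind(u, data.frame(resid = "GLY", phi = 10, psi = 10))
  by_res <- dihedral_histograms(u2, bin_1d = 30, by_residue = TRUE)
  expect_setequal(names(by_res), c("ALA", "GLY"))
  expect_equal(sum(by_res$GLY$phi), 1)
})

test_that("percentage deviation is signed and guards the zero reference", {
  expect_equal(delta_q_percent(1.0, 1.0), 0)
  expect_equal(delta_q_percent(1.1, 1.0), 10, tolerance = 1e-9)
  expect_equal(delta_q_percent(0.9, 1.0), -10, tolerance = 1e-9)
  expect_error(delta_q_percent(1, 0), "zero reference")
})

test_that("structural metrics are invariant under rigid motion", {
  h <- build_ideal_helix(10)
  h2 <- h
  h2$xyz <- rigid_move(h$xyz, theta = 0.7, shift = c(-1, 0.2, 3))
  expect_equal(radius_of_gyration(h2), radius_of_gyration(h),
               tolerance = 1e-9)
  expect_equal(hydrogen_bonds(h2)$bonds$donor_res,
               hydrogen_bonds(h)$bonds$donor_res)
  expect_equal(assign_dssp(h2)$codes, assign_dssp(h)$codes)
  # sphere-point sampling is weakly orientation-dependent; demand agreement
  # well below the method's discretisation error
  expect_equal(sasa(h2)$total, sasa(h)$total, tolerance = 5e-3)
  d1 <- backbone_dihedrals(h); d2 <- backbone_dihedrals(h2)
  expect_equal(d2$phi, d1$phi, tolerance = 1e-6)
})
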