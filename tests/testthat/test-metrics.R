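# Per-residue structural/dynamic descriptors.

make_static_ensemble <- function(nres = 8, nframes = 5, stride = 1) {
  ref <- gen_ideal_structure("alpha_helix", nres)
  new_ensemble(ref, rep(list(coords(ref)), nframes), stride_ns = stride)
}

test_that("analysis frames follow the 1 ns tick convention", {
  ref <- gen_ideal_structure("alpha_helix", 4)
  ens <- gen_gaussian_ensemble(ref, fluctuation_spec(
    0.1, duration_ns = 20, stride_ns = 0.25, seed = 1))
  expect_equal(n_frames(ens), 80)
  fidx <- analysis_frames(ens, 1.0)
  expect_length(fidx, 20)
  expect_equal(fidx, seq(4, 80, by = 4))
  expect_error(analysis_frames(ens, 25),
               class = "dynsite_empty_analysis_error")
})

test_that("per-residue RMSD is zero for a static ensemble", {
  ens <- make_static_ensemble()
  rr <- per_residue_rmsd(ens, analysis_stride_ns = 1)
  expect_true(all(abs(rr$mean) < 1e-10))
  expect_equal(ncol(rr$per_interval), 5)
})

test_that("per-residue RMSD matches a brute-force per-frame oracle", {
  ref <- gen_ideal_structure("alpha_helix", 15, sidechains = TRUE)
  refxyz <- coords(ref)
  keys <- residue_keys(ref)
  target <- residues(ref)$key[8]
  disp <- refxyz
  disp[keys == target, ] <- sweep(disp[keys == target, , drop = FALSE],
                                  2, c(0.7, -0.2, 0.4), "+")
  ens <- new_ensemble(ref, list(disp, disp, disp), stride_ns = 1)
  rr <- per_residue_rmsd(ens, analysis_stride_ns = 1)
  # oracle: independent superposition via bio3d::fit.xyz, then direct RMSD
  fit <- select_atoms(ref, selection_spec(atoms = "CA", hetero = FALSE))
  xyz_inds <- as.vector(rbind(3 * fit - 2, 3 * fit - 1, 3 * fit))
  sup_v <- bio3d::fit.xyz(as.vector(t(refxyz)), as.vector(t(disp)),
                          fixed.inds = xyz_inds, mobile.inds = xyz_inds)
  sup <- matrix(sup_v, ncol = 3, byrow = TRUE)
  heavy <- select_atoms(ref, selection_spec(atoms = "heavy"))
  for (k in unique(keys)) {
    ai <- intersect(which(keys == k), heavy)
    want <- sqrt(mean(rowSums((sup[ai, , drop = FALSE] -
                                 refxyz[ai, , drop = FALSE])^2)))
    expect_equal(unname(rr$mean[k]), want, tolerance = 1e-6)
  }
  # the displaced residue carries (approximately) the displacement norm
  expect_equal(unname(rr$mean[target]), sqrt(sum(c(0.7, -0.2, 0.4)^2)),
               tolerance = 0.08)
})

test_that("RMSF: static is zero, single frame errors", {
  ens <- make_static_ensemble()
  expect_true(all(per_residue_rmsf(ens) < 1e-10))
  one <- new_ensemble(ens$topology, ens$frames[1])
  expect_error(per_residue_rmsf(one),
               class = "dynsite_undefined_fluctuation_error")
})

test_that("RMSF two-point closed form: alternating +/- d displacement", {
  ref <- gen_ideal_structure("alpha_helix", 12)
  refxyz <- coords(ref)
  keys <- residue_keys(ref)
  target <- residues(ref)$key[6]
  d <- 0.8
  up <- refxyz; up[keys == target, 1] <- up[keys == target, 1] + d
  dn <- refxyz; dn[keys == target, 1] <- dn[keys == target, 1] - d
  ens <- new_ensemble(ref, list(up, dn, up, dn), stride_ns = 1)
  anchors <- selection_spec(resseq = setdiff(residues(ref)$resseq, 6),
                            atoms = "CA", hetero = FALSE)
  rf <- per_residue_rmsf(ens, fit_selection = anchors)
  expect_equal(unname(rf[target]), d, tolerance = 1e-9)
  expect_true(all(rf[names(rf) != target] < 1e-9))
})

test_that("RMSF recovers sigma*sqrt(3) on isotropic Gaussian noise", {
  ref <- gen_ideal_structure("alpha_helix", 30)
  sds <- rep(0.02, 30); sds[15] <- 0.5
  ens <- gen_gaussian_ensemble(ref, fluctuation_spec(sds, n_frames = 2000,
                                                     seed = 42))
  rf <- per_residue_rmsf(ens)
  expect_equal(unname(rf[residues(ref)$key[15]]), 0.5 * sqrt(3),
               tolerance = 0.05)
})

test_that("DCCM invariants: unit diagonal, symmetry, range", {
  ref <- gen_ideal_structure("alpha_helix", 10)
  ens <- gen_gaussian_ensemble(ref, fluctuation_spec(0.3, n_frames = 50,
                                                     seed = 2))
  C <- dccm(ens)$matrix
  expect_equal(unname(diag(C)), rep(1, 10))
  expect_equal(C, t(C))
  expect_true(all(C >= -1 & C <= 1, na.rm = TRUE))
})

test_that("rigid common translation gives all-ones DCCM (no superposition)", {
  ref <- gen_ideal_structure("alpha_helix", 6)
  refxyz <- coords(ref)
  frames <- lapply(c(0, 0.5, -0.3, 1.2), function(s)
    sweep(refxyz, 2, c(s, 2 * s, -s), "+"))
  ens <- new_ensemble(ref, frames, stride_ns = 1)
  C <- dccm(ens, superpose = FALSE)$matrix
  expect_true(all(abs(C - 1) < 1e-9))
})

test_that("zero-variance residues yield NA correlations, not 0", {
  ref <- gen_ideal_structure("alpha_helix", 6)
  refxyz <- coords(ref)
  keys <- residue_keys(ref)
  mobile <- residues(ref)$key[1:3]
  frames <- lapply(1:30, function(k) {
    f <- refxyz
    set.seed(k)
    for (m in mobile)
      f[keys == m, ] <- sweep(f[keys == m, , drop = FALSE], 2,
                              rnorm(3, sd = 0.3), "+")
    f
  })
  ens <- new_ensemble(ref, frames, stride_ns = 1)
  C <- dccm(ens, superpose = FALSE)$matrix
  expect_true(all(is.na(C[4:6, 1:3])))
  expect_equal(unname(diag(C)), rep(1, 6))
})

test_that("DCCM recovers prescribed two-block correlation structure", {
  ref <- gen_ideal_structure("alpha_helix", 40)
  sds <- rep(0.05, 40); sds[c(5:12, 18:25)] <- 0.4
  spec <- fluctuation_spec(sds, blocks = list(
    list(residues = 5:12, rho = 0.8),
    list(residues = 18:25, rho = 0.8)), n_frames = 5000, seed = 7)
  ens <- gen_gaussian_ensemble(ref, spec)
  anchors <- selection_spec(
    resseq = residues(ref)$resseq[setdiff(1:40, c(5:12, 18:25))],
    atoms = "CA", hetero = FALSE)
  C <- dccm(ens, fit_selection = anchors)$matrix
  b1 <- C[5:12, 5:12]
  expect_equal(mean(b1[upper.tri(b1)]), 0.8, tolerance = 0.05)
  b2 <- C[18:25, 18:25]
  expect_equal(mean(b2[upper.tri(b2)]), 0.8, tolerance = 0.05)
  expect_equal(mean(C[5:12, 18:25]), 0, tolerance = 0.05)
})

test_that("DCCM agrees with the bio3d estimator", {
  ref <- gen_ideal_structure("alpha_helix", 8)
  ens <- gen_gaussian_ensemble(ref, fluctuation_spec(0.3, n_frames = 200,
                                                     seed = 9))
  sel <- select_atoms(ref, selection_spec(atoms = "CA", hetero = FALSE))
  X <- do.call(rbind, lapply(ens$frames, function(f)
    as.vector(t(f[sel, ]))))
  want <- bio3d::dccm(X)
  got <- dccm(ens, superpose = FALSE)$matrix
  expect_equal(unname(got), unname(want[, ]), tolerance = 1e-6)
})

test_that("dccm_residue_score reduces correctly", {
  labels <- paste0("R", 1:6)
  set.seed(4)
  M <- matrix(runif(36, -1, 1), 6, 6)
  M <- (M + t(M)) / 2; diag(M) <- 1
  dimnames(M) <- list(labels, labels)
  dm <- structure(list(residues = labels, keys = labels, matrix = M),
                  class = "DCCMatrix")
  # direct-summation oracle
  partners <- c("R2", "R4", "R5")
  expect_equal(dccm_residue_score(dm, "R1", partners),
               mean(M["R1", partners]), tolerance = 1e-12)
  # self exclusion and symmetry examples
  M2 <- M; M2["R1", c("R2", "R3")] <- c(0.5, -0.5)
  dm2 <- structure(list(residues = labels, keys = labels, matrix = M2),
                   class = "DCCMatrix")
  expect_equal(dccm_residue_score(dm2, "R1", c("R2", "R3")), 0)
  M3 <- M; M3["R1", -1] <- 1
  dm3 <- structure(list(residues = labels, keys = labels, matrix = M3),
                   class = "DCCMatrix")
  expect_equal(dccm_residue_score(dm3, "R1", labels), 1)
  expect_error(dccm_residue_score(dm, "R1", "R1"),
               class = "dynsite_validation_error")
})

test_that("contact counts: isolated zero, single pair, inclusive boundary", {
  iso <- new_structure(carbon_grid(4, spacing = 20))
  expect_equal(contact_counts(iso, residue_label(rep("LIG", 1), 1)), 0)
  two <- new_structure(rbind(
    atom_row(1, "C1", "C", "LIG", 1, "A", 0, 0, 0, hetero = TRUE),
    atom_row(2, "C1", "C", "LIG", 2, "A", 4.9, 0, 0, hetero = TRUE)))
  expect_equal(contact_counts(two, "LIG1"), 1)
  atb <- new_structure(rbind(
    atom_row(1, "C1", "C", "LIG", 1, "A", 0, 0, 0, hetero = TRUE),
    atom_row(2, "C1", "C", "LIG", 2, "A", 5.0, 0, 0, hetero = TRUE)))
  expect_equal(contact_counts(atb, "LIG1"), 1)   # inclusive at 5.0
  expect_error(contact_counts(two, "NOPE"), class = "dynsite_lookup_error")
})

test_that("contact counts match the brute-force all-pairs oracle", {
  set.seed(12)
  at <- do.call(rbind, lapply(1:30, function(i)
    atom_row(i, sample(c("C1", "N1", "O1"), 1),
             sample(c("C", "N", "O"), 1), "XYZ",
             (i - 1) %/% 3 + 1, "A",
             rnorm(1, sd = 3), rnorm(1, sd = 3), rnorm(1, sd = 3),
             hetero = TRUE)))
  s <- new_structure(at)
  for (r in residues(s)$label)
    expect_equal(unname(contact_counts(s, r)), oracle_contact_count(s, r))
})

test_that("contacts are symmetric as a relation and peptide links excluded", {
  s <- gen_ideal_structure("alpha_helix", 6, sidechains = TRUE)
  cc <- contact_counts(s)
  a <- s$atoms
  # peptide C-N link sits well under 5 A yet adjacent-residue atom pairs
  # must exclude exactly that bonded pair: verify via the oracle
  for (r in residues(s)$label)
    expect_equal(unname(cc[r]), oracle_contact_count(s, r))
})

test_that("SASA closed forms: single sphere, no-overlap additivity, caps", {
  one <- new_structure(atom_row(1, "C1", "C", "LIG", 1, "A", 0, 0, 0,
                                hetero = TRUE))
  a1 <- sum(sasa(one)$atom_area)
  exact1 <- 4 * pi * (1.7 + 1.4)^2
  expect_equal(a1, exact1, tolerance = 0.005)
  far <- new_structure(rbind(
    atom_row(1, "C1", "C", "LIG", 1, "A", 0, 0, 0, hetero = TRUE),
    atom_row(2, "C1", "C", "LIG", 2, "A", 2 * (1.7 + 1.4) + 0.1, 0, 0,
             hetero = TRUE)))
  expect_equal(sum(sasa(far)$atom_area), 2 * a1, tolerance = 1e-9)
  r <- 1.7 + 1.4
  for (d in c(1.8, 3.0, 4.5)) {
    ov <- new_structure(rbind(
      atom_row(1, "C1", "C", "LIG", 1, "A", 0, 0, 0, hetero = TRUE),
      atom_row(2, "C1", "C", "LIG", 2, "A", d, 0, 0, hetero = TRUE)))
    expect_equal(sum(sasa(ov, n_points = 4000)$atom_area),
                 two_sphere_area(r, d), tolerance = 0.01)
  }
})

test_that("SASA never exceeds isolated-sphere areas; unknown element errors", {
  s <- gen_ideal_structure("alpha_helix", 8, sidechains = TRUE)
  sa <- sasa(s)
  iso <- vapply(s$atoms$element[sa$atom_idx], function(el)
    4 * pi * (dynsite:::VDW_RADII[[el]] + 1.4)^2, numeric(1))
  expect_true(all(sa$atom_area <= iso + 1e-9))
  bad <- new_structure(atom_row(1, "XX", "XQ", "LIG", 1, "A", 0, 0, 0,
                                hetero = TRUE))
  expect_error(sasa(bad), class = "dynsite_radius_error")
})

test_that("exposure ratio: buried cage near 0, GXG near 100, glycine proxy", {
  tri <- gen_reference_tripeptide("LEU")
  lab <- residues(tri)$label[2]
  expect_equal(exposure_ratio(tri, lab), 100, tolerance = 0.15)
  # cage: surround the side chain with a dense shell of carbons
  sc <- select_atoms(tri, selection_spec(resseq = 2, atoms = "sidechain"))
  ctr <- colMeans(coords(tri)[sc, , drop = FALSE])
  pts <- dynsite:::golden_spiral(300) * 6.0
  cage <- do.call(rbind, lapply(seq_len(nrow(pts)), function(i)
    atom_row(1000 + i, "C1", "C", "CAG", 900 + i, "Z",
             ctr[1] + pts[i, 1], ctr[2] + pts[i, 2], ctr[3] + pts[i, 3],
             hetero = TRUE)))
  caged <- new_structure(rbind(tri$atoms[, names(cage)], cage))
  expect_lt(exposure_ratio(caged, lab), 5)
  # glycine: CA as side-chain proxy
  gtri <- gen_reference_tripeptide("GLY")
  glab <- residues(gtri)$label[2]
  expect_equal(exposure_ratio(gtri, glab), 100, tolerance = 0.15)
  hetero <- new_structure(atom_row(1, "C1", "C", "LIG", 1, "A", 0, 0, 0,
                                   hetero = TRUE))
  expect_error(exposure_ratio(hetero, "LIG1"),
               class = "dynsite_unsupported_residue_error")
})

test_that("secondary structure: helix H, 3-10 G, sheet E, dipeptide C", {
  h <- assign_secondary_structure(gen_ideal_structure("alpha_helix", 12))
  expect_true(all(h[3:10] == "H"))
  g <- assign_secondary_structure(gen_ideal_structure("three10_helix", 12))
  expect_true(all(g[3:10] == "G"))
  e <- assign_secondary_structure(gen_ideal_structure("antiparallel_sheet", 6))
  expect_true(all(e[c(2:5, 8:11)] == "E"))
  d <- assign_secondary_structure(gen_ideal_structure("coil", 2))
  expect_true(all(d == "C"))
})

test_that("missing backbone atoms label C with a warning record", {
  s <- gen_ideal_structure("alpha_helix", 12)
  drop <- which(s$atoms$resseq == 6 & s$atoms$name == "O")
  s2 <- new_structure(s$atoms[-drop, ])
  lab <- assign_secondary_structure(s2)
  expect_equal(unname(lab["A6"]), "C")
  expect_match(attr(lab, "warnings"), "A6", all = FALSE)
})

test_that("ss_fractions tally frames exactly and sum to one", {
  helix <- gen_ideal_structure("alpha_helix", 10)
  coil <- gen_ideal_structure("coil", 10)
  ens <- new_ensemble(helix, c(rep(list(coords(helix)), 3),
                               rep(list(coords(coil)), 2)), stride_ns = 1)
  sf <- ss_fractions(ens, 1)
  expect_true(all(abs(rowSums(sf) - 1) < 1e-9))
  expect_equal(unname(sf["A5", "H"]), 0.6)
  expect_equal(unname(sf["A5", "C"]), 0.4)
})

test_that("metrics are invariant under global rigid transforms of frames", {
  ref <- gen_ideal_structure("alpha_helix", 10)
  ens <- gen_gaussian_ensemble(ref, fluctuation_spec(0.3, n_frames = 20,
                                                     seed = 5))
  set.seed(99)
  trs <- lapply(seq_len(n_frames(ens)), function(i) random_rigid_transform())
  ens2 <- new_ensemble(ref, lapply(seq_len(n_frames(ens)), function(i)
    apply_rigid(ens$frames[[i]], trs[[i]])), stride_ns = 0.25)
  expect_equal(per_residue_rmsf(ens2), per_residue_rmsf(ens),
               tolerance = 1e-6)
  expect_equal(dccm(ens2)$matrix, dccm(ens)$matrix, tolerance = 1e-6)
  expect_equal(per_residue_rmsd(ens2)$mean, per_residue_rmsd(ens)$mean,
               tolerance = 1e-6)
})

test_that("residue metric table assembles with valid invariants", {
  ref <- gen_ideal_structure("alpha_helix", 8, sidechains = TRUE)
  ens <- gen_gaussian_ensemble(ref, fluctuation_spec(0.2, n_frames = 5,
                                                     stride_ns = 1, seed = 3))
  tab <- residue_metric_table(ens, n_points = 240)
  expect_s3_class(tab, "ResidueMetricTable")
  expect_true(all(tab$rmsf >= 0))
  expect_true(all(tab$sasa_mean >= 0))
  expect_true(all(tab$contacts_mean >= 0))
  ssum <- rowSums(tab[, paste0("ss_", c("H", "G", "E", "T", "C"))])
  expect_true(all(abs(ssum - 1) < 1e-9))
  expect_true(all(tab$dccm_score >= -1 & tab$dccm_score <= 1, na.rm = TRUE))
  f <- tempfile(fileext = ".tsv")
  write_metric_table(tab, f)
  hdr <- readLines(f, n = 1)
  expect_match(hdr, "^# ")
  tab2 <- read_metric_table(f)
  expect_equal(tab2$residue, tab$residue)
  expect_equal(tab2$rmsf, tab$rmsf, tolerance = 1e-12)
})
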