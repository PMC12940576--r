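# Ligand interaction detection, pose triage, bound-state classification,
# and interaction-set algebra.

# serine residue with backbone + explicit amide H, plus a ligand oxygen
# placed so that d(N, O) = o_dist and the D-H-A angle equals dha_deg
hbond_fixture <- function(o_dist, dha_deg = 180) {
  prot <- rbind(
    atom_row(1, "N", "N", "SER", 10, "A", 0, 0, 0),
    atom_row(2, "CA", "C", "SER", 10, "A", 1.458, 0, 0),
    atom_row(3, "C", "C", "SER", 10, "A", 2.0, 1.3, 0),
    atom_row(4, "O", "O", "SER", 10, "A", 2.0, 2.5, 0),
    atom_row(5, "H", "H", "SER", 10, "A", 0, -1.01, 0))
  hpos <- c(0, -1.01, 0)
  phi <- dha_deg * pi / 180
  w <- cos(phi) * c(0, 1, 0) + sin(phi) * c(1, 0, 0)   # from H; +y is H->D
  ra <- 1.01 * cos(phi) + sqrt(o_dist^2 - 1.01^2 * sin(phi)^2)
  opos <- hpos + ra * w
  lig <- atom_row(10, "OH", "O", "LTY", 601, "L", opos[1], opos[2], opos[3],
                  hetero = TRUE)
  s <- new_structure(rbind(prot, lig))
  list(frame = s, ligand_idx = which(s$atoms$resname == "LTY"))
}

test_that("canonical N-H...O hydrogen bond is detected", {
  fx <- hbond_fixture(2.9)
  rec <- detect_hbonds(fx$frame, fx$ligand_idx)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$residue, "S10")
  expect_equal(rec$type, "hbond")
  expect_equal(rec$distance, 2.9, tolerance = 1e-9)
  expect_equal(rec$angle, 180, tolerance = 1e-6)
})

test_that("pairs beyond base + tolerance are rejected; boundary inclusive", {
  expect_equal(nrow(detect_hbonds(hbond_fixture(3.45)$frame,
                                  hbond_fixture(3.45)$ligand_idx)), 0)
  # exactly base + 0.39 A and base_angle - 19 degrees: detected
  fx <- hbond_fixture(3.39, dha_deg = 121)
  rec <- detect_hbonds(fx$frame, fx$ligand_idx)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$angle, 121, tolerance = 1e-6)
  expect_equal(rec$distance, 3.39, tolerance = 1e-9)
  # past the angle window: rejected
  fx2 <- hbond_fixture(2.9, dha_deg = 110)
  expect_equal(nrow(detect_hbonds(fx2$frame, fx2$ligand_idx)), 0)
})

test_that("ligand without polar atoms yields an empty record set", {
  prot <- rbind(atom_row(1, "N", "N", "SER", 10, "A", 0, 0, 0),
                atom_row(2, "O", "O", "SER", 10, "A", 2, 2.5, 0))
  lig <- atom_row(10, "C1", "C", "UNK", 601, "L", 0, -3, 0, hetero = TRUE)
  s <- new_structure(rbind(prot, lig))
  rec <- detect_hbonds(s, which(s$atoms$resname == "UNK"))
  expect_equal(nrow(rec), 0)
})

test_that("hydrophobic contacts: within cutoff detected, beyond rejected", {
  leu <- rbind(atom_row(1, "CA", "C", "LEU", 20, "A", 0, 0, 0),
               atom_row(2, "CD1", "C", "LEU", 20, "A", 1.5, 0, 0))
  mk <- function(d) {
    lig <- atom_row(10, "C2", "C", "DHI", 601, "L", 1.5 + d, 0, 0,
                    hetero = TRUE)
    new_structure(rbind(leu, lig))
  }
  s1 <- mk(4.5)
  rec <- detect_nonbonded_contacts(s1, which(s1$atoms$resname == "DHI"))
  expect_equal(nrow(rec), 1)
  expect_equal(rec$residue, "L20")
  expect_equal(rec$type, "hydrophobic")
  expect_equal(rec$distance, 4.5, tolerance = 1e-9)
  s2 <- mk(5.2)
  expect_equal(nrow(detect_nonbonded_contacts(
    s2, which(s2$atoms$resname == "DHI"))), 0)
})

test_that("hydrophobic record set equals exhaustive pair enumeration", {
  set.seed(21)
  prot <- do.call(rbind, lapply(1:12, function(i)
    atom_row(i, c("CA", "CB", "OG")[(i %% 3) + 1],
             c("C", "C", "O")[(i %% 3) + 1], "SER",
             (i - 1) %/% 3 + 1, "A", rnorm(1, sd = 3), rnorm(1, sd = 3),
             rnorm(1, sd = 3))))
  lig <- rbind(atom_row(100, "C1", "C", "DHI", 601, "L", 0, 0, 0,
                        hetero = TRUE),
               atom_row(101, "O5", "O", "DHI", 601, "L", 1.3, 0, 0,
                        hetero = TRUE))
  s <- new_structure(rbind(prot, lig))
  lidx <- which(s$atoms$resname == "DHI")
  rec <- detect_nonbonded_contacts(s, lidx)
  # oracle: apolar-apolar pairs within 5 A, grouped by residue, min dist
  a <- s$atoms
  want <- list()
  for (i in setdiff(which(a$element %in% c("C", "S") & !a$hetero), lidx)) {
    for (j in intersect(lidx, which(a$element %in% c("C", "S")))) {
      d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) -
                       c(a$x[j], a$y[j], a$z[j]))^2))
      if (d <= 5) {
        key <- residue_keys(s)[i]
        want[[key]] <- min(want[[key]] %||% Inf, d)
      }
    }
  }
  res <- residues(s)
  expect_setequal(rec$residue, res$label[match(names(want), res$key)])
  for (k in seq_len(nrow(rec))) {
    key <- res$key[res$label == rec$residue[k]]
    expect_equal(rec$distance[k], want[[key]], tolerance = 1e-9)
  }
})

# build a PHE residue plus a ligand ring at distance d with plane angle ang
pi_fixture <- function(d, ang_deg, code = "LTY") {
  phe <- gen_ideal_structure("beta_strand", 3,
                             sequence = c("GLY", "PHE", "GLY"),
                             sidechains = TRUE)
  ring_names <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  ridx <- which(phe$atoms$name %in% ring_names & phe$atoms$resname == "PHE")
  rg <- coords(phe)[ridx, ]
  ctr <- colMeans(rg)
  nrm <- svd(sweep(rg, 2, ctr))$v[, 3]
  tpl <- ligand_template(code)
  lr <- tpl$atoms$name %in% tpl$rings[[1]]
  lctr <- colMeans(tpl$coords[lr, , drop = FALSE])
  # template ring lies in the xy-plane (normal z); tilt by ang about x
  th <- ang_deg * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)),
               3, 3, byrow = TRUE)
  base <- dynsite:::rotation_between(c(0, 0, 1), nrm)
  placed <- sweep(tpl$coords, 2, lctr) %*% t(Rx) %*% t(base)
  placed <- sweep(placed, 2, ctr + d * nrm, "+")
  la <- tpl$atoms
  la$x <- placed[, 1]; la$y <- placed[, 2]; la$z <- placed[, 3]
  la$serial <- max(phe$atoms$serial) + seq_len(nrow(la))
  s <- new_structure(rbind(phe$atoms[, names(la)], la))
  list(frame = s, ligand_idx = which(s$atoms$resname == code))
}

test_that("pi stacking: parallel, out-of-range, and T-shaped geometries", {
  fx <- pi_fixture(3.8, 0)
  rec <- detect_pi_stacking(fx$frame, fx$ligand_idx)
  expect_gte(nrow(rec), 1)
  expect_true(any(rec$detail == "parallel" & rec$residue == "F2"))
  fx6 <- pi_fixture(6.0, 0)
  expect_equal(nrow(detect_pi_stacking(fx6$frame, fx6$ligand_idx)), 0)
  fxt <- pi_fixture(4.8, 90)
  rect <- detect_pi_stacking(fxt$frame, fxt$ligand_idx)
  expect_true(any(rect$detail == "t_shaped" & rect$residue == "F2"))
})

test_that("pose validity: distance, orientation, and missing oxygen", {
  toy <- gen_toy_active_site()
  site <- toy$site
  u <- (site$cuA - site$cuB); u <- u / sqrt(sum(u^2))
  place_lig <- function(o_dist, flip = FALSE) {
    tpl <- ligand_template("LTY")
    oxyz <- tpl$coords[tpl$atoms$name == "OH", ]
    rctr <- colMeans(tpl$coords[tpl$atoms$name %in% tpl$rings[[1]], ])
    v <- (oxyz - rctr); v <- v / sqrt(sum(v^2))
    target_dir <- if (flip) u else -u
    R <- dynsite:::rotation_between(v, target_dir)
    placed <- sweep(tpl$coords, 2, oxyz) %*% t(R)
    placed <- sweep(placed, 2, site$cuA + o_dist * u, "+")
    la <- tpl$atoms
    la$x <- placed[, 1]; la$y <- placed[, 2]; la$z <- placed[, 3]
    ligand_pose(new_structure(la), -7.0, id = 1)
  }
  expect_true(validate_pose(place_lig(3.5), site)$valid)
  v2 <- validate_pose(place_lig(4.5), site)
  expect_false(v2$valid); expect_equal(v2$reason, "distance")
  # at 3.5 A but ring centroid between oxygen and the copper midpoint
  v3 <- validate_pose(place_lig(3.5, flip = TRUE), site)
  expect_false(v3$valid); expect_equal(v3$reason, "orientation")
  # no qualifying oxygen
  bare <- ligand_pose(new_structure(atom_row(1, "C1", "C", "UNK", 601, "L",
                                             0, 0, 3.5, hetero = TRUE)),
                      -5, id = 2)
  v4 <- validate_pose(bare, site)
  expect_false(v4$valid); expect_equal(v4$reason, "no_candidate_oxygen")
})

test_that("greedy energy-ranked pose clustering", {
  mkpose <- function(x, e, id) {
    at <- rbind(atom_row(1, "C1", "C", "LIG", 1, "L", x, 0, 0,
                         hetero = TRUE),
                atom_row(2, "C2", "C", "LIG", 1, "L", x + 1, 0, 0,
                         hetero = TRUE))
    ligand_pose(new_structure(at), e, id = id)
  }
  same <- cluster_poses(list(mkpose(0, -9, 1), mkpose(0, -8, 2)))
  expect_equal(vapply(same, `[[`, integer(1), "cluster"), c(1L, 1L))
  apart <- cluster_poses(list(mkpose(0, -9, 1), mkpose(6, -8, 2)))
  expect_equal(vapply(apart, `[[`, integer(1), "cluster"), c(1L, 2L))
  # chain A-B 4, B-C 4, A-C 8 with energies A < B < C -> {A,B}, {C}
  chain <- cluster_poses(list(A = mkpose(0, -9, "A"), B = mkpose(4, -8, "B"),
                              C = mkpose(8, -7, "C")))
  expect_equal(unname(vapply(chain, `[[`, integer(1), "cluster")),
               c(1L, 1L, 2L))
  # invariants: every pose in one cluster; members within threshold of
  # seed; seeds are lowest-energy members
  set.seed(31)
  many <- lapply(1:12, function(i) mkpose(runif(1, 0, 30), runif(1, -9, -2),
                                          i))
  cl <- cluster_poses(many)
  ids <- vapply(cl, `[[`, integer(1), "cluster")
  expect_true(all(!is.na(ids)))
  members <- attr(cl, "clusters")
  for (k in seq_along(members)) {
    seed <- members[[k]][1]
    es <- vapply(members[[k]], function(i) cl[[i]]$binding_energy,
                 numeric(1))
    expect_equal(cl[[seed]]$binding_energy, min(es))
    for (m in members[[k]])
      expect_lt(dynsite:::pose_rmsd(cl[[seed]], cl[[m]]), 5.0)
  }
  bad <- list(mkpose(0, -9, 1),
              ligand_pose(new_structure(atom_row(1, "N9", "N", "LIG", 1,
                                                 "L", 0, 0, 0,
                                                 hetero = TRUE)), -7))
  expect_error(cluster_poses(bad), class = "dynsite_congruence_error")
})

test_that("bound-state classification: generator ground truth both modes", {
  toy <- gen_toy_active_site()
  ensb <- gen_ligand_trajectory(toy$structure, toy$site,
                                ligand_motion_spec("bound", jitter = 0.3,
                                                   n_frames = 20, seed = 8),
                                "LTY")
  li <- which(toupper(ensb$topology$atoms$resname) == "LTY")
  cb <- classify_bound(ensb, li, toy$site)
  expect_true(cb$bound)
  expect_true(all(cb$per_frame))
  ense <- gen_ligand_trajectory(toy$structure, toy$site,
                                ligand_motion_spec("escape", jitter = 0,
                                                   drift = 0.45,
                                                   n_frames = 20, seed = 8),
                                "DHI")
  le <- which(toupper(ense$topology$atoms$resname) == "DHI")
  ce <- classify_bound(ense, le, toy$site)
  expect_false(ce$bound)
  expect_equal(ce$first_fail, floor(0.8 / 0.45 + 1e-9) + 1)
})

test_that("single-frame boundary at exactly 4.0 A is bound (inclusive)", {
  toy <- gen_toy_active_site()
  site <- toy$site
  u <- (site$cuA - site$cuB); u <- u / sqrt(sum(u^2))
  tpl <- ligand_template("LTY")
  oxyz <- tpl$coords[tpl$atoms$name == "OH", ]
  rctr <- colMeans(tpl$coords[tpl$atoms$name %in% tpl$rings[[1]], ])
  v <- (oxyz - rctr); v <- v / sqrt(sum(v^2))
  R <- dynsite:::rotation_between(v, -u)
  placed <- sweep(tpl$coords, 2, oxyz) %*% t(R)
  placed <- sweep(placed, 2, site$cuA + 4.0 * u, "+")
  la <- tpl$atoms
  la$x <- placed[, 1]; la$y <- placed[, 2]; la$z <- placed[, 3]
  la$serial <- max(toy$structure$atoms$serial) + seq_len(nrow(la))
  topo <- new_structure(rbind(toy$structure$atoms[, names(la)], la))
  ens1 <- new_ensemble(topo, list(coords(topo)), stride_ns = 1)
  li <- which(topo$atoms$resname == "LTY")
  cb <- classify_bound(ens1, li, site, analysis_stride_ns = 1)
  expect_true(cb$bound)
  expect_equal(cb$values, 4.0, tolerance = 1e-9)
  # validate_pose and classify_bound agree on single-frame ensembles
  vp <- validate_pose(ligand_pose(new_structure(la), -6), site)
  expect_equal(vp$valid, cb$bound)
})

test_that("interaction map: persistence bookkeeping and exclusion", {
  rec_full <- do.call(rbind, lapply(1:20, function(t)
    data.frame(residue = "H367", substrate = "s1", type = "hbond",
               frame_ns = t, distance = 2.9, angle = 170, detail = "",
               stringsAsFactors = FALSE)))
  rec_none <- rec_full[0, ]
  map <- build_interaction_map(list(s1 = rec_full, s2 = rec_none), 20)
  expect_equal(unname(map$persistence$s1["H367"]), 1.0)
  expect_true("H367" %in% map$sets$s1)
  expect_length(map$sets$s2, 0)
  # force-include of coordinating histidines
  map2 <- build_interaction_map(list(s1 = rec_full, s2 = rec_none), 20,
                                force_include = c("H211", "H390"))
  expect_true(all(c("H211", "H390") %in% map2$sets$s2))
})

test_that("curated interaction sets reproduce the published set algebra", {
  full <- interaction_map_from_sets(tyr_substrate_sets("full"))
  cls <- classify_universal_specific(full)
  expect_length(cls$union, 23)
  expect_setequal(cls$universal, c("F347", "H367", "S375"))
  expect_setequal(cls$specific$DHICA, "R196")
  expect_setequal(cls$specific$`L-tyrosine`, c("H180", "G379"))
  expect_setequal(cls$specific$`L-DOPA`, c("A357", "H363"))
  expect_setequal(cls$specific$DHI, c("I368", "N364"))
  t1 <- interaction_map_from_sets(tyr_substrate_sets("table1"))
  cls1 <- classify_universal_specific(t1)
  expect_setequal(cls1$universal, c("F347", "H367", "S375"))
})

test_that("universal/specific/shared partition the union exactly", {
  sets <- list(a = c("R1", "R2", "R3", "R5"), b = c("R1", "R2", "R4"),
               c = c("R1", "R3", "R4", "R6"))
  cls <- classify_universal_specific(interaction_map_from_sets(sets))
  parts <- c(cls$universal, unlist(cls$specific), unlist(cls$shared))
  expect_setequal(parts, cls$union)
  expect_equal(length(parts), length(cls$union))   # no double counting
  # degenerate: identical sets
  cls2 <- classify_universal_specific(
    interaction_map_from_sets(list(a = c("R1", "R2"), b = c("R1", "R2"))))
  expect_setequal(cls2$universal, c("R1", "R2"))
  expect_true(all(lengths(cls2$specific) == 0))
})

test_that("copper proximity annotation matches a distance oracle", {
  toy <- gen_toy_active_site()
  ann <- copper_proximity_annotation(
    c("H180", "H202", "H211", "H363", "H367", "H390"), toy$site,
    toy$structure)
  expect_true(all(ann$assignment[1:3] == "CuA"))
  expect_true(all(ann$assignment[4:6] == "CuB"))
  # brute-force distance comparison
  xyz <- coords(toy$structure)
  keys <- residue_keys(toy$structure)
  res <- residues(toy$structure)
  for (k in seq_len(nrow(ann))) {
    key <- res$key[res$label == ann$residue[k]]
    idx <- which(keys == key)
    dA <- min(sqrt(rowSums(sweep(xyz[idx, , drop = FALSE], 2,
                                 toy$site$cuA)^2)))
    dB <- min(sqrt(rowSums(sweep(xyz[idx, , drop = FALSE], 2,
                                 toy$site$cuB)^2)))
    expect_equal(ann$d_cuA[k], dA, tolerance = 1e-9)
    expect_equal(ann$d_cuB[k], dB, tolerance = 1e-9)
  }
  # equidistant residue -> "both"; unknown residue -> unassigned
  mid <- new_structure(atom_row(1, "CA", "C", "GLY", 99, "A",
                                1.75, 5, 0))
  comb <- new_structure(rbind(toy$structure$atoms,
                              transform(mid$atoms, serial = 999)))
  ann2 <- copper_proximity_annotation("G99", toy$site, comb)
  expect_equal(ann2$assignment, "both")
  ann3 <- copper_proximity_annotation("Z1", toy$site, toy$structure)
  expect_equal(ann3$assignment, "unassigned")
})

test_that("detection operators are invariant under rigid transforms", {
  fx <- pi_fixture(3.8, 0)
  set.seed(17)
  tr <- random_rigid_transform()
  moved <- set_coords(fx$frame, apply_rigid(coords(fx$frame), tr))
  r1 <- detect_pi_stacking(fx$frame, fx$ligand_idx)
  r2 <- detect_pi_stacking(moved, fx$ligand_idx)
  expect_equal(r1$residue, r2$residue)
  expect_equal(r1$distance, r2$distance, tolerance = 1e-9)
  hb <- hbond_fixture(2.9)
  movedh <- set_coords(hb$frame, apply_rigid(coords(hb$frame), tr))
  expect_equal(detect_hbonds(movedh, hb$ligand_idx)$distance, 2.9,
               tolerance = 1e-9)
})
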