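# Ligand-protein interaction detection, docking-pose triage, bound-state
# classification over ensembles, and interaction-set algebra.
#
# Ligand chemistry (aromatic rings, hydroxyl/carbonyl oxygens, donors and
# acceptors) comes from embedded templates for the four melanogenic
# substrates; no general-purpose chemical perception is attempted.

# planar hexagon/pentagon coordinate helpers (bond length b, xy-plane)
hexagon_xy <- function(b = 1.39) {
  r <- b
  th <- (0:5) * pi / 3
  cbind(r * cos(th), r * sin(th), 0)
}

#' Embedded ligand template
#'
#' Idealised planar coordinates and chemical annotations for the four
#' melanogenic substrates: L-tyrosine (`"LTY"`), L-DOPA (`"LDO"`), DHICA
#' (`"DHC"`), DHI (`"DHI"`).
#'
#' @param code template code.
#' @return list with `code`, `atoms` (atom table), `coords`, `rings`
#'   (list of atom-name vectors), `qualifying_oxygens` (hydroxyl/carbonyl
#'   oxygens), `donors`, `acceptors`.
#' @export
ligand_template <- function(code = c("LTY", "LDO", "DHC", "DHI")) {
  code <- match.arg(code)
  hx <- hexagon_xy()
  # ring: CG at vertex 1, then CD1/CE1/CZ/CE2/CD2 around
  ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  mk <- function(names, coords, rings, qox, donors, acceptors) {
    atoms <- data.frame(
      serial = seq_along(names), name = names,
      element = vapply(names, element_of, character(1)),
      resname = code, resseq = 601L, icode = "", chain = "L",
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      hetero = TRUE, stringsAsFactors = FALSE)
    list(code = code, atoms = atoms, coords = coords, rings = rings,
         qualifying_oxygens = qox, donors = donors, acceptors = acceptors)
  }
  sub_out <- function(p_from, p_ctr, bond) {
    d <- p_from - p_ctr
    p_from + bond * d / sqrt(sum(d^2))
  }
  ctr <- c(0, 0, 0)
  if (code %in% c("LTY", "LDO")) {
    co <- hx
    rownames(co) <- ring_names
    oh <- sub_out(co["CZ", ], ctr, 1.36)             # para hydroxyl
    cb <- sub_out(co["CG", ], ctr, 1.51)             # side chain off CG
    ca <- cb + c(0.8, 1.3, 0)
    nn <- ca + c(1.2, 0.8, 0)
    cc <- ca + c(0.5, -1.4, 0.3)
    o1 <- cc + c(1.1, -0.6, 0)
    o2 <- cc + c(-0.6, -1.1, 0)
    names_ <- c(ring_names, "OH", "CB", "CA", "N", "C", "O", "OXT")
    coords_ <- rbind(co, oh, cb, ca, nn, cc, o1, o2)
    if (code == "LTY") {
      return(mk(names_, coords_, list(ring_names), "OH",
                donors = c("OH", "N"), acceptors = c("OH", "O", "OXT")))
    }
    oh2 <- sub_out(co["CE2", ], ctr, 1.36)           # meta hydroxyl (catechol)
    return(mk(c(names_, "OH2"), rbind(coords_, oh2), list(ring_names),
              c("OH", "OH2"), donors = c("OH", "OH2", "N"),
              acceptors = c("OH", "OH2", "O", "OXT")))
  }
  # 5,6-dihydroxyindole scaffold: benzene ring fused to pyrrole
  benz_names <- c("C3A", "C4", "C5", "C6", "C7", "C7A")
  co <- hx
  rownames(co) <- benz_names
  pyr <- regular_polygon_on_edge(co["C7A", ], co["C3A", ], 5, ctr)
  pyr_names <- c("N1", "C2", "C3")                   # C7A-N1-C2-C3-C3A
  o5 <- sub_out(co["C5", ], ctr, 1.36)
  o6 <- sub_out(co["C6", ], ctr, 1.36)
  names_ <- c(benz_names, pyr_names, "O5", "O6")
  coords_ <- rbind(co, pyr, o5, o6)
  rings <- list(benz_names, c("C7A", "N1", "C2", "C3", "C3A"))
  if (code == "DHI") {
    return(mk(names_, coords_, rings, c("O5", "O6"),
              donors = c("O5", "O6", "N1"), acceptors = c("O5", "O6")))
  }
  # DHICA: carboxylate on C2
  pyr_ctr <- colMeans(rbind(co["C7A", ], co["C3A", ], pyr))
  c2 <- pyr[2, ]
  cx <- sub_out(c2, pyr_ctr, 1.50)
  dd <- (cx - c2) / sqrt(sum((cx - c2)^2))
  perp <- c(-dd[2], dd[1], 0)
  ox1 <- cx + 1.25 * (0.5 * dd + 0.866 * perp)
  ox2 <- cx + 1.25 * (0.5 * dd - 0.866 * perp)
  mk(c(names_, "CX", "OX1", "OX2"), rbind(coords_, cx, ox1, ox2), rings,
     c("O5", "O6", "OX1", "OX2"),
     donors = c("O5", "O6", "N1", "OX2"),
     acceptors = c("O5", "O6", "OX1", "OX2"))
}

#' Ligand template as a Structure
#' @param code template code (see [ligand_template()]).
#' @return a `Structure` holding the ligand's idealised coordinates.
#' @export
ligand_structure <- function(code) {
  tpl <- ligand_template(code)
  new_structure(tpl$atoms, metadata = list(template = tpl$code))
}

# protein donor/acceptor typing by (resname, atom name); backbone N donates
# (except proline), backbone O accepts, side chains per standard chemistry
PROTEIN_DONORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2", GLN = "NE2",
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"),
  TRP = "NE1", CYS = "SG")
PROTEIN_ACCEPTORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "OD1", GLN = "OE1",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"),
  MET = "SD")

protein_polar_atoms <- function(structure, role = c("donor", "acceptor")) {
  role <- match.arg(role)
  a <- structure$atoms
  std <- toupper(a$resname) %in% names(AA3TO1) & !a$hetero
  tbl <- if (role == "donor") PROTEIN_DONORS else PROTEIN_ACCEPTORS
  side <- vapply(seq_len(nrow(a)), function(i) {
    nm <- tbl[[toupper(a$resname[i])]]
    !is.null(nm) && toupper(a$name[i]) %in% nm
  }, logical(1))
  bb <- if (role == "donor")
    toupper(a$name) == "N" & toupper(a$resname) != "PRO"
  else toupper(a$name) %in% c("O", "OXT")
  which(std & (side | bb))
}

ligand_polar_atoms <- function(structure, ligand_idx,
                               role = c("donor", "acceptor")) {
  role <- match.arg(role)
  a <- structure$atoms[ligand_idx, , drop = FALSE]
  code <- unique(toupper(a$resname))[1]
  tpl <- tryCatch(ligand_template(code), error = function(e) NULL)
  if (!is.null(tpl)) {
    nm <- if (role == "donor") tpl$donors else tpl$acceptors
    return(ligand_idx[toupper(a$name) %in% nm])
  }
  # element heuristic fallback for unknown ligands
  el <- toupper(a$element)
  if (role == "donor") ligand_idx[el %in% c("N", "O")]
  else ligand_idx[el == "O"]
}

# explicit H attached to a donor (within 1.3 A), else inferred backbone
# amide H, else NULL (distance-only criterion applies)
donor_hydrogen <- function(structure, donor_idx, xyz) {
  a <- structure$atoms
  hs <- which(toupper(a$element) == "H")
  if (length(hs) > 0) {
    d <- sqrt(rowSums(sweep(xyz[hs, , drop = FALSE], 2,
                            xyz[donor_idx, ])^2))
    if (any(d < 1.3)) return(xyz[hs[which.min(d)], ])
  }
  if (toupper(a$name[donor_idx]) == "N" && !a$hetero[donor_idx]) {
    bb <- backbone_table(structure)
    keys <- residue_keys(structure)
    ri <- match(keys[donor_idx], vapply(bb, `[[`, character(1), "key"))
    if (!is.na(ri)) return(infer_amide_h(bb, ri))
  }
  NULL
}

new_record <- function(residue, substrate, type, frame_ns, distance,
                       angle = NA_real_, detail = "") {
  data.frame(residue = residue, substrate = substrate, type = type,
             frame_ns = frame_ns, distance = distance, angle = angle,
             detail = detail, stringsAsFactors = FALSE)
}

empty_records <- function() {
  data.frame(residue = character(0), substrate = character(0),
             type = character(0), frame_ns = numeric(0),
             distance = numeric(0), angle = numeric(0),
             detail = character(0), stringsAsFactors = FALSE)
}

#' Detect protein-ligand hydrogen bonds in one frame
#'
#' Geometric criterion with relaxed constraints: a bond is reported when the
#' donor-acceptor distance is at most `base_distance + distance_tolerance`
#' and the donor-H-acceptor angle at least `base_angle - angle_tolerance`
#' (boundaries inclusive). Defaults implement a 3.0 Angstrom / 140 degree
#' baseline relaxed by 0.4 Angstrom / 20 degrees. When no donor hydrogen is
#' present or inferable, the distance criterion alone applies.
#'
#' @param frame a `Structure` containing protein and ligand.
#' @param ligand_idx atom indices of the ligand.
#' @param distance_tolerance Angstrom added to the base distance.
#' @param angle_tolerance degrees subtracted from the base angle.
#' @param base_distance,base_angle baseline criteria.
#' @param substrate substrate name recorded on each hit.
#' @param frame_ns frame time recorded on each hit.
#' @return data.frame of interaction records (possibly empty).
#' @export
detect_hbonds <- function(frame, ligand_idx, distance_tolerance = 0.4,
                          angle_tolerance = 20, base_distance = 3.0,
                          base_angle = 140, substrate = "ligand",
                          frame_ns = NA_real_) {
  xyz <- coords(frame)
  keys <- residue_keys(frame)
  res <- residues(frame)
  dmax <- base_distance + distance_tolerance
  amin <- base_angle - angle_tolerance
  out <- list()
  pairs <- rbind(
    expand.grid(D = protein_polar_atoms(frame, "donor"),
                A = ligand_polar_atoms(frame, ligand_idx, "acceptor")),
    expand.grid(D = ligand_polar_atoms(frame, ligand_idx, "donor"),
                A = protein_polar_atoms(frame, "acceptor")))
  if (nrow(pairs) == 0) return(empty_records())
  for (p in seq_len(nrow(pairs))) {
    D <- pairs$D[p]; A <- pairs$A[p]
    d <- sqrt(sum((xyz[D, ] - xyz[A, ])^2))
    if (d > dmax) next
    H <- donor_hydrogen(frame, D, xyz)
    ang <- NA_real_
    if (!is.null(H)) {
      v1 <- xyz[D, ] - H; v2 <- xyz[A, ] - H
      ang <- acos(pmin(pmax(sum(v1 * v2) /
        sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) * 180 / pi
      if (ang < amin) next
    }
    prot <- if (D %in% ligand_idx) A else D
    lab <- res$label[match(keys[prot], res$key)]
    out[[length(out) + 1]] <- new_record(lab, substrate, "hbond",
                                         frame_ns, d, ang)
  }
  if (length(out) == 0) return(empty_records())
  do.call(rbind, out)
}

#' Detect nonbonded hydrophobic contacts in one frame
#'
#' Apolar-apolar (carbon/sulfur) atom pairs within the cutoff (inclusive);
#' each protein residue hosting a qualifying pair is reported once per
#' frame with its minimum contact distance.
#'
#' @inheritParams detect_hbonds
#' @param cutoff distance cutoff (Angstrom).
#' @return data.frame of `hydrophobic` interaction records.
#' @export
detect_nonbonded_contacts <- function(frame, ligand_idx, cutoff = 5.0,
                                      substrate = "ligand",
                                      frame_ns = NA_real_) {
  a <- frame$atoms
  xyz <- coords(frame)
  apolar <- toupper(a$element) %in% c("C", "S")
  lig_ap <- intersect(ligand_idx, which(apolar))
  prot_ap <- setdiff(which(apolar & !a$hetero), ligand_idx)
  if (length(lig_ap) == 0 || length(prot_ap) == 0) return(empty_records())
  keys <- residue_keys(frame)
  res <- residues(frame)
  out <- list()
  for (key in unique(keys[prot_ap])) {
    ridx <- prot_ap[keys[prot_ap] == key]
    dmin <- min(vapply(ridx, function(i)
      min(sqrt(rowSums(sweep(xyz[lig_ap, , drop = FALSE], 2,
                             xyz[i, ])^2))), numeric(1)))
    if (dmin <= cutoff) {
      lab <- res$label[match(key, res$key)]
      out[[length(out) + 1]] <- new_record(lab, substrate, "hydrophobic",
                                           frame_ns, dmin)
    }
  }
  if (length(out) == 0) return(empty_records())
  do.call(rbind, out)
}

AROMATIC_RINGS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "CD2", "NE1", "CE2"),
             c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")))

ring_geometry <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  list(centroid = ctr, normal = sv$v[, 3])
}

#' Detect pi-stacking between ligand rings and aromatic residues
#'
#' A stacking record is emitted when ring centroids are within 5.0 Angstrom
#' and the inter-plane angle is at most 30 degrees (`parallel`) or between
#' 60 and 90 degrees (`t_shaped`; plane angles are folded to [0, 90]).
#'
#' @inheritParams detect_hbonds
#' @param centroid_max centroid distance cutoff (Angstrom).
#' @return data.frame of `pi_stacking` records with the geometry class in
#'   `detail`.
#' @export
detect_pi_stacking <- function(frame, ligand_idx, centroid_max = 5.0,
                               substrate = "ligand", frame_ns = NA_real_) {
  a <- frame$atoms
  xyz <- coords(frame)
  keys <- residue_keys(frame)
  res <- residues(frame)
  lig <- a[ligand_idx, , drop = FALSE]
  code <- unique(toupper(lig$resname))[1]
  tpl <- tryCatch(ligand_template(code), error = function(e) NULL)
  lig_rings <- if (!is.null(tpl)) tpl$rings else list()
  lig_geoms <- lapply(lig_rings, function(rn) {
    idx <- ligand_idx[match(rn, toupper(lig$name))]
    if (any(is.na(idx))) return(NULL)
    ring_geometry(xyz[idx, , drop = FALSE])
  })
  lig_geoms <- Filter(Negate(is.null), lig_geoms)
  if (length(lig_geoms) == 0) return(empty_records())
  out <- list()
  arom <- res[toupper(res$resname) %in% names(AROMATIC_RINGS), , drop = FALSE]
  for (r in seq_len(nrow(arom))) {
    for (rn in AROMATIC_RINGS[[toupper(arom$resname[r])]]) {
      idx <- which(keys == arom$key[r] & toupper(a$name) %in% rn)
      if (length(idx) < length(rn)) {
        warning(sprintf("residue %s lacks ring atoms; skipped",
                        arom$label[r]))
        next
      }
      pg <- ring_geometry(xyz[idx, , drop = FALSE])
      for (lg in lig_geoms) {
        d <- sqrt(sum((pg$centroid - lg$centroid)^2))
        if (d > centroid_max) next
        cosang <- abs(sum(pg$normal * lg$normal))
        ang <- acos(pmin(pmax(cosang, 0), 1)) * 180 / pi   # folded to [0,90]
        cls <- if (ang <= 30) "parallel"
               else if (ang >= 60) "t_shaped" else NA_character_
        if (is.na(cls)) next
        out[[length(out) + 1]] <- new_record(arom$label[r], substrate,
                                             "pi_stacking", frame_ns, d,
                                             ang, cls)
      }
    }
  }
  if (length(out) == 0) return(empty_records())
  do.call(rbind, out)
}

#' Detect all interaction types for one frame
#'
#' Convenience wrapper running hydrogen-bond, hydrophobic and pi-stacking
#' detection with the package defaults.
#'
#' @inheritParams detect_hbonds
#' @param contact_cutoff hydrophobic cutoff (Angstrom).
#' @return combined record data.frame.
#' @export
detect_interactions <- function(frame, ligand_idx, substrate = "ligand",
                                frame_ns = NA_real_, contact_cutoff = 5.0) {
  rbind(detect_hbonds(frame, ligand_idx, substrate = substrate,
                      frame_ns = frame_ns),
        detect_nonbonded_contacts(frame, ligand_idx, cutoff = contact_cutoff,
                                  substrate = substrate, frame_ns = frame_ns),
        detect_pi_stacking(frame, ligand_idx, substrate = substrate,
                           frame_ns = frame_ns))
}

# ---- docking poses ----------------------------------------------------------

#' Construct a ligand pose
#' @param structure `Structure` holding the ligand atoms (receptor-frame
#'   coordinates).
#' @param binding_energy docking binding energy (kcal/mol; consumed, not
#'   computed).
#' @param id pose identifier.
#' @param template ligand template code (optional; inferred from the
#'   residue name when possible).
#' @return object of class `LigandPose`.
#' @export
ligand_pose <- function(structure, binding_energy, id = NA,
                        template = NULL) {
  if (!is.finite(binding_energy))
    ds_stop("binding energy must be finite", "dynsite_validation_error")
  if (is.null(template))
    template <- unique(toupper(structure$atoms$resname))[1]
  structure(list(structure = structure, binding_energy = binding_energy,
                 id = id, template = template, cluster = NA_integer_),
            class = "LigandPose")
}

pose_qualifying_oxygens <- function(pose) {
  tpl <- tryCatch(ligand_template(pose$template), error = function(e) NULL)
  a <- pose$structure$atoms
  if (!is.null(tpl)) {
    idx <- which(toupper(a$name) %in% tpl$qualifying_oxygens)
  } else {
    idx <- which(toupper(a$element) == "O")
  }
  idx
}

pose_ring_centroid <- function(pose) {
  tpl <- tryCatch(ligand_template(pose$template), error = function(e) NULL)
  a <- pose$structure$atoms
  xyz <- coords(pose$structure)
  if (!is.null(tpl)) {
    idx <- which(toupper(a$name) %in% tpl$rings[[1]])
    if (length(idx) >= 3) return(colMeans(xyz[idx, , drop = FALSE]))
  }
  colMeans(xyz[toupper(a$element) == "C", , drop = FALSE])
}

#' Validate a docked pose against the dicopper site
#'
#' A pose is valid iff (a) some hydroxyl/carbonyl oxygen lies within
#' `max_o_cu` (inclusive) of CuA or CuB, and (b) that oxygen points toward
#' the site: the ring-centroid-to-oxygen vector has positive projection
#' onto the centroid-to-copper-midpoint vector.
#'
#' @param pose a [ligand_pose()].
#' @param site a `CopperSite`.
#' @param max_o_cu O-Cu distance cutoff (Angstrom).
#' @return list with `valid` (logical) and `reason` (`"ok"`,
#'   `"no_candidate_oxygen"`, `"distance"`, or `"orientation"`).
#' @export
validate_pose <- function(pose, site, max_o_cu = 4.0) {
  qidx <- pose_qualifying_oxygens(pose)
  if (length(qidx) == 0)
    return(list(valid = FALSE, reason = "no_candidate_oxygen"))
  xyz <- coords(pose$structure)
  dcu <- vapply(qidx, function(i)
    min(sqrt(sum((xyz[i, ] - site$cuA)^2)),
        sqrt(sum((xyz[i, ] - site$cuB)^2))), numeric(1))
  if (min(dcu) > max_o_cu) return(list(valid = FALSE, reason = "distance"))
  best <- qidx[which.min(dcu)]
  ctr <- pose_ring_centroid(pose)
  v_ox <- xyz[best, ] - ctr
  v_cu <- cu_midpoint(site) - ctr
  if (sum(v_ox * v_cu) <= 0)
    return(list(valid = FALSE, reason = "orientation"))
  list(valid = TRUE, reason = "ok")
}

pose_rmsd <- function(p1, p2) {
  a1 <- p1$structure; a2 <- p2$structure
  if (n_atoms(a1) != n_atoms(a2) ||
      !identical(toupper(a1$atoms$name), toupper(a2$atoms$name)))
    ds_stop("poses differ in ligand atom ordering",
            "dynsite_congruence_error")
  heavy <- select_atoms(a1, selection_spec(atoms = "heavy"))
  sqrt(mean(rowSums((coords(a1)[heavy, , drop = FALSE] -
                       coords(a2)[heavy, , drop = FALSE])^2)))
}

#' Greedy energy-ranked pose clustering
#'
#' The best-energy unassigned pose seeds a cluster; unassigned poses with
#' heavy-atom RMSD below the threshold (no re-superposition; the receptor
#' frame is common) join it; repeat. Poses at or above the threshold from
#' every seed start new clusters.
#'
#' @param poses list of [ligand_pose()] objects sharing atom ordering.
#' @param rmsd_threshold clustering threshold (Angstrom); poses differing
#'   by at least this much seed distinct clusters.
#' @return the input poses with `cluster` ids assigned (seed-first order),
#'   plus a `clusters` attribute listing member indices per cluster.
#' @export
cluster_poses <- function(poses, rmsd_threshold = 5.0) {
  energies <- vapply(poses, `[[`, numeric(1), "binding_energy")
  order_e <- order(energies)
  assigned <- rep(NA_integer_, length(poses))
  members <- list()
  cl <- 0L
  for (i in order_e) {
    if (!is.na(assigned[i])) next
    cl <- cl + 1L
    assigned[i] <- cl
    members[[cl]] <- i
    for (j in order_e) {
      if (!is.na(assigned[j])) next
      if (pose_rmsd(poses[[i]], poses[[j]]) < rmsd_threshold) {
        assigned[j] <- cl
        members[[cl]] <- c(members[[cl]], j)
      }
    }
  }
  for (k in seq_along(poses)) poses[[k]]$cluster <- assigned[k]
  attr(poses, "clusters") <- members
  poses
}

#' Classify a ligand trajectory as bound or unbound
#'
#' Bound iff the criterion holds at every analysis frame. The default
#' criterion is the minimum qualifying-oxygen-to-copper distance at most
#' `max_dev` (inclusive); the alternative `positional_deviation` criterion
#' instead bounds the displacement of the ligand centroid from its
#' topology position.
#'
#' @param ensemble an `Ensemble` containing the ligand.
#' @param ligand_idx atom indices of the ligand within the topology.
#' @param site a `CopperSite`.
#' @param analysis_stride_ns analysis tick spacing (ns).
#' @param max_dev distance bound (Angstrom).
#' @param criterion `"ocu_distance"` (default) or `"positional_deviation"`.
#' @param template ligand template code (default from residue name).
#' @return list with `bound`, `per_frame` (logical), `first_fail` (analysis
#'   frame number or `NA`), `values` (the per-frame criterion values),
#'   `times_ns`, `criterion`.
#' @export
classify_bound <- function(ensemble, ligand_idx, site,
                           analysis_stride_ns = 1.0, max_dev = 4.0,
                           criterion = c("ocu_distance",
                                         "positional_deviation"),
                           template = NULL) {
  criterion <- match.arg(criterion)
  fidx <- analysis_frames(ensemble, analysis_stride_ns)
  a <- ensemble$topology$atoms[ligand_idx, , drop = FALSE]
  if (is.null(template)) template <- unique(toupper(a$resname))[1]
  tpl <- tryCatch(ligand_template(template), error = function(e) NULL)
  qnames <- if (!is.null(tpl)) tpl$qualifying_oxygens else
    a$name[toupper(a$element) == "O"]
  qidx <- ligand_idx[toupper(a$name) %in% toupper(qnames)]
  ref_ctr <- colMeans(coords(ensemble$topology)[ligand_idx, , drop = FALSE])
  vals <- vapply(fidx, function(f) {
    xyz <- ensemble$frames[[f]]
    if (criterion == "ocu_distance") {
      min(vapply(qidx, function(i)
        min(sqrt(sum((xyz[i, ] - site$cuA)^2)),
            sqrt(sum((xyz[i, ] - site$cuB)^2))), numeric(1)))
    } else {
      ctr <- colMeans(xyz[ligand_idx, , drop = FALSE])
      sqrt(sum((ctr - ref_ctr)^2))
    }
  }, numeric(1))
  ok <- vals <= max_dev
  list(bound = all(ok), per_frame = ok,
       first_fail = if (all(ok)) NA_integer_ else which(!ok)[1],
       values = vals, times_ns = ensemble$times_ns[fidx],
       criterion = criterion)
}

# ---- interaction-set algebra ------------------------------------------------

#' Build an interaction map from per-substrate records
#'
#' A residue enters a substrate's set when it has qualifying records in
#' more than `min_persistence` of that substrate's analysis frames;
#' persistence fractions are always recorded. Copper-coordinating
#' histidines (or any residues) can be force-included via `force_include`.
#'
#' @param records_by_substrate named list of record data.frames (as
#'   produced by the detect_* operations), one per substrate.
#' @param n_analysis_frames analysis frame count per substrate (single
#'   number or named vector), the persistence denominator.
#' @param min_persistence inclusion threshold (fraction of frames).
#' @param force_include residue labels force-included in every substrate's
#'   set (flagged in the persistence tables).
#' @return object of class `InteractionMap`: list with `substrates`,
#'   `sets`, `persistence`, `params`.
#' @export
build_interaction_map <- function(records_by_substrate, n_analysis_frames,
                                  min_persistence = 0,
                                  force_include = NULL) {
  subs <- names(records_by_substrate)
  if (length(subs) < 1)
    ds_stop("need at least one substrate", "dynsite_validation_error")
  nf <- if (length(n_analysis_frames) == 1)
    setNames(rep(n_analysis_frames, length(subs)), subs)
  else n_analysis_frames[subs]
  sets <- list(); persis <- list()
  for (s in subs) {
    rec <- records_by_substrate[[s]]
    if (nrow(rec) == 0) {
      pv <- numeric(0)
    } else {
      pv <- vapply(split(rec$frame_ns, rec$residue),
                   function(fr) length(unique(fr)) / nf[s], numeric(1))
    }
    keep <- names(pv)[pv > min_persistence]
    forced <- setdiff(force_include, keep)
    sets[[s]] <- c(keep, forced)
    pv_all <- c(pv, setNames(rep(0, length(setdiff(forced, names(pv)))),
                             setdiff(forced, names(pv))))
    attr(pv_all, "forced") <- forced
    persis[[s]] <- pv_all
  }
  structure(list(substrates = subs, sets = sets, persistence = persis,
                 params = list(min_persistence = min_persistence,
                               n_analysis_frames = nf,
                               force_include = force_include)),
            class = "InteractionMap")
}

#' Build an InteractionMap directly from residue sets
#'
#' For transcribed or externally supplied per-substrate residue lists
#' (persistence set to 1 for every member).
#'
#' @param sets named list of residue-label vectors.
#' @return an `InteractionMap`.
#' @export
interaction_map_from_sets <- function(sets) {
  structure(list(substrates = names(sets),
                 sets = lapply(sets, unique),
                 persistence = lapply(sets, function(s)
                   setNames(rep(1, length(unique(s))), unique(s))),
                 params = list(min_persistence = 0,
                               n_analysis_frames = NA,
                               force_include = NULL)),
            class = "InteractionMap")
}

#' Universal / substrate-specific classification of an interaction map
#'
#' Universal residues are engaged by all substrates; specific residues by
#' exactly one; the remainder are reported with their substrate-combination
#' signature. The three classes partition the union of the map's sets.
#'
#' @param map an `InteractionMap` with at least 2 substrates.
#' @return list with `universal`, `specific` (named list per substrate),
#'   `shared` (named list keyed by substrate-combination signature), and
#'   `union`.
#' @export
classify_universal_specific <- function(map) {
  if (length(map$substrates) < 2)
    ds_stop("classification needs at least 2 substrates",
            "dynsite_validation_error")
  uni_all <- sort(unique(unlist(map$sets)))
  membership <- vapply(uni_all, function(r)
    paste(sort(map$substrates[vapply(map$sets, function(s) r %in% s,
                                     logical(1))]), collapse = "+"),
    character(1))
  counts <- vapply(uni_all, function(r)
    sum(vapply(map$sets, function(s) r %in% s, logical(1))), numeric(1))
  universal <- uni_all[counts == length(map$substrates)]
  specific <- lapply(setNames(map$substrates, map$substrates), function(s)
    uni_all[counts == 1 & membership == s])
  shared_idx <- counts > 1 & counts < length(map$substrates)
  shared <- split(uni_all[shared_idx], membership[shared_idx])
  list(universal = universal, specific = specific, shared = shared,
       union = uni_all)
}

#' Annotate mapped residues by nearest copper
#'
#' Each residue is labelled by the copper with the smaller minimum
#' heavy-atom distance; `"both"` when the two distances differ by at most
#' 1 Angstrom; `"unassigned"` when the residue has no coordinates in the
#' structure.
#'
#' @param residue_labels residue labels to annotate (e.g. the union of an
#'   `InteractionMap`'s sets).
#' @param site a `CopperSite`.
#' @param structure a `Structure` resolving the residues.
#' @param both_margin distance-difference margin for `"both"` (Angstrom).
#' @return data.frame with `residue`, `assignment`, `d_cuA`, `d_cuB`.
#' @export
copper_proximity_annotation <- function(residue_labels, site, structure,
                                        both_margin = 1.0) {
  if (inherits(residue_labels, "InteractionMap"))
    residue_labels <- sort(unique(unlist(residue_labels$sets)))
  res <- residues(structure)
  keys <- residue_keys(structure)
  xyz <- coords(structure)
  heavy <- toupper(structure$atoms$element) != "H"
  out <- lapply(residue_labels, function(r) {
    key <- res$key[res$label == r]
    if (length(key) == 0)
      return(data.frame(residue = r, assignment = "unassigned",
                        d_cuA = NA_real_, d_cuB = NA_real_,
                        stringsAsFactors = FALSE))
    idx <- which(keys == key[1] & heavy)
    dA <- min(sqrt(rowSums(sweep(xyz[idx, , drop = FALSE], 2, site$cuA)^2)))
    dB <- min(sqrt(rowSums(sweep(xyz[idx, , drop = FALSE], 2, site$cuB)^2)))
    lab <- if (abs(dA - dB) <= both_margin) "both"
           else if (dA < dB) "CuA" else "CuB"
    data.frame(residue = r, assignment = lab, d_cuA = dA, d_cuB = dB,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write interaction records as long-format TSV
#' @param records record data.frame.
#' @param path output path.
#' @param params optional named list recorded as header comments.
#' @return `path`, invisibly.
#' @export
write_interaction_records <- function(records, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(params) > 0)
    writeLines(sprintf("# %s = %s", names(params),
                       vapply(params, function(p)
                         paste(format(p), collapse = ","), character(1))),
               con)
  write.table(records, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
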