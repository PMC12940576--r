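# Per-residue structural/dynamic descriptors over conformational ensembles.
#
# All metrics are computed after global Calpha superposition, so they are
# invariant under rigid transforms applied to any frame. Analysis-frame
# sampling follows the 1 ns-tick convention: the saved frame nearest each
# tick is analysed, ties resolved toward the earlier frame.

#' Indices of analysis frames at a fixed tick spacing
#'
#' Ticks are placed at `stride_ns, 2*stride_ns, ...` up to the last frame
#' time; each tick maps to the nearest saved frame (ties toward the earlier
#' frame). A 20 ns ensemble saved every 0.25 ns analysed at 1 ns yields
#' exactly 20 analysis frames.
#'
#' @param ensemble an `Ensemble`.
#' @param analysis_stride_ns tick spacing in ns.
#' @return integer frame indices (one per tick, possibly repeating).
#' @export
analysis_frames <- function(ensemble, analysis_stride_ns = 1.0) {
  tmax <- max(ensemble$times_ns)
  if (analysis_stride_ns > tmax + 1e-9)
    ds_stop("analysis stride exceeds trajectory span",
            "dynsite_empty_analysis_error")
  ticks <- seq(analysis_stride_ns, tmax + 1e-9, by = analysis_stride_ns)
  vapply(ticks, function(tk) {
    d <- abs(ensemble$times_ns - tk)
    which(d <= min(d) + 1e-12)[1]          # tie -> earlier frame
  }, integer(1))
}

resolve_fit_indices <- function(structure, fit_selection) {
  if (is.null(fit_selection)) return(ca_fit_indices(structure))
  if (inherits(fit_selection, "SelectionSpec"))
    return(select_atoms(structure, fit_selection))
  as.integer(fit_selection)
}

ca_fit_indices <- function(structure) {
  idx <- select_atoms(structure, selection_spec(atoms = "CA", hetero = FALSE))
  if (length(idx) >= 3) return(idx)
  select_atoms(structure, selection_spec(atoms = "heavy"))
}

superpose_frames <- function(ensemble, fit_indices = NULL,
                             frame_idx = seq_len(n_frames(ensemble))) {
  ref <- coords(ensemble$topology)
  if (is.null(fit_indices)) fit_indices <- ca_fit_indices(ensemble$topology)
  lapply(frame_idx, function(i) {
    kabsch_superpose(ensemble$frames[[i]], ref, fit_indices)$coords
  })
}

#' Per-residue RMSD over an ensemble
#'
#' For each analysis frame the whole system is superposed on the reference
#' using Calpha atoms, then each residue's heavy-atom RMSD to the reference
#' is computed. Reported as a per-interval series and its time average.
#'
#' @param ensemble an `Ensemble`.
#' @param reference reference `Structure` congruent with the topology
#'   (default: the topology itself).
#' @param analysis_stride_ns analysis tick spacing (ns).
#' @return list with `per_interval` (residues x intervals matrix, Angstrom),
#'   `mean` (named per-residue vector), `times_ns`, `frame_idx`.
#' @export
per_residue_rmsd <- function(ensemble, reference = ensemble$topology,
                             analysis_stride_ns = 1.0) {
  if (n_atoms(reference) != n_atoms(ensemble$topology))
    ds_stop("reference not congruent with ensemble topology",
            "dynsite_congruence_error")
  fidx <- analysis_frames(ensemble, analysis_stride_ns)
  refxyz <- coords(reference)
  fit <- ca_fit_indices(reference)
  keys <- residue_keys(ensemble$topology)
  heavy <- select_atoms(ensemble$topology, selection_spec(atoms = "heavy"))
  res_atoms <- split(heavy, keys[heavy])
  res_order <- unique(keys)
  res_order <- res_order[res_order %in% names(res_atoms)]
  out <- matrix(NA_real_, length(res_order), length(fidx),
                dimnames = list(res_order, NULL))
  refstr <- set_coords(ensemble$topology, refxyz)
  for (k in seq_along(fidx)) {
    sup <- kabsch_superpose(ensemble$frames[[fidx[k]]], refxyz, fit)$coords
    for (r in res_order) {
      ai <- res_atoms[[r]]
      out[r, k] <- sqrt(mean(rowSums((sup[ai, , drop = FALSE] -
                                      refxyz[ai, , drop = FALSE])^2)))
    }
  }
  list(per_interval = out, mean = rowMeans(out),
       times_ns = ensemble$times_ns[fidx], frame_idx = fidx)
}

#' Per-residue RMSF
#'
#' Root mean square fluctuation about the time-mean position, computed on
#' Calpha-superposed frames and averaged over each residue's selected atoms:
#' `RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2)`.
#'
#' @param ensemble an `Ensemble` with at least 2 frames.
#' @param selection a [selection_spec()]; default Calpha atoms.
#' @param fit_selection atoms used for the superposition fit (a
#'   [selection_spec()] or atom indices); default all Calpha. Fitting on a
#'   quasi-rigid core avoids aliasing collective motion into the
#'   fluctuations.
#' @return named per-residue vector (Angstrom).
#' @export
per_residue_rmsf <- function(ensemble,
                             selection = selection_spec(atoms = "CA",
                                                        hetero = FALSE),
                             fit_selection = NULL) {
  if (n_frames(ensemble) < 2)
    ds_stop("RMSF undefined for a single frame",
            "dynsite_undefined_fluctuation_error")
  sel <- select_atoms(ensemble$topology, selection)
  if (length(sel) == 0)
    ds_stop("selection matches no atoms", "dynsite_validation_error")
  fit <- resolve_fit_indices(ensemble$topology, fit_selection)
  sup <- superpose_frames(ensemble, fit_indices = fit)
  nf <- length(sup)
  mean_pos <- Reduce(`+`, sup) / nf
  ssd <- Reduce(`+`, lapply(sup, function(f) rowSums((f - mean_pos)^2))) / nf
  atom_rmsf <- sqrt(ssd)
  keys <- residue_keys(ensemble$topology)
  vapply(split(atom_rmsf[sel], factor(keys[sel], levels = unique(keys[sel]))),
         mean, numeric(1))
}

#' Dynamic cross-correlation matrix
#'
#' Normalised covariance of per-residue displacement vectors on superposed
#' frames: `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)` with `dr`
#' the deviation from the time-mean position. Residues with zero variance
#' yield `NA` off-diagonals (undefined correlation, never silently 0); the
#' diagonal is 1 by convention.
#'
#' @param ensemble an `Ensemble` with at least 2 frames.
#' @param selection a [selection_spec()] choosing one atom per residue
#'   (default Calpha).
#' @param superpose superpose frames on the topology first? Default `TRUE`.
#' @param fit_selection atoms used for the superposition fit (a
#'   [selection_spec()] or atom indices); default all Calpha. Fitting on
#'   highly mobile correlated regions aliases their collective motion into
#'   apparent anti-correlation, so a quasi-rigid core is preferable when
#'   one is known.
#' @return object of class `DCCMatrix`: list with `residues` (labels),
#'   `keys`, and `matrix` (symmetric, unit diagonal, entries in [-1, 1]).
#' @export
dccm <- function(ensemble,
                 selection = selection_spec(atoms = "CA", hetero = FALSE),
                 superpose = TRUE, fit_selection = NULL) {
  if (n_frames(ensemble) < 2)
    ds_stop("DCCM undefined for a single frame",
            "dynsite_undefined_fluctuation_error")
  sel <- select_atoms(ensemble$topology, selection)
  if (length(sel) == 0)
    ds_stop("selection matches no atoms", "dynsite_validation_error")
  fit <- resolve_fit_indices(ensemble$topology, fit_selection)
  frames <- if (superpose) superpose_frames(ensemble, fit_indices = fit)
            else ensemble$frames
  nf <- length(frames)
  n <- length(sel)
  # stack selected displacements: nf x (3n)
  X <- t(vapply(frames, function(f) as.vector(t(f[sel, , drop = FALSE])),
                numeric(3 * n)))
  X <- sweep(X, 2, colMeans(X))
  # <dr_i . dr_j> = sum over the 3 coordinate axes of covariances
  ix <- seq(1, 3 * n, by = 3)
  G <- (crossprod(X[, ix]) + crossprod(X[, ix + 1]) +
          crossprod(X[, ix + 2])) / nf
  v <- diag(G)
  denom <- sqrt(outer(v, v))
  C <- G / denom
  C[!is.finite(C)] <- NA_real_
  diag(C) <- 1
  C <- (C + t(C)) / 2
  C[C > 1] <- 1; C[C < -1] <- -1
  keys <- residue_keys(ensemble$topology)[sel]
  res <- residues(ensemble$topology)
  labels <- res$label[match(keys, res$key)]
  dimnames(C) <- list(labels, labels)
  structure(list(residues = labels, keys = keys, matrix = C),
            class = "DCCMatrix")
}

#' Per-residue DCCM coupling score
#'
#' Reduces a DCCM to one scalar per residue: the mean correlation of the
#' residue to a partner set (e.g. the active-site interaction set),
#' excluding self-correlation.
#'
#' @param dccm_matrix a `DCCMatrix`.
#' @param residue residue label present in the matrix.
#' @param partner_set character vector of residue labels (default: all
#'   residues in the matrix).
#' @return scalar mean correlation (NA-aware).
#' @export
dccm_residue_score <- function(dccm_matrix, residue,
                               partner_set = dccm_matrix$residues) {
  C <- dccm_matrix$matrix
  if (!residue %in% rownames(C))
    ds_stop(paste("residue not in matrix:", residue), "dynsite_lookup_error")
  partners <- setdiff(intersect(partner_set, colnames(C)), residue)
  if (length(partners) == 0)
    ds_stop("empty partner set", "dynsite_validation_error")
  mean(C[residue, partners], na.rm = TRUE)
}

# ---- contacts ---------------------------------------------------------------

# covalent exclusion: peptide C-N link between chain-adjacent residues, or
# any inter-residue heavy-atom pair closer than a covalent-bond ceiling
is_peptide_link <- function(atoms, i, j) {
  same_chain <- atoms$chain[i] == atoms$chain[j]
  dr <- atoms$resseq[j] - atoms$resseq[i]
  (same_chain & dr == 1 & atoms$name[i] == "C" & atoms$name[j] == "N") |
    (same_chain & dr == -1 & atoms$name[i] == "N" & atoms$name[j] == "C")
}

#' Heavy-atom contact count of a residue
#'
#' Number of heavy-atom pairs (a, b) with a in the residue, b outside it,
#' within `cutoff` (inclusive), excluding covalently bonded pairs (the
#' peptide link to adjacent residues and any pair below bonding distance).
#'
#' @param structure a `Structure` (one frame).
#' @param residue residue label (e.g. "H367") or key; `NULL` for all
#'   residues.
#' @param cutoff distance cutoff in Angstrom.
#' @param mode `"pairs"` counts qualifying atom pairs; `"partners"` counts
#'   distinct partner residues instead.
#' @param covalent_max inter-residue distances below this are treated as
#'   covalent and excluded.
#' @return named integer vector (all residues) or single integer.
#' @export
contact_counts <- function(structure, residue = NULL, cutoff = 5.0,
                           mode = c("pairs", "partners"),
                           covalent_max = 1.7) {
  mode <- match.arg(mode)
  a <- structure$atoms
  heavy <- select_atoms(structure, selection_spec(atoms = "heavy"))
  keys <- residue_keys(structure)
  res <- residues(structure)
  xyz <- coords(structure)[heavy, , drop = FALSE]
  hk <- keys[heavy]
  d <- as.matrix(stats::dist(xyz))
  qual <- d <= cutoff & outer(hk, hk, "!=")
  # covalent exclusions
  close_cov <- d < covalent_max
  hsub <- a[heavy, , drop = FALSE]
  pep <- outer(seq_along(heavy), seq_along(heavy), function(i, j)
    is_peptide_link(hsub, i, j))
  qual <- qual & !close_cov & !pep
  count_for <- function(key) {
    rows <- which(hk == key)
    if (length(rows) == 0)
      ds_stop(paste("unknown residue:", key), "dynsite_lookup_error")
    sub <- qual[rows, , drop = FALSE]
    if (mode == "pairs") as.numeric(sum(sub))
    else as.numeric(length(unique(hk[which(colSums(sub) > 0)])))
  }
  if (!is.null(residue)) {
    key <- resolve_residue_key(structure, residue)
    return(count_for(key))
  }
  out <- vapply(res$key, count_for, numeric(1))
  names(out) <- res$label
  out
}

resolve_residue_key <- function(structure, residue) {
  res <- residues(structure)
  if (residue %in% res$key) return(residue)
  hit <- res$key[res$label == residue]
  if (length(hit) == 0)
    ds_stop(paste("unknown residue:", residue), "dynsite_lookup_error")
  hit[1]
}

#' Ensemble-averaged contact counts
#' @inheritParams contact_counts
#' @param ensemble an `Ensemble`.
#' @param analysis_stride_ns analysis tick spacing (ns).
#' @return named per-residue numeric vector of mean contact counts.
#' @export
contact_counts_mean <- function(ensemble, cutoff = 5.0,
                                analysis_stride_ns = 1.0,
                                mode = c("pairs", "partners")) {
  mode <- match.arg(mode)
  fidx <- analysis_frames(ensemble, analysis_stride_ns)
  per <- vapply(fidx, function(i) {
    contact_counts(frame_structure(ensemble, i), cutoff = cutoff, mode = mode)
  }, numeric(length(unique(residue_keys(ensemble$topology)))))
  rowMeans(as.matrix(per))
}

# ---- solvent-accessible surface area ---------------------------------------

VDW_RADII <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, CU = 1.4, H = 1.2,
               P = 1.8, FE = 1.4, ZN = 1.39)

# deterministic golden-spiral unit sphere layout
golden_spiral <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Quadrature on a deterministic golden-spiral point layout: each atom's
#' accessible area is the unoccluded fraction of points on a sphere of
#' radius `r_vdw + probe`, times `4*pi*(r_vdw + probe)^2`. Hydrogens are
#' ignored by default (heavy-atom model).
#'
#' @param structure a `Structure`.
#' @param probe_radius probe radius in Angstrom (water: 1.4).
#' @param n_points quadrature points per atom.
#' @param include_h include hydrogen atoms?
#' @return list with `atom_area` (per included atom, named by serial) and
#'   `residue_area` (named by residue label), both in Angstrom^2, plus
#'   `atom_idx` (indices of the included atoms).
#' @export
sasa <- function(structure, probe_radius = 1.4, n_points = 960,
                 include_h = FALSE) {
  sel <- if (include_h) seq_len(n_atoms(structure))
         else select_atoms(structure, selection_spec(atoms = "heavy"))
  a <- structure$atoms[sel, , drop = FALSE]
  el <- toupper(a$element)
  unknown <- setdiff(unique(el), names(VDW_RADII))
  if (length(unknown) > 0)
    ds_stop(paste("no van der Waals radius for element(s):",
                  paste(unknown, collapse = ", ")), "dynsite_radius_error")
  rad <- VDW_RADII[el] + probe_radius
  xyz <- coords(structure)[sel, , drop = FALSE]
  pts <- golden_spiral(n_points)
  n <- length(sel)
  area <- numeric(n)
  for (i in seq_len(n)) {
    sp <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    dij <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(dij < rad + rad[i] & seq_len(n) != i)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      free <- free & (rowSums(sweep(sp, 2, xyz[j, ])^2) > rad[j]^2)
      if (!any(free)) break
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(free) / n_points
  }
  keys <- residue_keys(structure)[sel]
  res <- residues(structure)
  res_area <- vapply(split(area, factor(keys, levels = unique(keys))),
                     sum, numeric(1))
  names(res_area) <- res$label[match(names(res_area), res$key)]
  list(atom_area = setNames(area, a$serial), residue_area = res_area,
       atom_idx = sel)
}

#' Side-chain exposure ratio
#'
#' Side-chain SASA divided by a random-coil reference area for the residue
#' type (computed from extended Gly-X-Gly tripeptides with the package's own
#' SASA engine; see [exposure_reference_areas()]), times 100. Values can
#' exceed 100 and are reported unclamped; use `clamp = TRUE` for a display
#' variant in [0, 100]. Glycine uses its Calpha as the side-chain proxy.
#'
#' @param structure a `Structure`.
#' @param residue residue label or key; `NULL` for all standard residues.
#' @param probe_radius,n_points passed to [sasa()].
#' @param clamp clamp the result to [0, 100]?
#' @param sasa_result optional precomputed [sasa()] result for this
#'   structure at the same probe/quadrature settings.
#' @return percent exposure (named vector when `residue` is `NULL`).
#' @export
exposure_ratio <- function(structure, residue = NULL, probe_radius = 1.4,
                           n_points = 960, clamp = FALSE,
                           sasa_result = NULL) {
  sa <- sasa_result %||% sasa(structure, probe_radius, n_points)
  refs <- exposure_reference_areas(probe_radius, n_points)
  a <- structure$atoms
  keys <- residue_keys(structure)
  res <- residues(structure)
  one_ratio <- function(key) {
    rn <- toupper(res$resname[res$key == key][1])
    if (!rn %in% names(AA3TO1))
      ds_stop(paste("exposure ratio undefined for non-standard residue:", rn),
              "dynsite_unsupported_residue_error")
    sc_names <- if (rn == "GLY") "CA" else NULL
    in_res <- which(keys[sa$atom_idx] == key)
    nm <- toupper(a$name[sa$atom_idx[in_res]])
    sc <- if (is.null(sc_names)) in_res[!(nm %in% BACKBONE_ATOMS)]
          else in_res[nm %in% sc_names]
    100 * sum(sa$atom_area[sc]) / refs[rn]
  }
  if (!is.null(residue)) {
    val <- unname(one_ratio(resolve_residue_key(structure, residue)))
    return(if (clamp) min(max(val, 0), 100) else val)
  }
  std <- res$key[toupper(res$resname) %in% names(AA3TO1)]
  out <- vapply(std, one_ratio, numeric(1))
  names(out) <- res$label[match(std, res$key)]
  if (clamp) out <- pmin(pmax(out, 0), 100)
  out
}

# cache environment for the lazily computed random-coil reference table
.exposure_cache <- new.env(parent = emptyenv())

#' Random-coil side-chain reference areas
#'
#' Per-residue-type side-chain SASA of an extended Gly-X-Gly tripeptide
#' built from the package's idealised geometry, computed once per
#' (probe, quadrature) setting and cached. These synthetic reference areas
#' are self-consistent with [sasa()]: exposure ratios of isolated extended
#' residues evaluate near 100 percent by construction.
#'
#' @param probe_radius probe radius in Angstrom.
#' @param n_points quadrature points per atom.
#' @return named numeric vector over the 20 standard residue types
#'   (Angstrom^2).
#' @export
exposure_reference_areas <- function(probe_radius = 1.4, n_points = 960) {
  key <- sprintf("p%.3f_n%d", probe_radius, n_points)
  if (!is.null(.exposure_cache[[key]])) return(.exposure_cache[[key]])
  types <- names(AA3TO1)
  out <- vapply(types, function(rn) {
    tri <- gen_reference_tripeptide(rn)
    sa <- sasa(tri, probe_radius, n_points)
    keys <- residue_keys(tri)
    mid <- residues(tri)$key[2]
    in_res <- which(keys[sa$atom_idx] == mid)
    nm <- toupper(tri$atoms$name[sa$atom_idx[in_res]])
    sc <- if (rn == "GLY") in_res[nm == "CA"]
          else in_res[!(nm %in% BACKBONE_ATOMS)]
    sum(sa$atom_area[sc])
  }, numeric(1))
  .exposure_cache[[key]] <- out
  out
}

# ---- secondary structure ----------------------------------------------------

# backbone H-bond energy, Kabsch-Sander style (kcal/mol)
ks_energy <- function(N, H, C, O) {
  rON <- sqrt(sum((O - N)^2)); rCH <- sqrt(sum((C - H)^2))
  rOH <- sqrt(sum((O - H)^2)); rCN <- sqrt(sum((C - N)^2))
  if (min(rON, rCH, rOH, rCN) < 0.5) return(Inf)  # clashing geometry
  0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
}

backbone_table <- function(structure) {
  a <- structure$atoms
  keys <- residue_keys(structure)
  res <- residues(structure)
  get1 <- function(key, nm) {
    i <- which(keys == key & toupper(a$name) == nm)
    if (length(i) == 0) return(NULL)
    c(a$x[i[1]], a$y[i[1]], a$z[i[1]])
  }
  lapply(seq_len(nrow(res)), function(r) {
    k <- res$key[r]
    list(key = k, resname = toupper(res$resname[r]), chain = res$chain[r],
         N = get1(k, "N"), CA = get1(k, "CA"), C = get1(k, "C"),
         O = get1(k, "O"), H = get1(k, "H") %||% get1(k, "HN"))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# infer the amide H along the direction opposed to the bisector of the
# N->C(prev) and N->CA bonds, at 1.01 Angstrom
infer_amide_h <- function(bb, i) {
  if (i < 2) return(NULL)
  prev <- bb[[i - 1]]
  cur <- bb[[i]]
  if (cur$chain != prev$chain) return(NULL)
  if (is.null(prev$C) || is.null(cur$N) || is.null(cur$CA)) return(NULL)
  u1 <- prev$C - cur$N; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- cur$CA - cur$N; u2 <- u2 / sqrt(sum(u2^2))
  u <- -(u1 + u2); u <- u / sqrt(sum(u^2))
  cur$N + 1.01 * u
}

#' Assign secondary structure to one frame
#'
#' Backbone hydrogen bonds are scored with the Kabsch-Sander electrostatic
#' energy `E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)` kcal/mol and
#' assigned when `E < -0.5`. Two consecutive n-turns at offset 4 define
#' alpha-helix (H), at offset 3 a 3-10 helix (G); bridge hydrogen-bond
#' patterns define strand (E); isolated turns are T; everything else coil
#' (C). Conflicts resolve H > G > E > T > C. Amide hydrogens are inferred
#' geometrically when absent; residues missing backbone atoms are labelled C
#' and listed in the `warnings` attribute.
#'
#' @param frame a `Structure`.
#' @return named character vector of labels in `{H, G, E, T, C}`, one per
#'   residue (names are residue labels), with a `warnings` attribute.
#' @export
assign_secondary_structure <- function(frame) {
  bb <- backbone_table(frame)
  n <- length(bb)
  res <- residues(frame)
  warnings <- character(0)
  complete <- vapply(bb, function(b)
    !is.null(b$N) && !is.null(b$CA) && !is.null(b$C) && !is.null(b$O),
    logical(1))
  for (i in seq_len(n)) {
    if (!complete[i] && res$resname[i] %in% names(AA3TO1))
      warnings <- c(warnings,
                    sprintf("residue %s missing backbone atoms; labelled C",
                            res$label[i]))
    if (is.null(bb[[i]]$H)) bb[[i]]$H <- infer_amide_h(bb, i)
  }
  # HB[i, j]: C=O of residue i accepts from N-H of residue j
  HB <- matrix(FALSE, n, n)
  for (j in seq_len(n)) {
    if (!complete[j] || is.null(bb[[j]]$H) || bb[[j]]$resname == "PRO") next
    for (i in seq_len(n)) {
      if (i == j || !complete[i]) next
      if (bb[[i]]$chain == bb[[j]]$chain && abs(i - j) < 2) next
      e <- ks_energy(bb[[j]]$N, bb[[j]]$H, bb[[i]]$C, bb[[i]]$O)
      if (e < -0.5) HB[i, j] <- TRUE
    }
  }
  same_chain_run <- function(i, k) {
    k >= 1 && k <= n && bb[[i]]$chain == bb[[k]]$chain
  }
  lab <- rep("C", n)
  mark <- function(lab, idx, code) {
    prio <- c(H = 5, G = 4, E = 3, T = 2, C = 1)
    for (k in idx) if (prio[code] > prio[lab[k]]) lab[k] <- code
    lab
  }
  turn4 <- vapply(seq_len(n), function(i)
    same_chain_run(i, i + 4) && HB[i, i + 4], logical(1))
  turn3 <- vapply(seq_len(n), function(i)
    same_chain_run(i, i + 3) && HB[i, i + 3], logical(1))
  for (i in 2:max(n, 2)) {
    if (i <= n && i >= 2 && turn4[i - 1] && turn4[i])
      lab <- mark(lab, i:min(i + 3, n), "H")
  }
  for (i in 2:max(n, 2)) {
    if (i <= n && i >= 2 && turn3[i - 1] && turn3[i])
      lab <- mark(lab, i:min(i + 2, n), "G")
  }
  # bridges
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) < 3 && bb[[i]]$chain == bb[[j]]$chain) next
      anti <- (HB[i, j] && HB[j, i]) ||
        (i > 1 && j < n && i + 1 <= n && j - 1 >= 1 &&
           HB[i - 1, j + 1] && HB[j - 1, i + 1])
      par <- (i > 1 && i + 1 <= n && HB[i - 1, j] && HB[j, i + 1]) ||
        (j > 1 && j + 1 <= n && HB[j - 1, i] && HB[i, j + 1])
      if (anti || par) lab <- mark(lab, c(i, j), "E")
    }
  }
  # isolated turns: residues strictly inside an n-turn
  for (i in seq_len(n)) {
    if (turn3[i]) lab <- mark(lab, (i + 1):(i + 2), "T")
    if (turn4[i]) lab <- mark(lab, (i + 1):(i + 3), "T")
  }
  lab[!complete] <- "C"                  # incomplete backbone: coil
  names(lab) <- res$label
  attr(lab, "warnings") <- warnings
  lab
}

#' Secondary-structure fractions over an ensemble
#'
#' Fraction of analysis frames in each state per residue; rows sum to 1.
#'
#' @param ensemble an `Ensemble`.
#' @param analysis_stride_ns analysis tick spacing (ns).
#' @return residues x 5 matrix with columns `H, G, E, T, C`.
#' @export
ss_fractions <- function(ensemble, analysis_stride_ns = 1.0) {
  fidx <- analysis_frames(ensemble, analysis_stride_ns)
  states <- c("H", "G", "E", "T", "C")
  labs <- vapply(fidx, function(i)
    as.character(assign_secondary_structure(frame_structure(ensemble, i))),
    character(nrow(residues(ensemble$topology))))
  labs <- matrix(labs, ncol = length(fidx))
  out <- t(apply(labs, 1, function(row)
    table(factor(row, levels = states)) / length(row)))
  rownames(out) <- residues(ensemble$topology)$label
  colnames(out) <- states
  out
}

# ---- assembled metric table -------------------------------------------------

#' Per-residue metric table for an ensemble
#'
#' Assembles the module's descriptors into one table: mean per-residue RMSD,
#' RMSF, mean contact count, mean SASA, side-chain exposure ratio, a DCCM
#' coupling score, and secondary-structure state fractions.
#'
#' @param ensemble an `Ensemble`.
#' @param partner_residues residue labels defining the DCCM coupling score
#'   partner set (default: all residues).
#' @param analysis_stride_ns analysis tick spacing (ns).
#' @param contact_cutoff contact distance cutoff (Angstrom).
#' @param probe_radius SASA probe radius (Angstrom).
#' @param n_points SASA quadrature points.
#' @param metrics which metric families to compute (subset of the default).
#' @return data.frame of class `ResidueMetricTable`, one row per residue,
#'   with the parameter set in the `params` attribute.
#' @export
residue_metric_table <- function(ensemble, partner_residues = NULL,
                                 analysis_stride_ns = 1.0,
                                 contact_cutoff = 5.0, probe_radius = 1.4,
                                 n_points = 960,
                                 metrics = c("rmsd", "rmsf", "contacts",
                                             "sasa", "exposure", "dccm",
                                             "ss")) {
  res <- residues(ensemble$topology)
  out <- data.frame(residue = res$label, chain = res$chain,
                    resseq = res$resseq, stringsAsFactors = FALSE)
  fidx <- analysis_frames(ensemble, analysis_stride_ns)
  if ("rmsd" %in% metrics) {
    rr <- per_residue_rmsd(ensemble, analysis_stride_ns = analysis_stride_ns)
    out$rmsd_mean <- rr$mean[match(res$key, names(rr$mean))]
  }
  if ("rmsf" %in% metrics && n_frames(ensemble) >= 2) {
    rf <- per_residue_rmsf(ensemble)
    out$rmsf <- rf[match(res$key, names(rf))]
  }
  if ("contacts" %in% metrics) {
    cc <- contact_counts_mean(ensemble, cutoff = contact_cutoff,
                              analysis_stride_ns = analysis_stride_ns)
    out$contacts_mean <- cc[match(res$label, names(cc))]
  }
  if ("sasa" %in% metrics || "exposure" %in% metrics) {
    sa_frames <- lapply(fidx, function(i)
      sasa(frame_structure(ensemble, i), probe_radius, n_points))
    sa_mean <- Reduce(`+`, lapply(sa_frames, `[[`, "residue_area")) /
      length(sa_frames)
    if ("sasa" %in% metrics)
      out$sasa_mean <- sa_mean[match(res$label, names(sa_mean))]
    if ("exposure" %in% metrics) {
      ex_frames <- lapply(seq_along(fidx), function(k)
        tryCatch(exposure_ratio(frame_structure(ensemble, fidx[k]),
                                probe_radius = probe_radius,
                                n_points = n_points,
                                sasa_result = sa_frames[[k]]),
                 dynsite_error = function(e) NULL))
      ex_frames <- Filter(Negate(is.null), ex_frames)
      if (length(ex_frames) > 0) {
        ex_mean <- Reduce(`+`, ex_frames) / length(ex_frames)
        out$exposure_ratio <- ex_mean[match(res$label, names(ex_mean))]
      }
    }
  }
  if ("dccm" %in% metrics && n_frames(ensemble) >= 2) {
    dm <- dccm(ensemble)
    out$dccm_score <- vapply(res$label, function(r) {
      if (!r %in% dm$residues) return(NA_real_)
      tryCatch(dccm_residue_score(dm, r, partner_residues %||% dm$residues),
               dynsite_error = function(e) NA_real_)
    }, numeric(1))
  }
  if ("ss" %in% metrics) {
    sf <- ss_fractions(ensemble, analysis_stride_ns)
    for (st in colnames(sf)) out[[paste0("ss_", st)]] <- sf[, st]
  }
  attr(out, "params") <- list(analysis_stride_ns = analysis_stride_ns,
                              contact_cutoff = contact_cutoff,
                              probe_radius = probe_radius,
                              n_points = n_points,
                              n_frames = n_frames(ensemble),
                              partner_residues = partner_residues)
  class(out) <- c("ResidueMetricTable", class(out))
  out
}

#' Write a metric table as TSV with a parameter header
#'
#' @param table a `ResidueMetricTable` (or plain data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(table, path) {
  params <- attr(table, "params")
  hdr <- if (is.null(params)) character(0) else
    sprintf("# %s = %s", names(params),
            vapply(params, function(p) paste(format(p), collapse = ","),
                   character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a metric table written by [write_metric_table()]
#' @param path TSV path.
#' @return data.frame of class `ResidueMetricTable`.
#' @export
read_metric_table <- function(path) {
  out <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
  class(out) <- c("ResidueMetricTable", class(out))
  out
}
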