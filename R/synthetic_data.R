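# Ground-truth generators: every analysis stage of the package can be
# exercised on synthetic inputs whose true answer is known by construction.
# All generators are deterministic given a seed.

# ---- internal-coordinate geometry (NeRF) ------------------------------------

# place atom D given A-B-C, bond |C-D|, angle B-C-D (deg), torsion A-B-C-D (deg)
nerf_place <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

PHI_PSI <- list(
  alpha_helix = c(-57, -47),
  three10_helix = c(-49, -26),
  beta_strand = c(-139, 135),
  coil = c(-80, 150)
)

# simplified ideal side-chain internal coordinates: each heavy atom placed
# by NeRF from three previously placed atoms (extended chi angles; rings
# built as regular polygons via ring closure approximations)
SIDECHAIN_DEFS <- local({
  ext <- function(name, p1, p2, p3, bond = 1.52, angle = 111, tor = 180)
    list(name, p1, p2, p3, bond, angle, tor)
  cb <- list(ext("CB", "C", "N", "CA", 1.53, 110.5, -122.0))
  ring6 <- function() list(                           # phenyl on CG
    ext("CD1", "CA", "CB", "CG", 1.39, 120, 90),
    ext("CD2", "CA", "CB", "CG", 1.39, 120, -90),
    ext("CE1", "CB", "CG", "CD1", 1.39, 120, 180),
    ext("CE2", "CB", "CG", "CD2", 1.39, 120, 180),
    ext("CZ", "CG", "CD1", "CE1", 1.39, 120, 0))
  list(
    GLY = list(),
    ALA = cb,
    SER = c(cb, list(ext("OG", "N", "CA", "CB", 1.42, 110.5))),
    CYS = c(cb, list(ext("SG", "N", "CA", "CB", 1.81, 113))),
    THR = c(cb, list(ext("OG1", "N", "CA", "CB", 1.42, 109, 60),
                     ext("CG2", "N", "CA", "CB", 1.52, 111, 180))),
    VAL = c(cb, list(ext("CG1", "N", "CA", "CB", 1.52, 111, 175),
                     ext("CG2", "N", "CA", "CB", 1.52, 111, -65))),
    LEU = c(cb, list(ext("CG", "N", "CA", "CB"),
                     ext("CD1", "CA", "CB", "CG", 1.52, 111, 65),
                     ext("CD2", "CA", "CB", "CG", 1.52, 111, 180))),
    ILE = c(cb, list(ext("CG1", "N", "CA", "CB", 1.52, 111, 180),
                     ext("CG2", "N", "CA", "CB", 1.52, 111, -65),
                     ext("CD1", "CA", "CB", "CG1"))),
    MET = c(cb, list(ext("CG", "N", "CA", "CB"),
                     ext("SD", "CA", "CB", "CG", 1.81, 113),
                     ext("CE", "CB", "CG", "SD", 1.79, 100))),
    PRO = c(cb, list(ext("CG", "N", "CA", "CB", 1.51, 104, 30),
                     ext("CD", "CA", "CB", "CG", 1.51, 104, -35))),
    PHE = c(cb, list(ext("CG", "N", "CA", "CB", 1.50, 114)), ring6()),
    TYR = c(cb, list(ext("CG", "N", "CA", "CB", 1.50, 114)), ring6(),
            list(ext("OH", "CD1", "CE1", "CZ", 1.36, 120, 180))),
    TRP = c(cb, list(ext("CG", "N", "CA", "CB", 1.50, 114),
                     ext("CD1", "CA", "CB", "CG", 1.37, 127, 90),
                     ext("CD2", "CA", "CB", "CG", 1.43, 127, -90),
                     ext("NE1", "CB", "CG", "CD1", 1.38, 110, 180),
                     ext("CE2", "CB", "CG", "CD2", 1.40, 107, 180),
                     ext("CE3", "CG", "CD1", "CD2", 1.40, 133, 180),
                     ext("CZ2", "CG", "CD2", "CE2", 1.40, 122, 180),
                     ext("CZ3", "CD1", "CD2", "CE3", 1.40, 118, 180),
                     ext("CH2", "CD2", "CE2", "CZ2", 1.40, 117, 0))),
    HIS = c(cb, list(ext("CG", "N", "CA", "CB", 1.50, 114),
                     ext("ND1", "CA", "CB", "CG", 1.38, 122, 90),
                     ext("CD2", "CA", "CB", "CG", 1.36, 130, -90),
                     ext("CE1", "CB", "CG", "ND1", 1.32, 109, 180),
                     ext("NE2", "CB", "CG", "CD2", 1.37, 107, 180))),
    ASP = c(cb, list(ext("CG", "N", "CA", "CB", 1.52, 113),
                     ext("OD1", "CA", "CB", "CG", 1.25, 119, 0),
                     ext("OD2", "CA", "CB", "CG", 1.25, 119, 180))),
    ASN = c(cb, list(ext("CG", "N", "CA", "CB", 1.52, 113),
                     ext("OD1", "CA", "CB", "CG", 1.23, 121, 0),
                     ext("ND2", "CA", "CB", "CG", 1.33, 117, 180))),
    GLU = c(cb, list(ext("CG", "N", "CA", "CB"),
                     ext("CD", "CA", "CB", "CG", 1.52, 113),
                     ext("OE1", "CB", "CG", "CD", 1.25, 119, 0),
                     ext("OE2", "CB", "CG", "CD", 1.25, 119, 180))),
    GLN = c(cb, list(ext("CG", "N", "CA", "CB"),
                     ext("CD", "CA", "CB", "CG", 1.52, 113),
                     ext("OE1", "CB", "CG", "CD", 1.23, 121, 0),
                     ext("NE2", "CB", "CG", "CD", 1.33, 117, 180))),
    LYS = c(cb, list(ext("CG", "N", "CA", "CB"),
                     ext("CD", "CA", "CB", "CG"),
                     ext("CE", "CB", "CG", "CD"),
                     ext("NZ", "CG", "CD", "CE", 1.49, 112))),
    ARG = c(cb, list(ext("CG", "N", "CA", "CB"),
                     ext("CD", "CA", "CB", "CG"),
                     ext("NE", "CB", "CG", "CD", 1.46, 112),
                     ext("CZ", "CG", "CD", "NE", 1.33, 124),
                     ext("NH1", "CD", "NE", "CZ", 1.33, 120, 0),
                     ext("NH2", "CD", "NE", "CZ", 1.33, 120, 180)))
  )
})

build_sidechain <- function(resname, pos) {
  defs <- SIDECHAIN_DEFS[[resname]]
  if (is.null(defs) || length(defs) == 0) return(pos)
  for (d in defs) {
    pos[[d[[1]]]] <- nerf_place(pos[[d[[2]]]], pos[[d[[3]]]], pos[[d[[4]]]],
                                d[[5]], d[[6]], d[[7]])
  }
  pos
}

element_of <- function(name) {
  n <- toupper(name)
  if (substr(n, 1, 2) %in% c("CU", "FE", "ZN", "MG")) return(substr(n, 1, 2))
  substr(gsub("[0-9']", "", n), 1, 1)
}

build_peptide <- function(sequence, phi, psi, chain = "A", resseq_start = 1,
                          sidechains = TRUE, serial_start = 1) {
  nres <- length(sequence)
  phi <- rep_len(phi, nres); psi <- rep_len(psi, nres)
  N <- vector("list", nres); CA <- vector("list", nres)
  C <- vector("list", nres); O <- vector("list", nres)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  C[[1]] <- CA[[1]] + 1.525 * c(cos(pi - ang), sin(pi - ang), 0)
  for (i in seq_len(nres)) {
    if (i < nres) {
      N[[i + 1]] <- nerf_place(N[[i]], CA[[i]], C[[i]], 1.329, 116.2, psi[i])
      CA[[i + 1]] <- nerf_place(CA[[i]], C[[i]], N[[i + 1]], 1.458, 121.7, 180)
      C[[i + 1]] <- nerf_place(C[[i]], N[[i + 1]], CA[[i + 1]],
                               1.525, 111.2, phi[i + 1])
    }
    O[[i]] <- nerf_place(N[[i]], CA[[i]], C[[i]], 1.231, 120.8, psi[i] + 180)
  }
  rows <- list()
  serial <- serial_start
  for (i in seq_len(nres)) {
    pos <- list(N = N[[i]], CA = CA[[i]], C = C[[i]], O = O[[i]])
    if (sidechains) pos <- build_sidechain(sequence[i], pos)
    order_names <- c("N", "CA", "C", "O",
                     setdiff(names(pos), c("N", "CA", "C", "O")))
    for (nm in order_names) {
      rows[[length(rows) + 1]] <- data.frame(
        serial = serial, name = nm, element = element_of(nm),
        resname = sequence[i], resseq = resseq_start + i - 1, icode = "",
        chain = chain, x = pos[[nm]][1], y = pos[[nm]][2], z = pos[[nm]][3],
        hetero = FALSE, stringsAsFactors = FALSE)
      serial <- serial + 1
    }
  }
  do.call(rbind, rows)
}

#' Build an idealised secondary-structure element
#'
#' Backbone (N, CA, C, O) constructed from canonical internal coordinates
#' (alpha helix: phi = -57, psi = -47; 3-10 helix: -49/-26; strand:
#' -139/135), with standard peptide bond lengths and angles; deterministic.
#' `antiparallel_sheet` builds two strands (chains A and B), placing the
#' partner by a deterministic grid search over rigid offsets that maximises
#' the inter-strand backbone hydrogen-bond count.
#'
#' @param kind one of `alpha_helix`, `three10_helix`, `beta_strand`,
#'   `antiparallel_sheet`, `coil`.
#' @param length residues per strand (>= 2).
#' @param sequence 3-letter residue codes, recycled (default poly-alanine).
#' @param sidechains build simplified ideal side chains?
#' @return a `Structure`.
#' @export
gen_ideal_structure <- function(kind = c("alpha_helix", "three10_helix",
                                         "beta_strand", "antiparallel_sheet",
                                         "coil"),
                                length, sequence = "ALA",
                                sidechains = FALSE) {
  kind <- match.arg(kind)
  if (length < 2)
    ds_stop("length must be >= 2", "dynsite_validation_error")
  seqv <- rep_len(toupper(sequence), length)
  bad <- setdiff(seqv, names(SIDECHAIN_DEFS))
  if (length(bad) > 0)
    ds_stop(paste("unsupported residue type:", paste(bad, collapse = ", ")),
            "dynsite_validation_error")
  if (kind == "antiparallel_sheet") {
    pp <- PHI_PSI$beta_strand
    a1 <- build_peptide(seqv, pp[1], pp[2], chain = "A",
                        sidechains = sidechains)
    a2 <- place_antiparallel_partner(a1, seqv, pp, sidechains)
    return(new_structure(rbind(a1, a2),
                         metadata = list(generator = "antiparallel_sheet")))
  }
  pp <- PHI_PSI[[kind]]
  atoms <- build_peptide(seqv, pp[1], pp[2], sidechains = sidechains)
  new_structure(atoms, metadata = list(generator = kind))
}

# deterministic rigid placement of the partner strand: flip about the y
# axis, then grid-search x/y offsets for the most inter-strand H-bonds
place_antiparallel_partner <- function(a1, seqv, pp, sidechains) {
  a2 <- build_peptide(seqv, pp[1], pp[2], chain = "B",
                      resseq_start = length(seqv) + 11,
                      sidechains = sidechains,
                      serial_start = max(a1$serial) + 1)
  xyz1 <- as.matrix(a1[, c("x", "y", "z")])
  xyz2 <- as.matrix(a2[, c("x", "y", "z")])
  ctr <- colMeans(xyz1)
  flips <- list(diag(c(-1, 1, -1)), diag(c(-1, -1, 1)))
  best <- NULL; best_n <- -1
  for (Fm in flips) {
    base <- sweep(sweep(xyz2, 2, ctr) %*% t(Fm), 2, ctr, "+")
    for (dy in seq(3.8, 5.6, by = 0.1)) {
      for (dx in seq(-3, 3, by = 0.25)) {
        cand <- sweep(base, 2, c(dx, dy, 0), "+")
        a2c <- a2; a2c$x <- cand[, 1]; a2c$y <- cand[, 2]; a2c$z <- cand[, 3]
        s <- new_structure(rbind(a1, a2c))
        nhb <- count_interchain_hbonds(s)
        if (nhb > best_n) { best_n <- nhb; best <- a2c }
      }
    }
  }
  best
}

count_interchain_hbonds <- function(structure) {
  bb <- backbone_table(structure)
  n <- length(bb)
  for (i in seq_len(n)) if (is.null(bb[[i]]$H))
    bb[[i]]$H <- infer_amide_h(bb, i)
  cnt <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (bb[[i]]$chain == bb[[j]]$chain) next
    if (is.null(bb[[j]]$H) || is.null(bb[[i]]$O)) next
    if (ks_energy(bb[[j]]$N, bb[[j]]$H, bb[[i]]$C, bb[[i]]$O) < -0.5)
      cnt <- cnt + 1
  }
  cnt
}

#' Extended Gly-X-Gly reference tripeptide
#'
#' Builds the extended tripeptide used to define the random-coil side-chain
#' reference areas behind [exposure_ratio()].
#'
#' @param restype central residue 3-letter code.
#' @return a `Structure` with side chains.
#' @export
gen_reference_tripeptide <- function(restype) {
  gen_ideal_structure("beta_strand", 3,
                      sequence = c("GLY", toupper(restype), "GLY"),
                      sidechains = TRUE)
}

# ---- correlated Gaussian ensembles ------------------------------------------

#' Fluctuation specification for Gaussian ensembles
#'
#' Describes per-residue isotropic per-coordinate displacement standard
#' deviations and a block correlation structure. The implied correlation
#' matrix is validated as positive semidefinite at construction.
#'
#' @param sds per-residue per-coordinate displacement std (Angstrom),
#'   recycled to the residue count at generation time.
#' @param blocks list of lists, each with `residues` (indices into the
#'   reference's residue order) and `rho` (intra-block correlation).
#' @param inter_rho correlation between residues of different blocks.
#' @param n_frames frame count (alternatively give `duration_ns`).
#' @param duration_ns trajectory length; frames = `duration_ns / stride_ns`.
#' @param stride_ns save stride (ns).
#' @param seed RNG seed.
#' @return object of class `FluctuationSpec`.
#' @export
fluctuation_spec <- function(sds, blocks = list(), inter_rho = 0,
                             n_frames = NULL, duration_ns = NULL,
                             stride_ns = 0.25, seed = 1) {
  if (any(sds < 0)) ds_stop("stds must be >= 0", "dynsite_validation_error")
  for (b in blocks)
    if (abs(b$rho) > 1)
      ds_stop("|rho| must be <= 1", "dynsite_validation_error")
  if (is.null(n_frames)) {
    if (is.null(duration_ns))
      ds_stop("give n_frames or duration_ns", "dynsite_validation_error")
    n_frames <- round(duration_ns / stride_ns)
  }
  structure(list(sds = sds, blocks = blocks, inter_rho = inter_rho,
                 n_frames = as.integer(n_frames), stride_ns = stride_ns,
                 seed = seed),
            class = "FluctuationSpec")
}

spec_correlation_matrix <- function(spec, nres) {
  R <- diag(nres)
  in_block <- rep(0L, nres)
  for (k in seq_along(spec$blocks)) {
    b <- spec$blocks[[k]]
    in_block[b$residues] <- k
    for (i in b$residues) for (j in b$residues)
      if (i != j) R[i, j] <- b$rho
  }
  if (spec$inter_rho != 0) {
    for (i in seq_len(nres)) for (j in seq_len(nres)) {
      if (i != j && in_block[i] > 0 && in_block[j] > 0 &&
          in_block[i] != in_block[j])
        R[i, j] <- spec$inter_rho
    }
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    ds_stop("implied correlation matrix is not positive semidefinite",
            "dynsite_construction_error")
  R
}

#' Generate a correlated-Gaussian conformational ensemble
#'
#' Frames are the reference plus multivariate-normal Calpha displacements
#' realising the spec's covariance (per-coordinate std `sds`, correlation
#' from the block structure); each residue's other atoms follow its Calpha
#' displacement rigidly. Bit-reproducible per seed.
#'
#' @param reference a `Structure`.
#' @param spec a [fluctuation_spec()].
#' @return an `Ensemble`.
#' @export
gen_gaussian_ensemble <- function(reference, spec) {
  res <- residues(reference)
  nres <- nrow(res)
  sds <- rep_len(spec$sds, nres)
  R <- spec_correlation_matrix(spec, nres)
  S <- diag(sds, nres) %*% R %*% diag(sds, nres)
  ed <- eigen(S, symmetric = TRUE)
  L <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), nres)
  keys <- residue_keys(reference)
  res_idx <- match(keys, res$key)            # residue index per atom
  refxyz <- coords(reference)
  set.seed(spec$seed)
  frames <- vector("list", spec$n_frames)
  for (f in seq_len(spec$n_frames)) {
    disp <- vapply(1:3, function(ax) as.numeric(L %*% rnorm(nres)),
                   numeric(nres))                     # nres x 3
    frames[[f]] <- refxyz + disp[res_idx, , drop = FALSE]
  }
  new_ensemble(reference, frames, stride_ns = spec$stride_ns)
}

# ---- toy dicopper site ------------------------------------------------------

#' Dicopper site descriptor
#' @param cuA,cuB copper positions (length-3, Angstrom; must differ).
#' @param coordinating residue labels of the coordinating histidines.
#' @param o2 optional 2 x 3 matrix of bridging O2 positions.
#' @return object of class `CopperSite`.
#' @export
copper_site <- function(cuA, cuB, coordinating = character(0), o2 = NULL) {
  if (!all(is.finite(c(cuA, cuB))) || isTRUE(all(cuA == cuB)))
    ds_stop("copper positions must be finite and distinct",
            "dynsite_validation_error")
  structure(list(cuA = as.numeric(cuA), cuB = as.numeric(cuB),
                 coordinating = coordinating, o2 = o2),
            class = "CopperSite")
}

#' Midpoint of the two coppers
#' @param site a `CopperSite`.
#' @return length-3 numeric.
#' @export
cu_midpoint <- function(site) (site$cuA + site$cuB) / 2

regular_polygon_on_edge <- function(p1, p2, nvert, away_from) {
  # planar regular polygon containing edge p1-p2, remaining vertices on the
  # side away from `away_from`; returns the other nvert-2 vertices in order
  s <- sqrt(sum((p2 - p1)^2))
  Rp <- s / (2 * sin(pi / nvert))
  mid <- (p1 + p2) / 2
  e <- (p2 - p1) / s
  w <- away_from - mid
  w <- w - sum(w * e) * e
  w <- -w / sqrt(sum(w^2))                  # away side
  apo <- Rp * cos(pi / nvert)
  ctr <- mid + apo * w
  u1 <- (p1 - ctr) / Rp
  n3 <- c(e[2] * w[3] - e[3] * w[2], e[3] * w[1] - e[1] * w[3],
          e[1] * w[2] - e[2] * w[1])
  u2 <- c(u1[2] * n3[3] - u1[3] * n3[2], u1[3] * n3[1] - u1[1] * n3[3],
          u1[1] * n3[2] - u1[2] * n3[1])
  th0 <- atan2(sum((p2 - ctr) * u2), sum((p2 - ctr) * u1))
  step <- if (th0 > 0) 2 * pi / nvert else -2 * pi / nvert
  t(vapply(2:(nvert - 1), function(k)
    ctr + Rp * (cos(k * step) * u1 + sin(k * step) * u2), numeric(3)))
}

#' Toy dicopper active site
#'
#' Two copper centres ~3.5 Angstrom apart flanked by six histidine-like
#' residues (three per copper, coordinating nitrogen ~2.1 Angstrom from its
#' copper) and a bridging O2 placeholder; deterministic coordinates.
#' Residue numbering follows the tyrosinase coordinating histidines
#' (180/202/211 on CuA; 363/367/390 on CuB).
#'
#' @param scale geometry scale factor (> 0).
#' @return list with `structure` (a `Structure`) and `site` (a
#'   `CopperSite`).
#' @export
gen_toy_active_site <- function(scale = 1) {
  if (scale <= 0) ds_stop("scale must be > 0", "dynsite_validation_error")
  cuA <- c(0, 0, 0); cuB <- c(3.5, 0, 0)
  dirs <- list(c(-1, 1, 0.6), c(-1, -1, 0.6), c(-0.4, 0, -1))
  dirs <- lapply(dirs, function(d) d / sqrt(sum(d^2)))
  his <- list(
    list(cu = cuA, dir = dirs[[1]], resseq = 180),
    list(cu = cuA, dir = dirs[[2]], resseq = 202),
    list(cu = cuA, dir = dirs[[3]], resseq = 211),
    list(cu = cuB, dir = lapply(dirs, function(d) d * c(-1, 1, 1))[[1]],
         resseq = 363),
    list(cu = cuB, dir = lapply(dirs, function(d) d * c(-1, 1, 1))[[2]],
         resseq = 367),
    list(cu = cuB, dir = lapply(dirs, function(d) d * c(-1, 1, 1))[[3]],
         resseq = 390)
  )
  rows <- list(); serial <- 1
  add <- function(name, el, resname, resseq, pos, hetero) {
    rows[[length(rows) + 1]] <<- data.frame(
      serial = serial, name = name, element = el, resname = resname,
      resseq = resseq, icode = "", chain = if (hetero) "X" else "A",
      x = pos[1] * scale, y = pos[2] * scale, z = pos[3] * scale,
      hetero = hetero, stringsAsFactors = FALSE)
    serial <<- serial + 1
  }
  for (h in his) {
    nd1 <- h$cu + 2.1 * h$dir
    # imidazole ring: regular pentagon on a synthetic ND1-CE1 edge,
    # extending away from the copper
    ce1 <- nd1 + 1.32 * rotate_off_axis(h$dir, 72)
    rest <- regular_polygon_on_edge(nd1, ce1, 5, h$cu)
    add("ND1", "N", "HIS", h$resseq, nd1, FALSE)
    add("CE1", "C", "HIS", h$resseq, ce1, FALSE)
    add("NE2", "N", "HIS", h$resseq, rest[1, ], FALSE)
    add("CD2", "C", "HIS", h$resseq, rest[2, ], FALSE)
    cg <- rest[3, ]
    add("CG", "C", "HIS", h$resseq, cg, FALSE)
    ring_ctr <- colMeans(rbind(nd1, ce1, rest))
    out_dir <- (cg - ring_ctr) / sqrt(sum((cg - ring_ctr)^2))
    cb <- cg + 1.5 * out_dir
    add("CB", "C", "HIS", h$resseq, cb, FALSE)
    add("CA", "C", "HIS", h$resseq, cb + 1.53 * out_dir, FALSE)
  }
  add("CU", "CU", "CU1", 501, cuA, TRUE)
  add("CU", "CU", "CU2", 502, cuB, TRUE)
  o2 <- rbind(c(1.45, 1.0, 0), c(2.05, 1.0, 0))
  add("O1", "O", "OXY", 503, o2[1, ], TRUE)
  add("O2", "O", "OXY", 503, o2[2, ], TRUE)
  st <- new_structure(do.call(rbind, rows),
                      metadata = list(generator = "toy_active_site",
                                      scale = scale))
  site <- copper_site(cuA * scale, cuB * scale,
                      coordinating = c("H180", "H202", "H211",
                                       "H363", "H367", "H390"),
                      o2 = o2 * scale)
  list(structure = st, site = site)
}

# a deterministic unit vector at `deg` degrees from axis u
rotate_off_axis <- function(u, deg) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u
  v <- v / sqrt(sum(v^2))
  a <- deg * pi / 180
  cos(a) * u + sin(a) * v
}

# ---- ligand trajectories ----------------------------------------------------

#' Ligand motion specification
#' @param mode `"bound"` (jitter about the docked geometry) or `"escape"`
#'   (linear drift away from the copper midpoint).
#' @param jitter displacement std per frame (Angstrom); bound-mode
#'   displacements are resampled to stay within `2 * jitter` so the mode's
#'   ground-truth label is guaranteed for `jitter <= 0.4`.
#' @param drift drift rate (Angstrom per frame; escape mode, > 0).
#' @param n_frames frame count.
#' @param stride_ns save stride (ns).
#' @param seed RNG seed.
#' @return object of class `LigandMotionSpec`.
#' @export
ligand_motion_spec <- function(mode = c("bound", "escape"), jitter = 0.2,
                               drift = 0.5, n_frames = 20, stride_ns = 1.0,
                               seed = 1) {
  mode <- match.arg(mode)
  if (jitter < 0) ds_stop("jitter must be >= 0", "dynsite_validation_error")
  if (mode == "escape" && drift <= 0)
    ds_stop("escape mode needs drift > 0", "dynsite_validation_error")
  structure(list(mode = mode, jitter = jitter, drift = drift,
                 n_frames = as.integer(n_frames), stride_ns = stride_ns,
                 seed = seed),
            class = "LigandMotionSpec")
}

#' Generate a ligand trajectory around a dicopper site
#'
#' The ligand template is rigidly docked so its first qualifying oxygen sits
#' 3.2 Angstrom from CuA, collinear with the CuA-CuB axis and oriented
#' toward the site (ring centroid outside). Bound mode adds bounded rigid
#' jitter; escape mode adds linear drift `drift * k` along the outward axis,
#' so the O-Cu distance at frame k is exactly `3.2 + drift * k`.
#'
#' @param site_structure the site `Structure` (e.g. from
#'   [gen_toy_active_site()]).
#' @param site a `CopperSite`.
#' @param spec a [ligand_motion_spec()].
#' @param template ligand template code: `"LTY"`, `"LDO"`, `"DHC"`, `"DHI"`.
#' @return an `Ensemble` whose topology is site + ligand.
#' @export
gen_ligand_trajectory <- function(site_structure, site, spec,
                                  template = "LTY") {
  lig <- ligand_template(template)
  u <- site$cuA - site$cuB
  u <- u / sqrt(sum(u^2))                  # outward axis through CuA
  o_name <- lig$qualifying_oxygens[1]
  oxyz <- lig$coords[lig$atoms$name == o_name, ]
  ring_ctr <- colMeans(lig$coords[lig$atoms$name %in% lig$rings[[1]], ,
                                  drop = FALSE])
  v <- oxyz - ring_ctr                     # template centroid -> oxygen
  Rrot <- rotation_between(v / sqrt(sum(v^2)), -u)
  placed <- sweep(lig$coords, 2, oxyz) %*% t(Rrot)
  placed <- sweep(placed, 2, site$cuA + 3.2 * u, "+")
  lig_atoms <- lig$atoms
  lig_atoms$x <- placed[, 1]; lig_atoms$y <- placed[, 2]
  lig_atoms$z <- placed[, 3]
  lig_atoms$serial <- max(site_structure$atoms$serial) + seq_len(nrow(lig_atoms))
  topo <- new_structure(rbind(site_structure$atoms[,
                                names(lig_atoms)], lig_atoms),
                        metadata = list(generator = "ligand_trajectory",
                                        mode = spec$mode, seed = spec$seed,
                                        template = template))
  nl <- nrow(lig_atoms)
  nprot <- n_atoms(site_structure)
  refxyz <- coords(topo)
  set.seed(spec$seed)
  frames <- vector("list", spec$n_frames)
  for (k in seq_len(spec$n_frames)) {
    if (spec$jitter > 0) {
      repeat {
        delta <- stats::rnorm(3, 0, spec$jitter)
        if (sqrt(sum(delta^2)) <= 2 * spec$jitter) break
      }
    } else delta <- c(0, 0, 0)
    if (spec$mode == "escape") delta <- delta + spec$drift * k * u
    fx <- refxyz
    fx[nprot + seq_len(nl), ] <- sweep(fx[nprot + seq_len(nl), , drop = FALSE],
                                       2, delta, "+")
    frames[[k]] <- fx
  }
  new_ensemble(topo, frames, stride_ns = spec$stride_ns)
}

# proper rotation taking unit vector a to unit vector b (Rodrigues)
rotation_between <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (sum(v^2) < 1e-12) {
    if (c_ > 0) return(diag(3))
    # opposite: rotate 180 about any axis perpendicular to a
    p <- rotate_off_axis(a, 90)
    K <- matrix(c(0, -p[3], p[2], p[3], 0, -p[1], -p[2], p[1], 0), 3, 3,
                byrow = TRUE)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K * (1 - c_) / sum(v^2)
}

# ---- variant panels ---------------------------------------------------------

#' Variant panel specification
#'
#' @param universe residue labels forming the interaction set.
#' @param groups named list of residue-label vectors (non-overlapping,
#'   within the universe).
#' @param effect_sizes named per-group mean destabilisation magnitude
#'   (relative change; >= 0).
#' @param noise_cv multiplicative lognormal noise coefficient of variation.
#' @param n_variants variant count (>= 1).
#' @param seed RNG seed.
#' @return object of class `VariantPanelSpec`.
#' @export
variant_panel_spec <- function(universe, groups, effect_sizes,
                               noise_cv = 0, n_variants = 25, seed = 1) {
  all_members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_members))
    ds_stop("groups must not overlap", "dynsite_validation_error")
  if (!all(all_members %in% universe))
    ds_stop("groups must lie within the universe", "dynsite_validation_error")
  if (any(effect_sizes < 0))
    ds_stop("effect sizes must be >= 0", "dynsite_validation_error")
  if (n_variants < 1)
    ds_stop("need at least one variant", "dynsite_validation_error")
  if (!all(names(groups) %in% names(effect_sizes)))
    ds_stop("each group needs an effect size", "dynsite_validation_error")
  structure(list(universe = universe, groups = groups,
                 effect_sizes = effect_sizes, noise_cv = noise_cv,
                 n_variants = as.integer(n_variants), seed = seed),
            class = "VariantPanelSpec")
}

PANEL_METRICS <- c("rmsd_mean", "rmsf", "sasa_mean", "contacts_mean",
                   "dccm_score")
PANEL_BASELINES <- c(rmsd_mean = 1.5, rmsf = 0.8, sasa_mean = 60,
                     contacts_mean = 20, dccm_score = 0.5)

#' Generate a synthetic variant panel with known group effects
#'
#' Per variant and group residue, destabilisation magnitudes are drawn as
#' `effect_size * lognormal(CV)` (lognormal keeps magnitudes positive;
#' mean 1). Mutant metric values move from realistic wild-type baselines in
#' the destabilising direction by that relative magnitude (RMSD/RMSF/SASA
#' up; contacts/DCCM down), so relative-change commensuration recovers the
#' drawn magnitudes exactly. Perturbation flags derive from the neutral
#' band.
#'
#' @param spec a [variant_panel_spec()].
#' @return list with `variants` (data.frame), `deltas` (list of
#'   `DeltaReport`), `wildtype` (metric table), `flags` (long data.frame of
#'   perturbation flags), and `ground_truth`.
#' @export
gen_variant_panel <- function(spec) {
  uni <- spec$universe
  wt <- data.frame(residue = uni, stringsAsFactors = FALSE)
  for (m in PANEL_METRICS) wt[[m]] <- unname(PANEL_BASELINES[m])
  class(wt) <- c("ResidueMetricTable", class(wt))
  sdlog <- sqrt(log(1 + spec$noise_cv^2))
  meanlog <- -sdlog^2 / 2                   # mean-1 lognormal
  group_of <- rep(NA_character_, length(uni))
  names(group_of) <- uni
  for (g in names(spec$groups)) group_of[spec$groups[[g]]] <- g
  set.seed(spec$seed)
  classes <- c("pathogenic", "likely_pathogenic", "uncertain",
               "conflicting", "benign")
  aa_pool <- setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z"))
  variants <- data.frame(
    variant = character(0), wt_aa = character(0), position = integer(0),
    mut_aa = character(0), clinvar_class = character(0),
    stringsAsFactors = FALSE)
  deltas <- vector("list", spec$n_variants)
  flags <- list()
  for (v in seq_len(spec$n_variants)) {
    src <- uni[((v - 1) %% length(uni)) + 1]
    wt_aa <- substr(src, 1, 1)
    posn <- suppressWarnings(as.integer(gsub("[^0-9]", "", src)))
    if (is.na(posn)) posn <- v
    mut_aa <- setdiff(aa_pool, wt_aa)[((v - 1) %% 18) + 1]
    vname <- paste0(wt_aa, posn, mut_aa, if (v > length(uni))
      paste0(".", (v - 1) %/% length(uni)) else "")
    variants <- rbind(variants, data.frame(
      variant = vname, wt_aa = wt_aa, position = posn, mut_aa = mut_aa,
      clinvar_class = classes[((v - 1) %% length(classes)) + 1],
      stringsAsFactors = FALSE))
    mut <- wt
    for (r in seq_along(uni)) {
      g <- group_of[uni[r]]
      if (is.na(g)) next
      eff <- spec$effect_sizes[[g]]
      for (m in PANEL_METRICS) {
        mag <- eff * if (spec$noise_cv > 0)
          stats::rlnorm(1, meanlog, sdlog) else 1
        sgn <- if (m %in% c("contacts_mean", "dccm_score")) -1 else 1
        mut[[m]][r] <- wt[[m]][r] * (1 + sgn * mag)
      }
    }
    deltas[[v]] <- delta_metrics(wt, mut)
    lab <- classify_stabilization(deltas[[v]])
    for (m in PANEL_METRICS) {
      flags[[length(flags) + 1]] <- data.frame(
        variant = vname, analysis = m, residue = uni,
        flagged = lab$per_metric[[m]] != "neutral",
        stringsAsFactors = FALSE)
    }
  }
  list(variants = variants, deltas = deltas, wildtype = wt,
       flags = do.call(rbind, flags),
       ground_truth = list(groups = spec$groups,
                           effect_sizes = spec$effect_sizes,
                           expected_ratio =
                             unname(spec$effect_sizes[1] /
                                      spec$effect_sizes[2])))
}

# ---- curated tyrosinase reference sets --------------------------------------

#' Curated human tyrosinase active-site reference sets
#'
#' Machine-readable transcriptions of the reported human tyrosinase
#' interaction data that the analysis operations consume: the 23-residue
#' substrate-interaction set, per-substrate specific residues and the
#' universal triad, the copper-coordinating histidines included by
#' convention, the anchoring-region and gating-loop residue groups used for
#' disruption scoring, the ClinVar missense variant list (the stray
#' "M374,T" entry is normalised to M374T; see `notes`), and species tags
#' for conservation analysis.
#'
#' @return named list of reference sets.
#' @export
tyr_reference_sets <- function() {
  interacting <- c("H180", "S184", "R196", "I198", "D199", "H202", "H211",
                   "K334", "E345", "F347", "A357", "H363", "N364", "H367",
                   "I368", "M374", "S375", "Q376", "V377", "G379", "S380",
                   "F386", "H390")
  specific <- list(
    `L-tyrosine` = c("H180", "G379"),
    `L-DOPA` = c("A357", "H363"),
    DHICA = c("R196"),
    DHI = c("I368", "N364"))
  triad <- c("F347", "H367", "S375")
  variants <- c("H180N", "R196K", "I198N", "I198S", "I198T", "H202Q",
                "H202R", "H202Y", "H211Y", "E345K", "F347L", "H367Q",
                "H367R", "H367Y", "M374T", "S375F", "Q376R", "V377A",
                "V377E", "V377L", "G379A", "G379V", "S380F", "S380P",
                "H390D", "P406L")
  list(
    interacting_residues = interacting,
    substrate_specific = specific,
    universal_triad = triad,
    coordinating_histidines = c("H211", "H390"),
    groups = list(anchoring_334_347 = c("K334", "E345", "F347"),
                  gating_374_386 = c("M374", "S375", "Q376", "V377",
                                     "G379", "S380", "F386")),
    clinvar_variants = variants,
    clinvar_missense_count = length(setdiff(variants, "P406L")),
    vertebrate_species = c("human", "chicken", "mouse", "gorilla",
                           "bovine", "cat", "dog"),
    distant_species = c("Aspergillus", "Neurospora", "Streptomyces"),
    notes = c(M374T = "normalised from the stray comma form 'M374,T'")
  )
}

#' Per-substrate interaction sets assembled from the reference data
#'
#' `"table1"` reproduces the published per-substrate rosters at the level
#' the comparative table states them: each substrate's specific residues
#' plus the universal triad. `"full"` additionally distributes the
#' remaining interaction-set residues (engaged by several but not all
#' substrates; their exact per-substrate rosters are not tabulated) across
#' substrate pairs round-robin, so the union over substrates is the full
#' 23-residue set while the intersection stays the triad and the specific
#' sets stay as documented. Only the shared (non-specific, non-universal)
#' status of those residues is meaningful in the `"full"` sets.
#'
#' @param mode `"table1"` or `"full"`.
#' @return named list of residue-label vectors, one per substrate.
#' @export
tyr_substrate_sets <- function(mode = c("table1", "full")) {
  mode <- match.arg(mode)
  refs <- tyr_reference_sets()
  sets <- lapply(refs$substrate_specific, function(sp)
    unique(c(sp, refs$universal_triad)))
  if (mode == "full") {
    shared_rest <- setdiff(refs$interacting_residues,
                           c(unlist(refs$substrate_specific),
                             refs$universal_triad))
    ns <- length(sets)
    for (k in seq_along(shared_rest)) {
      a <- ((k - 1) %% ns) + 1
      b <- (k %% ns) + 1
      sets[[a]] <- c(sets[[a]], shared_rest[k])
      sets[[b]] <- c(sets[[b]], shared_rest[k])
    }
    sets <- lapply(sets, unique)
  }
  sets
}
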