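#' @importFrom stats sd setNames
#' @importFrom utils read.table write.table
NULL

# internal condition helper: all package errors carry a sub-classable condition
ds_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "dynsite_error")))
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Construct a Structure from an atom table
#'
#' A `Structure` is the package's coordinate container: an ordered atom table
#' with residue grouping derived from `(chain, resseq, icode)` in atom order.
#' Coordinates are in Angstrom throughout; author residue numbering is used
#' for all reporting so residue labels match the literature (e.g. H180, H390).
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resseq`, `icode`, `chain`, `x`, `y`, `z`, `hetero`
#'   (logical). Missing `serial` is filled with `seq_len(n)`; missing
#'   `icode` with `""`; missing `hetero` with `FALSE`.
#' @param metadata free-form provenance list.
#' @return object of class `Structure`.
#' @export
new_structure <- function(atoms, metadata = list()) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$icode)) atoms$icode <- ""
  if (is.null(atoms$hetero)) atoms$hetero <- FALSE
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  atoms$icode[is.na(atoms$icode)] <- ""
  atoms$chain[is.na(atoms$chain)] <- ""
  need <- c("serial", "name", "element", "resname", "resseq", "icode",
            "chain", "x", "y", "z", "hetero")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0)
    ds_stop(paste("atom table missing columns:", paste(miss, collapse = ", ")),
            "dynsite_validation_error")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    ds_stop("non-finite atom coordinates", "dynsite_validation_error")
  if (any(atoms$element == "" | is.na(atoms$element)))
    ds_stop("empty element symbol", "dynsite_validation_error")
  if (anyDuplicated(atoms$serial))
    ds_stop("duplicate atom serial numbers", "dynsite_validation_error")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, metadata = metadata), class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("<Structure: %d atoms, %d residues>\n",
              n_atoms(x), length(unique(residue_keys(x)))))
  invisible(x)
}

#' Number of atoms in a Structure
#' @param structure a `Structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Atom coordinates as an n x 3 matrix
#' @param structure a `Structure`.
#' @return numeric matrix with columns x, y, z in topology order.
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Replace coordinates of a Structure
#' @param structure a `Structure`.
#' @param xyz n x 3 matrix congruent with the atom table.
#' @return the updated `Structure`.
#' @export
set_coords <- function(structure, xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != n_atoms(structure) || ncol(xyz) != 3)
    ds_stop("coordinate matrix not congruent with atom table",
            "dynsite_congruence_error")
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

#' Per-atom residue keys
#'
#' The residue identity key is `(chain, author resseq, insertion code)`,
#' rendered `"chain:resseq:icode"`.
#' @param structure a `Structure`.
#' @return character vector, one key per atom, in atom order.
#' @export
residue_keys <- function(structure) {
  a <- structure$atoms
  paste(a$chain, a$resseq, a$icode, sep = ":")
}

#' Residue table of a Structure
#'
#' One row per residue group in atom order: key, chain, resseq, icode,
#' resname, a one-letter + number label (e.g. `"H367"`) for standard amino
#' acids, and the atom index range.
#' @param structure a `Structure`.
#' @return data.frame, one row per residue.
#' @export
residues <- function(structure) {
  keys <- residue_keys(structure)
  idx <- which(!duplicated(keys))
  a <- structure$atoms
  data.frame(
    key = keys[idx],
    chain = a$chain[idx],
    resseq = a$resseq[idx],
    icode = a$icode[idx],
    resname = a$resname[idx],
    label = residue_label(a$resname[idx], a$resseq[idx]),
    stringsAsFactors = FALSE
  )
}

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' One-letter residue label ("H367") from 3-letter code and author number
#' @param resname character 3-letter codes.
#' @param resseq integer author numbering.
#' @return character labels; non-standard residues keep the 3-letter code.
#' @export
residue_label <- function(resname, resseq) {
  one <- AA3TO1[toupper(resname)]
  one[is.na(one)] <- toupper(resname)[is.na(one)]
  paste0(one, resseq)
}

#' Atom selection specification
#'
#' An empty spec matches all atoms. `atoms` may be the shorthands `"CA"`
#' (alpha carbons of amino acids), `"heavy"` (non-hydrogen), `"sidechain"`
#' (heavy atoms excluding backbone N/CA/C/O/OXT), or a vector of literal
#' atom names.
#'
#' @param chain optional chain id(s) to keep.
#' @param resseq optional integer vector of author residue numbers (use
#'   `a:b` for ranges).
#' @param atoms optional atom-name filter (see Details).
#' @param hetero include HETATM records? Default `TRUE` (empty spec matches
#'   everything); set `FALSE` to restrict to polymer atoms.
#' @return object of class `SelectionSpec`.
#' @export
selection_spec <- function(chain = NULL, resseq = NULL, atoms = NULL,
                           hetero = TRUE) {
  structure(list(chain = chain, resseq = resseq, atoms = atoms,
                 hetero = hetero), class = "SelectionSpec")
}

#' Select atoms of a Structure
#'
#' Deterministic: returns indices in topology order; applying the same spec
#' twice yields the same result, and every output is a subsequence of
#' `1:n_atoms(structure)`.
#'
#' @param structure a `Structure`.
#' @param spec a [selection_spec()]. The default empty spec selects all atoms.
#' @return integer vector of atom indices (possibly empty).
#' @export
select_atoms <- function(structure, spec = selection_spec()) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(spec$chain)) keep <- keep & a$chain %in% spec$chain
  if (!is.null(spec$resseq)) keep <- keep & a$resseq %in% spec$resseq
  if (!isTRUE(spec$hetero)) keep <- keep & !a$hetero
  if (!is.null(spec$atoms)) {
    nm <- toupper(a$name)
    el <- toupper(a$element)
    if (identical(spec$atoms, "CA")) {
      keep <- keep & nm == "CA" & toupper(a$resname) %in% names(AA3TO1)
    } else if (identical(spec$atoms, "heavy")) {
      keep <- keep & el != "H"
    } else if (identical(spec$atoms, "sidechain")) {
      keep <- keep & el != "H" & !(nm %in% BACKBONE_ATOMS)
    } else {
      keep <- keep & nm %in% toupper(spec$atoms)
    }
  }
  which(keep)
}

#' Construct an Ensemble
#'
#' An `Ensemble` couples a reference topology (the t = 0 structure) with a
#' list of coordinate frames sharing the topology's atom order, at strictly
#' increasing times in ns. Under the package's frame-time convention saved
#' snapshots begin at `t = stride` (t = 0 is the reference, not a frame), so
#' a 20 ns run saved every 0.25 ns carries 80 frames.
#'
#' @param topology a `Structure` (reference at t = 0).
#' @param frames list of n x 3 coordinate matrices congruent with the
#'   topology.
#' @param times_ns strictly increasing frame times (ns); default
#'   `stride_ns * seq_along(frames)`.
#' @param stride_ns save stride used for default times (ns).
#' @return object of class `Ensemble`.
#' @export
new_ensemble <- function(topology, frames, times_ns = NULL,
                         stride_ns = 0.25) {
  if (!inherits(topology, "Structure"))
    ds_stop("topology must be a Structure", "dynsite_validation_error")
  if (length(frames) < 1)
    ds_stop("an Ensemble needs at least one frame", "dynsite_validation_error")
  na <- n_atoms(topology)
  for (i in seq_along(frames)) {
    frames[[i]] <- as.matrix(frames[[i]])
    if (nrow(frames[[i]]) != na || ncol(frames[[i]]) != 3)
      ds_stop(sprintf("frame %d has %d atoms; topology has %d",
                      i, nrow(frames[[i]]), na), "dynsite_congruence_error")
  }
  if (is.null(times_ns)) times_ns <- stride_ns * seq_along(frames)
  if (length(times_ns) != length(frames) || any(diff(times_ns) <= 0))
    ds_stop("frame times must be strictly increasing and match frame count",
            "dynsite_validation_error")
  structure(list(topology = topology, frames = frames,
                 times_ns = as.numeric(times_ns)),
            class = "Ensemble")
}

#' @export
print.Ensemble <- function(x, ...) {
  cat(sprintf("<Ensemble: %d frames x %d atoms, t = %.3g..%.3g ns>\n",
              n_frames(x), n_atoms(x$topology),
              min(x$times_ns), max(x$times_ns)))
  invisible(x)
}

#' Number of frames in an Ensemble
#' @param ensemble an `Ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(ensemble) length(ensemble$frames)

#' Extract one frame of an Ensemble as a Structure
#' @param ensemble an `Ensemble`.
#' @param i frame index.
#' @return a `Structure` with the frame's coordinates.
#' @export
frame_structure <- function(ensemble, i) {
  set_coords(ensemble$topology, ensemble$frames[[i]])
}

# ---- PDB I/O (format handling delegated to bio3d) ---------------------------

pdb_precheck <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(is_atom)) {
    fields <- substring(lines[i], c(31, 39, 47), c(38, 46, 54))
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals)))
      ds_stop(sprintf("unparseable coordinate field at line %d of %s",
                      i, path), "dynsite_format_error")
  }
  # MODEL congruence: count coordinate records per MODEL block
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1) {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) == length(model_starts)) {
      counts <- mapply(function(s, e) sum(is_atom[s:e]),
                       model_starts, model_ends)
      if (length(unique(counts)) > 1)
        ds_stop(sprintf(
          "MODEL blocks differ in atom count (%s) in %s",
          paste(unique(counts), collapse = " vs "), path),
          "dynsite_congruence_error")
    }
  }
  invisible(length(model_starts))
}

bio3d_to_atoms <- function(atom) {
  el <- trimws(atom$elesy)
  guess <- el == "" | is.na(el)
  if (any(guess)) {
    # fall back to the leading letter(s) of the atom name
    nm <- gsub("[0-9']", "", trimws(atom$elety[guess]))
    el[guess] <- ifelse(substr(nm, 1, 2) %in% c("CU", "FE", "ZN", "MG"),
                        substr(nm, 1, 2), substr(nm, 1, 1))
  }
  data.frame(
    serial = atom$eleno,
    name = trimws(atom$elety),
    element = toupper(el),
    resname = trimws(atom$resid),
    resseq = atom$resno,
    icode = ifelse(is.na(atom$insert) | atom$insert == " ", "", atom$insert),
    chain = ifelse(is.na(atom$chain), "", atom$chain),
    x = atom$x, y = atom$y, z = atom$z,
    hetero = atom$type == "HETATM",
    occupancy = ifelse(is.na(atom$o), 1, atom$o),
    stringsAsFactors = FALSE
  )
}

# altloc policy: keep the highest-occupancy conformer per
# (chain, resseq, icode, atom name); ties broken by altloc letter
resolve_altloc <- function(atom) {
  alt <- ifelse(is.na(atom$alt), "", atom$alt)
  if (all(alt == "")) return(seq_len(nrow(atom)))
  grp <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "|")
  occ <- ifelse(is.na(atom$o), 1, atom$o)
  keep <- rep(TRUE, nrow(atom))
  for (g in unique(grp[alt != ""])) {
    idx <- which(grp == g)
    if (length(idx) < 2) next
    best <- idx[order(-occ[idx], alt[idx])][1]
    keep[setdiff(idx, best)] <- FALSE
  }
  which(keep)
}

#' Read a PDB file as a Structure or Ensemble
#'
#' Single-MODEL files yield a `Structure`; multi-MODEL files yield an
#' `Ensemble` whose frame times follow the caller-supplied save stride,
#' starting at `t = stride` for the first MODEL. Atom order is preserved
#' verbatim. When alternate locations are present, the highest-occupancy
#' conformer is kept (ties broken by altloc letter).
#'
#' @param path PDB file path.
#' @param stride_ns save stride for frame-time assignment (ns).
#' @return a `Structure` or an `Ensemble`.
#' @export
read_pdb <- function(path, stride_ns = 0.25) {
  if (!file.exists(path))
    ds_stop(paste("file not found:", path), "dynsite_io_error")
  pdb_precheck(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                         verbose = FALSE)
  keep <- resolve_altloc(pdb$atom)
  atoms <- bio3d_to_atoms(pdb$atom[keep, , drop = FALSE])
  nmod <- nrow(pdb$xyz)
  if (is.null(nmod) || nmod <= 1) {
    return(new_structure(atoms, metadata = list(source = path)))
  }
  xyz_cols <- as.vector(rbind(3 * keep - 2, 3 * keep - 1, 3 * keep))
  frames <- lapply(seq_len(nmod), function(m) {
    matrix(pdb$xyz[m, xyz_cols], ncol = 3, byrow = TRUE)
  })
  topo <- new_structure(atoms, metadata = list(source = path))
  topo <- set_coords(topo, frames[[1]])
  new_ensemble(topo, frames, stride_ns = stride_ns)
}

#' Write a Structure or Ensemble to a PDB file
#'
#' Ensembles are written as multi-MODEL files. Coordinates survive a
#' read/write round trip to 3 decimals (the PDB fixed-width precision).
#'
#' @param x a `Structure` or `Ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "Ensemble")) {
    a <- x$topology$atoms
    xyz <- do.call(rbind, lapply(x$frames, function(f) as.vector(t(f))))
  } else if (inherits(x, "Structure")) {
    a <- x$atoms
    xyz <- matrix(as.vector(t(coords(x))), nrow = 1)
  } else {
    ds_stop("write_pdb needs a Structure or Ensemble",
            "dynsite_validation_error")
  }
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = ifelse(a$hetero, "HETATM", "ATOM"),
                   eleno = a$serial, elety = a$name, resid = a$resname,
                   chain = a$chain, resno = a$resseq,
                   insert = ifelse(a$icode == "", NA, a$icode),
                   o = a$occupancy, b = rep(0, nrow(a)), elesy = a$element)
  invisible(path)
}

# ---- rigid-body superposition ----------------------------------------------

#' Kabsch least-squares rigid superposition
#'
#' Closed-form SVD solution for the proper rotation and translation
#' minimising the RMSD between `mobile` and `reference` over `fit_indices`.
#' The returned transform maps mobile coordinates onto the reference frame:
#' `x' = R (x - mobile_centroid) + reference_centroid`.
#'
#' @param mobile n x 3 coordinate matrix.
#' @param reference n x 3 coordinate matrix congruent with `mobile`.
#' @param fit_indices atom indices used for the fit (default: all).
#' @return list with `rotation` (3 x 3, det +1), `translation` (length-3;
#'   `x' = R x + translation`), `fit_rmsd` (Angstrom) and `coords` (the
#'   superposed mobile coordinates).
#' @export
kabsch_superpose <- function(mobile, reference, fit_indices = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(fit_indices)) fit_indices <- seq_len(nrow(mobile))
  if (length(fit_indices) < 3)
    ds_stop("superposition needs at least 3 fit points",
            "dynsite_degeneracy_error")
  if (max(fit_indices) > nrow(mobile) || max(fit_indices) > nrow(reference))
    ds_stop("fit indices out of range", "dynsite_congruence_error")
  m <- mobile[fit_indices, , drop = FALSE]
  r <- reference[fit_indices, , drop = FALSE]
  mc <- colMeans(m); rc <- colMeans(r)
  m0 <- sweep(m, 2, mc); r0 <- sweep(r, 2, rc)
  if (svd(m0)$d[2] < 1e-8 || svd(r0)$d[2] < 1e-8)
    ds_stop("fit points are collinear", "dynsite_degeneracy_error")
  H <- crossprod(m0, r0)                 # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sup_fit <- m0 %*% t(R)
  fit_rmsd <- sqrt(mean(rowSums((sup_fit - r0)^2)))
  all_sup <- sweep(sweep(mobile, 2, mc) %*% t(R), 2, rc, "+")
  list(rotation = R, translation = as.numeric(rc - R %*% mc),
       fit_rmsd = fit_rmsd, coords = all_sup)
}
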