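# Fixtures built in code and independent brute-force oracles.

# minimal atom-table builder
atom_row <- function(serial, name, element, resname, resseq, chain,
                     x, y, z, hetero = FALSE, icode = "") {
  data.frame(serial = serial, name = name, element = element,
             resname = resname, resseq = resseq, icode = icode,
             chain = chain, x = x, y = y, z = z, hetero = hetero,
             stringsAsFactors = FALSE)
}

# n isolated "residues" (single carbon atoms) on a wide grid
carbon_grid <- function(n, spacing = 20) {
  do.call(rbind, lapply(seq_len(n), function(i)
    atom_row(i, "C1", "C", "LIG", i, "A", i * spacing, 0, 0, hetero = TRUE)))
}

random_rigid_transform <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  list(R = R, t = rnorm(3, sd = 5))
}

apply_rigid <- function(xyz, tr) sweep(xyz %*% t(tr$R), 2, tr$t, "+")

# --- independent oracles -----------------------------------------------------

# exhaustive rotation-grid Kabsch RMSD oracle (multi-resolution Euler grid)
oracle_kabsch_rmsd <- function(mobile, reference) {
  m0 <- sweep(mobile, 2, colMeans(mobile))
  r0 <- sweep(reference, 2, colMeans(reference))
  euler_rot <- function(a, b, g) {
    ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
    cg <- cos(g); sg <- sin(g)
    Rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, 3, byrow = TRUE)
    Rz2 <- matrix(c(cg, -sg, 0, sg, cg, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  rmsd_at <- function(a, b, g)
    sqrt(mean(rowSums((m0 %*% t(euler_rot(a, b, g)) - r0)^2)))
  best <- c(0, 0, 0); best_v <- Inf
  step <- 10 * pi / 180
  grid_a <- seq(0, 2 * pi, by = step)
  grid_b <- seq(0, pi, by = step)
  for (a in grid_a) for (b in grid_b) for (g in grid_a) {
    v <- rmsd_at(a, b, g)
    if (v < best_v) { best_v <- v; best <- c(a, b, g) }
  }
  # refine on successively finer grids, re-centring until stationary
  for (s in c(2, 0.4, 0.08, 0.016, 0.003) * pi / 180) {
    gr <- seq(-5 * s, 5 * s, by = s)
    repeat {
      improved <- FALSE
      for (da in gr) for (db in gr) for (dg in gr) {
        v <- rmsd_at(best[1] + da, best[2] + db, best[3] + dg)
        if (v < best_v - 1e-15) {
          best_v <- v; cand <- best + c(da, db, dg); improved <- TRUE
        }
      }
      if (!improved) break
      best <- cand
    }
  }
  best_v
}

# brute-force all-pairs contact count with the documented exclusions
oracle_contact_count <- function(structure, residue_label, cutoff = 5,
                                 covalent_max = 1.7) {
  a <- structure$atoms
  heavy <- which(toupper(a$element) != "H")
  keys <- residue_keys(structure)
  res <- residues(structure)
  key <- res$key[res$label == residue_label]
  cnt <- 0
  for (i in heavy) {
    if (keys[i] != key) next
    for (j in heavy) {
      if (keys[j] == key) next
      d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) -
                       c(a$x[j], a$y[j], a$z[j]))^2))
      if (d > cutoff || d < covalent_max) next
      pep <- a$chain[i] == a$chain[j] &&
        ((a$resseq[j] - a$resseq[i] == 1 && a$name[i] == "C" &&
            a$name[j] == "N") ||
           (a$resseq[i] - a$resseq[j] == 1 && a$name[i] == "N" &&
              a$name[j] == "C"))
      if (!pep) cnt <- cnt + 1
    }
  }
  cnt
}

# nested-mean disruption score oracle (straight loops)
oracle_disruption_ratio <- function(variant_deltas, groups) {
  sign_of <- c(rmsd_mean = 1, rmsf = 1, sasa_mean = 1,
               contacts_mean = -1, dccm_score = -1)
  all_res <- sort(unique(unlist(lapply(variant_deltas, `[[`, "residues"))))
  res_means <- sapply(all_res, function(r) {
    per_var <- sapply(variant_deltas, function(rep) {
      if (!r %in% rep$residues) return(NA_real_)
      vals <- sapply(rep$metrics, function(m) {
        d <- rep$delta[[m]][rep$residues == r]
        ref <- abs(rep$reference[[m]][rep$residues == r])
        if (is.na(ref) || ref == 0) return(NA_real_)
        sign_of[[m]] * d / ref
      })
      mean(vals, na.rm = TRUE)
    })
    mean(per_var, na.rm = TRUE)
  })
  gsc <- sapply(groups, function(g) mean(res_means[g]))
  unname(gsc[1] / gsc[2])
}

# pooled two-sample t and regularized-incomplete-beta p (closed form)
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  p <- pbeta(df / (df + t^2), df / 2, 1 / 2)
  list(t = t, p = p)
}

# spherical-cap closed form: total area of two equal overlapping spheres
two_sphere_area <- function(r, d) {
  2 * 4 * pi * r^2 - 2 * 2 * pi * r * (r - d / 2)
}

# tiny multi-MODEL PDB text written directly (for parser edge cases)
write_pdb_text <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

pdb_atom_line <- function(serial, name, resname, chain, resseq, x, y, z,
                          element = substr(name, 1, 1)) {
  sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, resname, chain, resseq, x, y, z, element)
}
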