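# Comparative analytics between systems (apo vs bound, wild-type vs
# variant): delta-metrics, stabilization labels, perturbation summaries,
# the group-level disruption score, significance testing, normalisations,
# correlation, and conservation tallies.

DELTA_METRICS <- c("rmsd_mean", "rmsf", "sasa_mean", "contacts_mean",
                   "dccm_score")
# destabilising direction per metric: +1 means an increase destabilises
DESTAB_SIGN <- c(rmsd_mean = 1, rmsf = 1, sasa_mean = 1,
                 contacts_mean = -1, dccm_score = -1)

#' Per-residue metric differences between two systems
#'
#' Computes `delta = B - A` per residue per metric for the metric columns
#' the tables share. Missing metrics propagate as `NA`, never zero. The
#' reference (system A) values are retained for downstream normalisation.
#'
#' @param table_a,table_b metric tables (data.frames with a `residue`
#'   column; e.g. from [residue_metric_table()]). A is the reference
#'   (wild-type / apo) system.
#' @param metrics metric columns to compare (default: the intersection of
#'   the standard metric set with both tables).
#' @return object of class `DeltaReport`: list with `residues`, `delta`
#'   (residues x metrics data.frame), `reference` (system-A values),
#'   `metrics`.
#' @export
delta_metrics <- function(table_a, table_b, metrics = NULL) {
  shared_res <- intersect(table_a$residue, table_b$residue)
  if (length(shared_res) == 0)
    ds_stop("tables share no residues", "dynsite_empty_comparison_error")
  if (is.null(metrics))
    metrics <- intersect(DELTA_METRICS,
                         intersect(names(table_a), names(table_b)))
  ia <- match(shared_res, table_a$residue)
  ib <- match(shared_res, table_b$residue)
  delta <- as.data.frame(lapply(metrics, function(m)
    table_b[[m]][ib] - table_a[[m]][ia]))
  refv <- as.data.frame(lapply(metrics, function(m) table_a[[m]][ia]))
  names(delta) <- names(refv) <- metrics
  rownames(delta) <- rownames(refv) <- shared_res
  structure(list(residues = shared_res, delta = delta, reference = refv,
                 metrics = metrics),
            class = "DeltaReport")
}

neutral_band <- function(ref, rel_tol = 0.01, abs_tol = 1e-9) {
  pmax(abs(ref) * rel_tol, abs_tol)
}

#' Stabilization labels from a DeltaReport
#'
#' Sign convention: increases in RMSD, RMSF and SASA are destabilising;
#' decreases in contacts and DCCM are loss of structural coupling and thus
#' destabilising. A delta within the neutral band (`rel_tol` of the
#' reference value, or `abs_tol` when the reference is 0) is neutral. A
#' residue counts as "stabilized in at least one metric" when any metric
#' moves in the stabilising direction beyond tolerance.
#'
#' @param report a `DeltaReport`.
#' @param rel_tol relative neutral-band width.
#' @param abs_tol absolute neutral-band floor.
#' @return list with `per_metric` (named list of label vectors over
#'   residues), `overall` (per-residue summary label), `stabilized_any`,
#'   `destabilized_any` (logical vectors), and `counts`.
#' @export
classify_stabilization <- function(report, rel_tol = 0.01,
                                   abs_tol = 1e-9) {
  res <- report$residues
  per_metric <- list()
  stab_n <- destab_n <- setNames(rep(0L, length(res)), res)
  for (m in report$metrics) {
    d <- report$delta[[m]]
    band <- neutral_band(report$reference[[m]], rel_tol, abs_tol)
    adj <- DESTAB_SIGN[[m]] * d            # positive = destabilising
    lab <- ifelse(is.na(d) | abs(d) <= band, "neutral",
                  ifelse(adj > 0, "destabilizing", "stabilizing"))
    per_metric[[m]] <- setNames(lab, res)
    stab_n <- stab_n + (lab == "stabilizing")
    destab_n <- destab_n + (lab == "destabilizing")
  }
  overall <- ifelse(stab_n + destab_n == 0, "neutral",
                    ifelse(destab_n > stab_n, "destabilizing",
                           ifelse(stab_n > destab_n, "stabilizing",
                                  "mixed")))
  list(per_metric = per_metric,
       overall = setNames(overall, res),
       stabilized_any = stab_n > 0,
       destabilized_any = destab_n > 0,
       counts = list(stabilizing = stab_n, destabilizing = destab_n))
}

#' Per-variant perturbation summary
#'
#' For each variant and analysis type, the fraction of universe residues
#' flagged as perturbed; the grand mean of those fractions across analysis
#' types; and a flag for grand means above the threshold (strictly
#' greater, mirroring an "over 50 percent" reading).
#'
#' @param flags long data.frame with columns `variant`, `analysis`,
#'   `residue`, `flagged` (logical).
#' @param universe residue labels defining the denominator.
#' @param threshold grand-mean flag threshold (fraction).
#' @return data.frame with one row per variant x analysis plus per-variant
#'   `grand_mean` and `above_threshold` in the `summary` attribute (also
#'   returned as list entries `fractions` and `summary`).
#' @export
perturbation_summary <- function(flags, universe, threshold = 0.5) {
  if (length(universe) == 0)
    ds_stop("empty residue universe", "dynsite_validation_error")
  variants <- unique(flags$variant)
  analyses <- unique(flags$analysis)
  fr <- expand.grid(variant = variants, analysis = analyses,
                    stringsAsFactors = FALSE)
  fr$fraction <- vapply(seq_len(nrow(fr)), function(i) {
    sub <- flags[flags$variant == fr$variant[i] &
                   flags$analysis == fr$analysis[i] &
                   flags$residue %in% universe & flags$flagged, ,
                 drop = FALSE]
    length(unique(sub$residue)) / length(universe)
  }, numeric(1))
  no_flag <- variants[!variants %in% flags$variant[flags$flagged]]
  if (length(no_flag) > 0)
    warning(sprintf("variant(s) with no perturbation flags: %s",
                    paste(no_flag, collapse = ", ")))
  summ <- data.frame(
    variant = variants,
    grand_mean = vapply(variants, function(v)
      mean(fr$fraction[fr$variant == v]), numeric(1)),
    stringsAsFactors = FALSE)
  summ$above_threshold <- summ$grand_mean > threshold
  list(fractions = fr, summary = summ, threshold = threshold,
       universe_size = length(universe))
}

#' Destabilisation magnitudes of a DeltaReport
#'
#' Commensuration used by [disruption_score()]: each delta is sign-adjusted
#' so positive means destabilising, then divided by the absolute reference
#' (wild-type) value of that metric for that residue. Residues whose
#' reference value is 0 fall back to a z-score across the report's
#' residues.
#'
#' @param report a `DeltaReport`.
#' @return residues x metrics matrix of dimensionless magnitudes.
#' @export
destabilization_magnitudes <- function(report) {
  out <- matrix(NA_real_, length(report$residues), length(report$metrics),
                dimnames = list(report$residues, report$metrics))
  for (m in report$metrics) {
    adj <- DESTAB_SIGN[[m]] * report$delta[[m]]
    ref <- abs(report$reference[[m]])
    v <- adj / ref
    zero_ref <- !is.na(ref) & ref == 0
    if (any(zero_ref)) {
      s <- sd(adj, na.rm = TRUE)
      v[zero_ref] <- if (is.na(s) || s == 0) 0 else
        (adj[zero_ref] - mean(adj, na.rm = TRUE)) / s
    }
    out[, m] <- v
  }
  out
}

#' Group-level mutation disruption score
#'
#' Destabilisation magnitudes (see [destabilization_magnitudes()]) are
#' averaged across metrics per residue per variant, then across variants
#' per residue, then across residues per group; the ratio of the first to
#' the second group's score is reported.
#'
#' @param variant_deltas list of `DeltaReport` objects, one per variant.
#' @param groups named list of residue-label vectors (non-overlapping);
#'   the ratio is `groups[[1]] / groups[[2]]`.
#' @return object of class `DisruptionReport`: list with `residue_means`,
#'   `group_scores`, `ratio`, `groups`, `n_variants`.
#' @export
disruption_score <- function(variant_deltas, groups) {
  if (anyDuplicated(unlist(groups)))
    ds_stop("groups must not overlap", "dynsite_validation_error")
  all_res <- sort(unique(unlist(lapply(variant_deltas, `[[`, "residues"))))
  missing <- setdiff(unlist(groups), all_res)
  if (length(missing) > 0)
    ds_stop(paste("group residue(s) absent from all deltas:",
                  paste(missing, collapse = ", ")),
            "dynsite_validation_error")
  per_variant <- lapply(variant_deltas, function(rep) {
    mags <- destabilization_magnitudes(rep)
    rowMeans(mags, na.rm = TRUE)           # across metrics, per residue
  })
  residue_means <- vapply(all_res, function(r) {
    vals <- vapply(per_variant, function(pv)
      if (r %in% names(pv)) pv[[r]] else NA_real_, numeric(1))
    mean(vals, na.rm = TRUE)               # across variants
  }, numeric(1))
  group_scores <- vapply(groups, function(g)
    mean(residue_means[g]), numeric(1))    # across residues
  ratio <- if (length(group_scores) >= 2 && group_scores[2] > 0)
    unname(group_scores[1] / group_scores[2]) else NA_real_
  structure(list(residue_means = residue_means,
                 group_scores = group_scores, ratio = ratio,
                 groups = groups, n_variants = length(variant_deltas)),
            class = "DisruptionReport")
}

#' @export
print.DisruptionReport <- function(x, ...) {
  cat(sprintf("<DisruptionReport: %d variants; group scores %s; ratio %.3g>\n",
              x$n_variants,
              paste(sprintf("%s=%.4g", names(x$group_scores),
                            x$group_scores), collapse = ", "),
              x$ratio))
  invisible(x)
}

#' Two-sample Student's t-test on per-interval series
#'
#' Pooled-variance two-sample t with two-tailed p, plus the conventional
#' star label (p < 0.05: `*`, < 0.01: `**`, < 0.001: `***`). Welch's
#' unequal-variance form is available behind `welch = TRUE`. Zero pooled
#' variance with equal means yields t = 0, p = 1; with unequal means the
#' infinite-t case is flagged (`t = Inf`/`-Inf`, p = 0).
#'
#' @param series_a,series_b numeric vectors (length >= 2 each).
#' @param welch use Welch's unequal-variance t instead of pooled?
#' @return list with `t`, `p`, `stars`, `df`.
#' @export
rmsd_ttest <- function(series_a, series_b, welch = FALSE) {
  if (length(series_a) < 2 || length(series_b) < 2)
    ds_stop("both series need length >= 2", "dynsite_validation_error")
  if (sd(series_a) == 0 && sd(series_b) == 0) {
    if (mean(series_a) == mean(series_b))
      return(list(t = 0, p = 1, stars = "",
                  df = length(series_a) + length(series_b) - 2))
    return(list(t = sign(mean(series_b) - mean(series_a)) * Inf, p = 0,
                stars = "***",
                df = length(series_a) + length(series_b) - 2))
  }
  ht <- stats::t.test(series_b, series_a, var.equal = !welch)
  p <- ht$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else ""
  list(t = unname(ht$statistic), p = p, stars = stars,
       df = unname(ht$parameter))
}

#' Squared Pearson correlation
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return R squared in [0, 1].
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    ds_stop("need equal-length vectors of length >= 3",
            "dynsite_validation_error")
  if (sd(x) == 0 || sd(y) == 0)
    ds_stop("zero variance: correlation undefined",
            "dynsite_undefined_correlation_error")
  stats::cor(x, y)^2
}

#' Normalise an unfolding-mutation-screen value to percent
#' @param raw UMS value in [0, 1].
#' @return percent (raw x 100).
#' @export
normalize_ums <- function(raw) {
  if (any(raw < 0 | raw > 1))
    ds_stop("UMS values must lie in [0, 1]", "dynsite_validation_error")
  raw * 100
}

#' Express a foldability value as percent of the reference maximum
#'
#' The reference maximum is 19; values above 100 percent are flagged via
#' the `above_max` attribute.
#'
#' @param raw foldability value (>= 0).
#' @param reference_max reference maximum.
#' @return percent, with attribute `above_max`.
#' @export
foldability_percent <- function(raw, reference_max = 19) {
  if (any(raw < 0))
    ds_stop("foldability values must be >= 0", "dynsite_validation_error")
  out <- raw / reference_max * 100
  attr(out, "above_max") <- out > 100
  out
}

# ---- conservation -----------------------------------------------------------

#' Read an alignment (aligned FASTA or Clustal) as a character matrix
#' @param path alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @return rows x columns character matrix with sequence names as rownames.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  aln <- seqinr::read.alignment(path, format = format)
  seqs <- toupper(unlist(aln$seq))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1)
    ds_stop("ragged alignment: sequences differ in length",
            "dynsite_format_error")
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- aln$nam
  m
}

#' Classify conservation of reference positions
#'
#' For each ungapped reference position: `conserved_distant` when the
#' column is identical across all rows, else `conserved_vertebrate` when
#' identical across the vertebrate-tagged rows, else `not_conserved`. A
#' gap in any considered row breaks identity; ambiguity codes (X, B, Z)
#' count as mismatches.
#'
#' @param alignment character matrix (from [read_alignment()]) or named
#'   character vector of aligned sequences.
#' @param reference row name of the reference sequence.
#' @param vertebrate_rows row names forming the vertebrate set.
#' @return data.frame with `position` (ungapped reference numbering),
#'   `column`, `residue`, `class`.
#' @export
conservation_classify <- function(alignment, reference, vertebrate_rows) {
  if (!is.matrix(alignment)) {
    lens <- nchar(alignment)
    if (length(unique(lens)) != 1)
      ds_stop("ragged alignment: sequences differ in length",
              "dynsite_format_error")
    nm <- names(alignment)
    alignment <- do.call(rbind, strsplit(toupper(alignment), ""))
    rownames(alignment) <- nm
  }
  if (!reference %in% rownames(alignment))
    ds_stop(paste("reference row not in alignment:", reference),
            "dynsite_validation_error")
  vert <- intersect(vertebrate_rows, rownames(alignment))
  refrow <- alignment[reference, ]
  gap <- c("-", ".")
  ambiguous <- c("X", "B", "Z")
  ungapped <- which(!refrow %in% gap)
  identical_over <- function(col, rows) {
    v <- alignment[rows, col]
    if (any(v %in% gap) || any(v %in% ambiguous)) return(FALSE)
    length(unique(v)) == 1
  }
  cls <- vapply(ungapped, function(col) {
    if (identical_over(col, rownames(alignment))) "conserved_distant"
    else if (length(vert) > 0 && identical_over(col, vert))
      "conserved_vertebrate"
    else "not_conserved"
  }, character(1))
  data.frame(position = seq_along(ungapped), column = ungapped,
             residue = refrow[ungapped], class = cls,
             stringsAsFactors = FALSE)
}

#' Read a variant list TSV
#'
#' Expected columns: `wt_aa`, `position`, `mut_aa`, `clinvar_class`, and
#' optionally `ums` (in [0, 1]) and `foldability` (>= 0).
#'
#' @param path TSV path.
#' @return data.frame of variant records with a derived `variant` label.
#' @export
read_variant_table <- function(path) {
  v <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                  stringsAsFactors = FALSE)
  need <- c("wt_aa", "position", "mut_aa", "clinvar_class")
  miss <- setdiff(need, names(v))
  if (length(miss) > 0)
    ds_stop(paste("variant table missing columns:",
                  paste(miss, collapse = ", ")), "dynsite_format_error")
  if (any(v$position <= 0))
    ds_stop("positions must be positive", "dynsite_validation_error")
  if (!is.null(v$ums) && any(!is.na(v$ums) & (v$ums < 0 | v$ums > 1)))
    ds_stop("UMS values must lie in [0, 1]", "dynsite_validation_error")
  v$variant <- paste0(v$wt_aa, v$position, v$mut_aa)
  v
}
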