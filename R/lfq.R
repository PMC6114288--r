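#' Build an ion-by-sample quantitation matrix from evidence rows
#'
#' The ion identity is the (peptide sequence, charge, m/z) triple. Multiple
#' evidence rows (spectra) of the same ion in the same sample are repeated
#' measurements of the same eluting species and are aggregated by their mean,
#' which keeps the per-sample ion intensity proportional to ion abundance
#' regardless of how often data-dependent acquisition resampled the ion.
#' Zero intensities mean "identified, not quantified" and are stored as
#' missing values; no imputation is performed anywhere downstream.
#'
#' @param ev filtered evidence tibble.
#' @param design sample design tibble (\code{sample_id}, \code{condition},
#'   \code{replicate}).
#' @return a \code{quant_matrix}: list with \code{values} (numeric matrix,
#'   ions x samples, NA = missing), \code{ions} (tibble \code{peptide_seq},
#'   \code{charge}, \code{mz}), \code{design}, \code{stage = "raw"}.
#' @export
build_quant_matrix <- function(ev, design) {
  design <- validate_design(design)
  ev <- ev[ev$intensity > 0, , drop = FALSE]
  ion <- sprintf("%s/%s/%s", ev$peptide_seq, ev$charge, format(ev$mz))
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(ion = ion,
                                   peptide_seq = ev$peptide_seq,
                                   charge = ev$charge, mz = ev$mz,
                                   sample_id = ev$sample_id,
                                   intensity = ev$intensity),
                    ion, peptide_seq, charge, mz, sample_id),
    intensity = mean(intensity), .groups = "drop")
  ions <- dplyr::distinct(agg, ion, peptide_seq, charge, mz) |>
    dplyr::arrange(ion)
  values <- matrix(NA_real_, nrow = nrow(ions), ncol = nrow(design),
                   dimnames = list(ions$ion, design$sample_id))
  values[cbind(match(agg$ion, ions$ion),
               match(agg$sample_id, design$sample_id))] <- agg$intensity
  structure(list(values = values,
                 ions = dplyr::select(ions, peptide_seq, charge, mz),
                 design = design, stage = "raw"),
            class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("quant_matrix: %d ions x %d samples, stage '%s'\n",
              nrow(x$values), ncol(x$values), x$stage))
  invisible(x)
}

#' Normalize ion intensities to the sample total
#'
#' Within each sample, every ion intensity is divided by the total ion
#' intensity of that sample, so per-sample column sums over observed entries
#' equal 1. This absorbs any constant per-sample loading or instrument
#' response factor.
#'
#' @param qm a raw \code{quant_matrix}.
#' @return the matrix at stage \code{"normalized"}.
#' @export
normalize_total <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  totals <- colSums(qm$values, na.rm = TRUE)
  zero <- totals <= 0
  if (any(zero)) {
    stop(sprintf("sample '%s' has zero total intensity",
                 colnames(qm$values)[which(zero)[1]]))
  }
  qm$values <- sweep(qm$values, 2L, totals, "/")
  qm$stage <- "normalized"
  qm
}

treatment_means <- function(values, design, conditions) {
  vapply(conditions, function(cc) {
    cols <- design$sample_id[design$condition == cc]
    rowMeans(values[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(values)))
}

#' Scale each ion against its cross-treatment average
#'
#' For each ion the mean normalized intensity is computed per treatment
#' (condition), then the grand mean over the treatments in which the ion was
#' observed; every entry is divided by that grand mean. Ions observed in no
#' sample are dropped. After scaling, the per-ion mean of treatment averages
#' equals 1 for ions observed in all treatments.
#'
#' @param qm a normalized \code{quant_matrix}.
#' @return the matrix at stage \code{"scaled"}.
#' @export
scale_across_treatments <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  conditions <- unique(qm$design$condition)
  tm <- treatment_means(qm$values, qm$design, conditions)
  tm[is.nan(tm)] <- NA_real_
  grand <- rowMeans(tm, na.rm = TRUE)
  observed <- !is.nan(grand) & !is.na(grand) & grand > 0
  qm$values <- qm$values[observed, , drop = FALSE] / grand[observed]
  qm$ions <- qm$ions[observed, , drop = FALSE]
  qm$stage <- "scaled"
  qm
}

#' Average scaled intensities over biological replicates
#'
#' Per ion and condition, the arithmetic mean over replicates with an
#' observation; conditions with fewer than \code{min_reps} observations are
#' marked missing. The default of 3 reflects designs with at least three
#' biological replicates per condition.
#'
#' @param qm a scaled \code{quant_matrix}.
#' @param min_reps minimum observed replicates per condition (default 3).
#' @return \code{quant_matrix} at stage \code{"averaged"} whose columns are
#'   conditions.
#' @export
average_replicates <- function(qm, min_reps = 3L) {
  stopifnot(inherits(qm, "quant_matrix"), min_reps >= 1L)
  conditions <- unique(qm$design$condition)
  avg <- vapply(conditions, function(cc) {
    cols <- qm$design$sample_id[qm$design$condition == cc]
    sub <- qm$values[, cols, drop = FALSE]
    n_obs <- rowSums(!is.na(sub))
    m <- rowMeans(sub, na.rm = TRUE)
    m[n_obs < min_reps] <- NA_real_
    m
  }, numeric(nrow(qm$values)))
  dimnames(avg) <- list(rownames(qm$values), conditions)
  structure(list(values = avg, ions = qm$ions,
                 design = tibble::tibble(sample_id = conditions,
                                         condition = conditions,
                                         replicate = NA_integer_),
                 stage = "averaged"),
            class = "quant_matrix")
}

proteotypic_map <- function(assignments) {
  asn <- assignments[assignments$proteotypic, , drop = FALSE]
  tibble::tibble(peptide_seq = asn$peptide_seq,
                 protein_id = vapply(asn$protein_ids, `[`, character(1), 1L))
}

#' Protein intensity sums over proteotypic ions
#'
#' Per protein and condition, the sum of averaged scaled intensities of all
#' proteotypic ions; shared ions are excluded. Proteins with no proteotypic
#' ion are omitted. \code{log2_ratio} = log2(acidic sum / alkaline sum),
#' finite only when both sums are positive.
#'
#' @param qm_avg an averaged \code{quant_matrix} (see [average_replicates()]).
#' @param assignments tibble from [map_peptides()].
#' @param conditions two condition labels, numerator first.
#' @return tibble \code{protein_id}, one mean column per condition,
#'   \code{log2_ratio}, \code{n_peptides}.
#' @export
protein_sums <- function(qm_avg, assignments,
                         conditions = c("acidic", "alkaline")) {
  stopifnot(inherits(qm_avg, "quant_matrix"), qm_avg$stage == "averaged")
  pmap <- proteotypic_map(assignments)
  idx <- match(qm_avg$ions$peptide_seq, pmap$peptide_seq)
  keep <- !is.na(idx)
  if (!any(keep)) stop("no proteotypic ions available")
  prot <- pmap$protein_id[idx[keep]]
  vals <- qm_avg$values[keep, conditions, drop = FALSE]
  out <- lapply(split(seq_along(prot), prot), function(rows) {
    sums <- colSums(vals[rows, , drop = FALSE], na.rm = TRUE)
    obs <- colSums(!is.na(vals[rows, , drop = FALSE]))
    sums[obs == 0L] <- NA_real_
    c(sums, n_peptides = length(rows))
  })
  res <- tibble::tibble(protein_id = names(out))
  for (cc in conditions) {
    res[[cc]] <- unname(vapply(out, `[[`, numeric(1), cc))
  }
  res$log2_ratio <- ifelse(
    !is.na(res[[conditions[1]]]) & !is.na(res[[conditions[2]]]) &
      res[[conditions[1]]] > 0 & res[[conditions[2]]] > 0,
    log2(res[[conditions[1]]] / res[[conditions[2]]]), NA_real_)
  res$n_peptides <- unname(as.integer(
    vapply(out, `[[`, numeric(1), "n_peptides")))
  res
}

welch_p <- function(x, y) {
  # two-sided Welch t on log-transformed values, with the degenerate cases
  # resolved explicitly: no spread and equal means -> 1; no spread and
  # different means -> smallest representable p (flagged upstream).
  if (length(x) < 2L || length(y) < 2L) return(NA_real_)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else .Machine$double.xmin)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    # t.test errors on constant data; fall back to the one-sample form
    # against the constant group's value.
    const <- if (stats::sd(x) == 0) x[1] else y[1]
    varying <- if (stats::sd(x) == 0) y else x
    return(stats::t.test(varying, mu = const)$p.value)
  }
  stats::t.test(x, y)$p.value
}

#' Differential acidic/alkaline statistics
#'
#' Two-sided Welch t-test on natural-log-transformed replicate-level scaled
#' values, at the ion level or on replicate-wise proteotypic protein sums.
#' Reported \code{log2_ratio} is log2 of the ratio of condition means of the
#' (unlogged) scaled values. p-values are raw by default, matching a raw
#' p = 0.05 threshold; Benjamini-Hochberg adjustment is available via
#' \code{adjust}.
#'
#' @param qm_scaled a scaled \code{quant_matrix}.
#' @param level \code{"ion"} or \code{"protein"}.
#' @param assignments required for protein level.
#' @param conditions two condition labels, numerator first.
#' @param adjust apply Benjamini-Hochberg correction (default FALSE).
#' @return tibble \code{feature}, \code{log2_ratio}, \code{p_value}
#'   (plus \code{p_adj} when \code{adjust}).
#' @export
differential_test <- function(qm_scaled, level = c("ion", "protein"),
                              assignments = NULL,
                              conditions = c("acidic", "alkaline"),
                              adjust = FALSE) {
  stopifnot(inherits(qm_scaled, "quant_matrix"))
  level <- match.arg(level)
  design <- qm_scaled$design
  cols_a <- design$sample_id[design$condition == conditions[1]]
  cols_b <- design$sample_id[design$condition == conditions[2]]
  if (level == "ion") {
    mat <- qm_scaled$values
    features <- rownames(mat)
  } else {
    if (is.null(assignments)) stop("assignments required at protein level")
    pmap <- proteotypic_map(assignments)
    idx <- match(qm_scaled$ions$peptide_seq, pmap$peptide_seq)
    keep <- !is.na(idx)
    prot <- pmap$protein_id[idx[keep]]
    sub <- qm_scaled$values[keep, , drop = FALSE]
    groups <- split(seq_along(prot), prot)
    mat <- t(vapply(groups, function(rows) {
      s <- colSums(sub[rows, , drop = FALSE], na.rm = TRUE)
      s[colSums(!is.na(sub[rows, , drop = FALSE])) == 0L] <- NA_real_
      s
    }, numeric(ncol(sub))))
    colnames(mat) <- colnames(sub)
    features <- names(groups)
  }
  stat_one <- function(i) {
    a <- mat[i, cols_a]; b <- mat[i, cols_b]
    a <- a[!is.na(a) & a > 0]; b <- b[!is.na(b) & b > 0]
    lr <- if (length(a) && length(b)) log2(mean(a) / mean(b)) else NA_real_
    p <- welch_p(log(a), log(b))
    c(lr, p)
  }
  st <- vapply(seq_len(nrow(mat)), stat_one, numeric(2))
  out <- tibble::tibble(feature = features, log2_ratio = st[1, ],
                        p_value = st[2, ])
  if (adjust) out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out
}
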