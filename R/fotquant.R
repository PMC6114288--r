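#' Spectral counts per protein or BIN class
#'
#' Each evidence row is one peptide-spectrum observation. At protein level a
#' shared (non-proteotypic) peptide's spectra are counted for each of its
#' proteins (\code{shared = "all"}) or dropped (\code{shared = "unique"}).
#' At BIN level each spectrum is counted once per distinct class among the
#' peptide's proteins, never once per protein, so co-members of one class do
#' not double-count (\code{shared = "once_per_class"}); \code{"drop"} removes
#' shared peptides entirely.
#'
#' @param ev filtered evidence tibble (with \code{condition}).
#' @param assignments tibble from [map_peptides()].
#' @param level \code{"protein"} or \code{"bin"}.
#' @param bins annotation tibble, required for \code{level = "bin"}.
#' @param shared shared-peptide counting mode (see Details).
#' @param conditions condition labels fixing the column order.
#' @param count_unmatched see [annotate_peptides()].
#' @return tibble with \code{key} and one count column per condition; the
#'   \code{"margins"} attribute holds per-condition totals.
#' @export
spectral_counts <- function(ev, assignments, level = c("protein", "bin"),
                            bins = NULL, shared = NULL,
                            conditions = c("acidic", "alkaline"),
                            count_unmatched = FALSE) {
  level <- match.arg(level)
  if (is.null(shared)) shared <- if (level == "bin") "once_per_class" else "all"
  keys <- if (level == "protein") {
    asn <- if (shared %in% c("unique", "drop")) {
      assignments[assignments$proteotypic, , drop = FALSE]
    } else assignments
    tidyr::unnest(
      dplyr::select(asn, peptide_seq, protein_ids),
      protein_ids
    ) |> dplyr::rename(key = protein_ids)
  } else {
    if (is.null(bins)) stop("bins required for level = 'bin'")
    asn <- if (shared == "drop") {
      assignments[assignments$proteotypic, , drop = FALSE]
    } else assignments
    ann <- annotate_peptides(asn, bins, count_unmatched)
    if (is.null(ann) || nrow(ann) == 0L) {
      ann <- tibble::tibble(peptide_seq = character(),
                            bin_code = character())
    }
    dplyr::rename(ann, key = bin_code)
  }
  counts <- ev |>
    dplyr::count(peptide_seq, condition, name = "n_spectra") |>
    dplyr::inner_join(keys, by = "peptide_seq",
                      relationship = "many-to-many") |>
    dplyr::group_by(key, condition) |>
    dplyr::summarise(n = sum(n_spectra), .groups = "drop")
  if (nrow(counts) == 0L) {
    wide <- tibble::tibble(key = character())
  } else {
    wide <- tidyr::pivot_wider(counts, names_from = condition,
                               values_from = n, values_fill = 0L)
  }
  for (cond in conditions) if (!cond %in% names(wide)) wide[[cond]] <- 0L
  wide <- wide[, c("key", conditions)]
  wide <- wide[order(wide$key), , drop = FALSE]
  attr(wide, "margins") <- vapply(conditions,
                                  function(cc) sum(wide[[cc]]), numeric(1))
  wide
}

bin_prefix <- function(code, level) {
  parts <- strsplit(code, ".", fixed = TRUE)
  vapply(parts, function(p) paste(p[seq_len(min(level, length(p)))],
                                  collapse = "."), character(1))
}

#' Aggregate protein-level counts to BIN classes
#'
#' Class counts are sums of member-protein counts with hierarchical roll-up
#' by code prefix: a protein annotated \code{34.1.1} contributes to
#' \code{34.1} at level 2 and to \code{34} at level 1. Proteins without
#' annotation fall into class \code{"35"}.
#'
#' @param protein_counts count tibble from
#'   \code{spectral_counts(level = "protein")}.
#' @param bins annotation tibble (\code{unigene_id}, \code{bin_code}).
#' @param level number of code components to keep (1 = top level).
#' @param conditions condition columns present in \code{protein_counts}.
#' @return class-level count tibble with margins attribute.
#' @export
aggregate_class <- function(protein_counts, bins, level = 1L,
                            conditions = c("acidic", "alkaline")) {
  bins <- validate_bins(bins)
  ann <- dplyr::distinct(
    tibble::tibble(key = protein_counts$key),
    key
  ) |>
    dplyr::left_join(dplyr::distinct(bins, unigene_id, bin_code),
                     by = c(key = "unigene_id"),
                     relationship = "many-to-many")
  ann$bin_code[is.na(ann$bin_code)] <- "35"
  ann$class <- bin_prefix(ann$bin_code, level)
  joined <- dplyr::inner_join(protein_counts, ann, by = "key",
                              relationship = "many-to-many") |>
    dplyr::distinct(dplyr::across(dplyr::all_of(c("key", conditions, "class"))))
  out <- joined |>
    dplyr::group_by(class) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(conditions), sum),
                     .groups = "drop") |>
    dplyr::rename(key = class) |>
    dplyr::arrange(key)
  attr(out, "margins") <- vapply(conditions,
                                 function(cc) sum(out[[cc]]), numeric(1))
  out
}

#' Fraction-of-total statistics per class
#'
#' fot(class, condition) = class spectral count / condition total. The
#' acidic/alkaline contrast is summarised as \code{ratio_minus1} =
#' fot(acidic)/fot(alkaline) - 1, positive for acidic-enriched classes and
#' \code{NA} (undefined) where the alkaline fot is zero.
#'
#' @param class_counts class-level count tibble (keys mutually exclusive at
#'   one hierarchy level).
#' @param conditions two condition labels, numerator first.
#' @return tibble \code{bin_code}, \code{fot_<condition>} columns,
#'   \code{ratio_minus1}.
#' @export
class_fot <- function(class_counts, conditions = c("acidic", "alkaline")) {
  margins <- vapply(conditions, function(cc) sum(class_counts[[cc]]),
                    numeric(1))
  if (any(margins <= 0)) {
    stop(sprintf("zero spectral-count margin in condition '%s'",
                 conditions[which(margins <= 0)[1]]))
  }
  out <- tibble::tibble(bin_code = class_counts$key)
  for (cc in conditions) {
    out[[paste0("fot_", cc)]] <- class_counts[[cc]] / margins[[cc]]
  }
  num <- out[[paste0("fot_", conditions[1])]]
  den <- out[[paste0("fot_", conditions[2])]]
  out$ratio_minus1 <- ifelse(den > 0, num / den - 1, NA_real_)
  out
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Acidic/alkaline enrichment percentage
#'
#' percent_excess = round(100 * (acidic - alkaline) / alkaline), rounded to
#' the nearest integer half away from zero. Rows with zero alkaline count are
#' retained with an infinite (undefined) percentage.
#'
#' @param count_acidic,count_alkaline non-negative spectral counts
#'   (vectorised).
#' @return tibble \code{count_acidic}, \code{count_alkaline}, \code{total},
#'   \code{percent_excess}.
#' @examples
#' enrichment_percent(280, 193)  # 45
#' @export
enrichment_percent <- function(count_acidic, count_alkaline) {
  stopifnot(all(count_acidic >= 0), all(count_alkaline >= 0))
  pct <- ifelse(count_alkaline > 0,
                round_half_away(100 * (count_acidic - count_alkaline) /
                                  count_alkaline),
                Inf)
  tibble::tibble(count_acidic = count_acidic,
                 count_alkaline = count_alkaline,
                 total = count_acidic + count_alkaline,
                 percent_excess = pct)
}

#' Published per-protein spectral counts for the transport and
#' vesicle-transport classes
#'
#' Loads the packaged fixture encoding the per-protein acidic/alkaline
#' spectral counts of the study's two printed tables (BIN class 34 transport
#' and BIN class 31.4 cell.vesicle transport). Subclasses that share a
#' printed numeric code are distinguished by \code{bin_name}.
#'
#' @return tibble \code{table}, \code{bin_code}, \code{bin_name},
#'   \code{protein}, \code{acidic}, \code{alkaline}, \code{total}.
#' @export
chara_band_counts <- function() {
  path <- system.file("extdata", "band_spectral_counts.tsv",
                      package = "charaband", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    table = readr::col_integer(), bin_code = readr::col_character(),
    bin_name = readr::col_character(), protein = readr::col_character(),
    acidic = readr::col_integer(), alkaline = readr::col_integer()
  )) |> dplyr::mutate(total = acidic + alkaline)
}

#' Subclass subtotals for the published count tables
#'
#' Sums per-protein counts within each (bin_code, bin_name) subclass, the
#' grouping used by the printed tables' bold subtotal rows.
#'
#' @param counts tibble in the [chara_band_counts()] layout.
#' @return tibble \code{table}, \code{bin_code}, \code{bin_name},
#'   \code{total}, \code{acidic}, \code{alkaline}.
#' @export
subclass_subtotals <- function(counts) {
  counts |>
    dplyr::group_by(table, bin_code, bin_name) |>
    dplyr::summarise(total = sum(total), acidic = sum(acidic),
                     alkaline = sum(alkaline), .groups = "drop")
}

#' Grand totals per published table
#'
#' @param counts tibble in the [chara_band_counts()] layout.
#' @return tibble \code{table}, \code{total}, \code{acidic}, \code{alkaline}.
#' @export
table_grand_totals <- function(counts) {
  counts |>
    dplyr::group_by(table) |>
    dplyr::summarise(total = sum(total), acidic = sum(acidic),
                     alkaline = sum(alkaline), .groups = "drop")
}
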