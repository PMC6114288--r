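#' Default MaxQuant-style evidence column schema
#'
#' Maps the internal field names onto the column headers of an
#' \code{evidence.txt}-like tab-separated table. Override entries to absorb
#' dialect drift across search-engine versions.
#'
#' @param ... named overrides, e.g. \code{sequence = "Modified sequence"}.
#' @return named list of column names.
#' @export
evidence_schema <- function(...) {
  schema <- list(
    sequence = "Sequence", charge = "Charge", mz = "m/z",
    intensity = "Intensity", sample = "Raw file",
    reverse = "Reverse", contaminant = "Potential contaminant"
  )
  utils::modifyList(schema, list(...))
}

flag_col <- function(x) {
  if (is.null(x)) return(FALSE)
  if (is.logical(x)) return(!is.na(x) & x)
  !is.na(x) & x %in% c("+", "1", "TRUE", "yes")
}

#' Strip modification annotations from peptide sequences
#'
#' Removes underscores and any parenthesised or bracketed modification tags,
#' leaving the plain amino-acid sequence. The (sequence, charge, m/z) triple
#' remains the ion identity for quantitation.
#'
#' @param x character vector of (possibly modified) peptide sequences.
#' @return plain sequences.
#' @export
strip_modifications <- function(x) {
  gsub("\\([^)]*\\)|\\[[^]]*\\]|_", "", x)
}

#' Read a sample design table
#'
#' @param path TSV with columns \code{sample_id}, \code{condition},
#'   \code{replicate}.
#' @return validated tibble.
#' @export
read_design <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), condition = readr::col_character(),
    replicate = readr::col_integer()
  ))
  validate_design(d)
}

validate_design <- function(design) {
  stopifnot(all(c("sample_id", "condition", "replicate") %in% names(design)))
  if (nrow(design) == 0L) stop("design declares zero replicates")
  if (any(design$replicate < 1L)) stop("replicate numbers must be positive")
  if (anyDuplicated(design$sample_id)) stop("duplicate sample_id in design")
  tibble::as_tibble(design)
}

#' Read a peptide-evidence table
#'
#' Parses a tab-separated MaxQuant-style evidence table, validates the
#' mandatory columns (peptide sequence, intensity, sample), strips
#' modification tags from sequences, and joins the sample design to obtain
#' condition and replicate labels.
#'
#' @param path evidence TSV.
#' @param design sample design tibble (\code{sample_id}, \code{condition},
#'   \code{replicate}) or path to one.
#' @param schema column mapping from [evidence_schema()].
#' @return tibble of evidence rows: \code{peptide_seq}, \code{charge},
#'   \code{mz}, \code{intensity}, \code{sample_id}, \code{condition},
#'   \code{replicate}, \code{is_reverse}, \code{is_contaminant}.
#' @export
read_evidence <- function(path, design, schema = evidence_schema()) {
  if (is.character(design)) design <- read_design(design)
  design <- validate_design(design)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0L) stop("empty evidence file")
  mandatory <- c("sequence", "intensity", "sample")
  for (f in mandatory) {
    if (!schema[[f]] %in% names(raw)) {
      stop(sprintf("missing mandatory column '%s'", schema[[f]]))
    }
  }
  num <- function(field) {
    col <- raw[[schema[[field]]]]
    if (is.null(col)) return(rep(NA_real_, nrow(raw)))
    col[col == ""] <- NA
    v <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(v))
    if (length(bad)) {
      stop(sprintf("unparseable %s value '%s' at line %d", field,
                   col[bad[1]], bad[1] + 1L))
    }
    v
  }
  ev <- tibble::tibble(
    peptide_seq = strip_modifications(raw[[schema$sequence]]),
    charge = as.integer(num("charge")),
    mz = num("mz"),
    intensity = num("intensity"),
    sample_id = raw[[schema$sample]],
    is_reverse = flag_col(raw[[schema$reverse]]),
    is_contaminant = flag_col(raw[[schema$contaminant]])
  )
  ev$intensity[is.na(ev$intensity)] <- 0
  if (any(ev$intensity < 0)) stop("negative intensity encountered")
  if (any(!nzchar(ev$peptide_seq))) stop("empty peptide sequence encountered")
  unknown <- setdiff(unique(ev$sample_id), design$sample_id)
  if (length(unknown)) {
    stop(sprintf("sample '%s' missing from design", unknown[1]))
  }
  ev <- dplyr::left_join(ev, design, by = "sample_id")
  message(sprintf("read %d evidence rows from %s", nrow(ev), path))
  ev
}

#' Remove reverse and contaminant hits
#'
#' Rows flagged as reverse (decoy) or contaminant by the upstream search are
#' excluded from all further analysis. Per-category removal counts are kept
#' in the \code{"removed"} attribute.
#'
#' @param ev evidence tibble from [read_evidence()].
#' @return filtered tibble.
#' @export
filter_rows <- function(ev) {
  removed <- c(reverse = sum(ev$is_reverse),
               contaminant = sum(ev$is_contaminant & !ev$is_reverse))
  out <- ev[!ev$is_reverse & !ev$is_contaminant, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Keep peptides observed in all biological replicates
#'
#' A peptide is retained when it appears (as at least one clean evidence row)
#' in every declared replicate of at least one condition
#' (\code{scope = "per_condition"}, the default, which preserves
#' condition-specific proteins) or in every replicate of every condition
#' (\code{scope = "global"}). Presence is assessed on rows not flagged
#' reverse/contaminant, so this filter commutes with [filter_rows()]. All
#' rows of dropped peptides are removed.
#'
#' @param ev evidence tibble.
#' @param design sample design tibble declaring replicates per condition.
#' @param scope completeness scope.
#' @return list with \code{rows} (filtered evidence) and \code{peptides}
#'   (retained peptide sequences).
#' @export
replicate_presence_filter <- function(ev, design,
                                      scope = c("per_condition", "global")) {
  scope <- match.arg(scope)
  design <- validate_design(design)
  declared <- dplyr::distinct(design, condition, replicate) |>
    dplyr::count(condition, name = "n_declared")
  clean <- ev[!ev$is_reverse & !ev$is_contaminant, , drop = FALSE]
  seen <- dplyr::distinct(clean, peptide_seq, condition, replicate) |>
    dplyr::count(peptide_seq, condition, name = "n_seen") |>
    dplyr::left_join(declared, by = "condition") |>
    dplyr::mutate(complete = n_seen == n_declared)
  retained <- if (scope == "per_condition") {
    seen |> dplyr::filter(complete) |> dplyr::pull(peptide_seq) |> unique()
  } else {
    full <- seen |> dplyr::group_by(peptide_seq) |>
      dplyr::summarise(ok = sum(complete) == nrow(declared), .groups = "drop")
    full$peptide_seq[full$ok]
  }
  list(rows = ev[ev$peptide_seq %in% retained, , drop = FALSE],
       peptides = sort(retained))
}

#' Assign peptides to database proteins
#'
#' A peptide is assigned every database protein containing it as a contiguous
#' substring; I and L are treated as equivalent by default. A peptide matching
#' exactly one protein is proteotypic; only those contribute to protein-level
#' intensity sums.
#'
#' @param peptides character vector of peptide sequences.
#' @param db protein database tibble from [build_protein_db()].
#' @param il_equivalent treat I and L as the same residue.
#' @return tibble \code{peptide_seq}, \code{protein_ids} (list-column),
#'   \code{n_proteins}, \code{proteotypic}.
#' @export
map_peptides <- function(peptides, db, il_equivalent = TRUE) {
  peptides <- unique(peptides)
  prot <- if (il_equivalent) canonical_il(db$aa_seq) else db$aa_seq
  peps <- if (il_equivalent) canonical_il(peptides) else peptides
  hits <- lapply(peps, function(p) db$unigene_id[grepl(p, prot, fixed = TRUE)])
  n <- lengths(hits)
  tibble::tibble(peptide_seq = peptides, protein_ids = hits,
                 n_proteins = n, proteotypic = n == 1L)
}

#' Read a BIN (MapMan/Mercator-style) annotation map
#'
#' @param path two-or-three-column TSV \code{unigene_id<TAB>bin_code[<TAB>bin_name]}.
#' @return tibble \code{unigene_id}, \code{bin_code}, \code{bin_name}.
#' @export
read_bins <- function(path) {
  b <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  names(b)[1:2] <- c("unigene_id", "bin_code")
  if (ncol(b) < 3L) b$bin_name <- NA_character_ else names(b)[3] <- "bin_name"
  validate_bins(b[, c("unigene_id", "bin_code", "bin_name")])
}

validate_bins <- function(bins) {
  bad <- !grepl("^\\d+(\\.\\d+)*$", bins$bin_code)
  if (any(bad)) {
    stop(sprintf("malformed bin_code '%s'", bins$bin_code[which(bad)[1]]))
  }
  tibble::as_tibble(bins)
}

#' Annotate peptide assignments with BIN classes
#'
#' Each matched peptide inherits the BIN code(s) of the unigenes of all its
#' proteins; peptides whose unigenes carry no annotation receive the reserved
#' code \code{"35"} (not assigned). Unmatched peptides are excluded unless
#' \code{count_unmatched} is set, in which case they also fall into
#' \code{"35"}.
#'
#' @param assignments tibble from [map_peptides()].
#' @param bins annotation tibble from [read_bins()] (or same layout).
#' @param count_unmatched include peptides matching no protein as class "35".
#' @return tibble \code{peptide_seq}, \code{bin_code}, one row per distinct
#'   peptide-class pair.
#' @export
annotate_peptides <- function(assignments, bins, count_unmatched = FALSE) {
  bins <- validate_bins(bins)
  rows <- lapply(seq_len(nrow(assignments)), function(i) {
    ids <- assignments$protein_ids[[i]]
    if (length(ids) == 0L) {
      if (!count_unmatched) return(NULL)
      return(tibble::tibble(peptide_seq = assignments$peptide_seq[i],
                            bin_code = "35"))
    }
    codes <- unique(bins$bin_code[bins$unigene_id %in% ids])
    if (length(codes) == 0L) codes <- "35"
    tibble::tibble(peptide_seq = assignments$peptide_seq[i], bin_code = codes)
  })
  dplyr::bind_rows(rows)
}
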