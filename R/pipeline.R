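#' Run the full region-resolved membrane proteome pipeline
#'
#' Orchestrates database construction, evidence ingestion and filtering,
#' peptide-to-protein assignment, BIN annotation, spectral-count and fot
#' statistics, the label-free intensity ladder (normalize, scale, average,
#' proteotypic sums, differential test) and protein sequence coverage, and
#' writes the result tables plus a run manifest with row counts at each
#' filter.
#'
#' @param transcripts nucleotide FASTA path or tibble (\code{id}, \code{seq}).
#' @param evidence evidence TSV path or evidence tibble from
#'   [read_evidence()].
#' @param bins annotation TSV path or tibble.
#' @param design design TSV path or tibble.
#' @param out_dir output directory; NULL to skip writing.
#' @param orf_policy,min_aa database construction parameters.
#' @param scope replicate-presence scope (see [replicate_presence_filter()]).
#' @param fot_level BIN hierarchy depth for the class fot table.
#' @param min_reps minimum replicates for averaging.
#' @param il_equivalent I/L equivalence in peptide matching.
#' @param conditions two condition labels, numerator first.
#' @param adjust Benjamini-Hochberg adjustment for the differential test.
#' @return list with \code{db}, \code{assignments}, \code{protein_counts},
#'   \code{class_counts}, \code{fot}, \code{protein_quant},
#'   \code{differential}, \code{coverage}, \code{manifest}.
#' @export
run_band_pipeline <- function(transcripts, evidence, bins, design,
                              out_dir = NULL, orf_policy = "stop-to-stop",
                              min_aa = 30L,
                              scope = "per_condition", fot_level = 1L,
                              min_reps = 3L, il_equivalent = TRUE,
                              conditions = c("acidic", "alkaline"),
                              adjust = FALSE) {
  if (is.character(bins)) bins <- read_bins(bins)
  if (is.character(design)) design <- read_design(design)
  design <- validate_design(design)
  db <- build_protein_db(transcripts, policy = orf_policy, min_aa = min_aa)
  if (nrow(db) == 0L) stop("stage build-db: no ORFs retained")
  ev <- if (is.character(evidence)) read_evidence(evidence, design) else evidence
  n_in <- nrow(ev)
  ev_f <- filter_rows(ev)
  removed <- attr(ev_f, "removed")
  pres <- replicate_presence_filter(ev_f, design, scope = scope)
  ev_p <- pres$rows
  asn <- map_peptides(unique(ev_p$peptide_seq), db,
                      il_equivalent = il_equivalent)
  matched <- asn$peptide_seq[asn$n_proteins > 0L]
  ev_m <- ev_p[ev_p$peptide_seq %in% matched, , drop = FALSE]
  prot_counts <- spectral_counts(ev_m, asn, level = "protein",
                                 conditions = conditions)
  class_counts <- aggregate_class(prot_counts, bins, level = fot_level,
                                  conditions = conditions)
  fot <- class_fot(class_counts, conditions = conditions)
  qm <- build_quant_matrix(ev_m, design) |>
    normalize_total() |>
    scale_across_treatments()
  qm_avg <- average_replicates(qm, min_reps = min_reps)
  pq <- protein_sums(qm_avg, asn, conditions = conditions)
  diff_prot <- differential_test(qm, level = "protein", assignments = asn,
                                 conditions = conditions, adjust = adjust)
  pq <- dplyr::left_join(pq,
                         dplyr::rename(diff_prot, protein_id = feature,
                                       p_value = p_value,
                                       log2_ratio_test = log2_ratio),
                         by = "protein_id")
  cov <- coverage_report(db, unique(ev_m$peptide_seq),
                         il_equivalent = il_equivalent)
  manifest <- list(
    n_transcripts = if (is.data.frame(transcripts)) nrow(transcripts) else NA,
    n_proteins_db = nrow(db),
    rows_in = n_in,
    rows_removed_reverse = unname(removed["reverse"]),
    rows_removed_contaminant = unname(removed["contaminant"]),
    rows_after_flag_filter = nrow(ev_f),
    rows_after_presence_filter = nrow(ev_p),
    peptides_retained = length(pres$peptides),
    peptides_matched = length(matched),
    rows_quantified = nrow(ev_m),
    conditions = conditions, fot_level = fot_level, min_reps = min_reps,
    orf_policy = orf_policy, scope = scope
  )
  res <- list(db = db, assignments = asn, protein_counts = prot_counts,
              class_counts = class_counts, fot = fot, protein_quant = pq,
              differential = diff_prot, coverage = cov, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_protein_fasta(db, file.path(out_dir, "proteins.faa"))
    readr::write_tsv(prot_counts, file.path(out_dir, "protein_counts.tsv"),
                     progress = FALSE)
    readr::write_tsv(class_counts, file.path(out_dir, "class_counts.tsv"),
                     progress = FALSE)
    readr::write_tsv(fot, file.path(out_dir, "class_fot.tsv"),
                     progress = FALSE)
    readr::write_tsv(pq, file.path(out_dir, "protein_quant.tsv"),
                     progress = FALSE)
    readr::write_tsv(cov, file.path(out_dir, "coverage.tsv"),
                     progress = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
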