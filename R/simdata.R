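#' Configuration for the synthetic proteomics data generator
#'
#' Defaults describe the study design being emulated: two conditions (acidic,
#' alkaline) with three biological replicates each, functional classes whose
#' acidic/alkaline abundance ratios span roughly 0.7 to 1.4 (the magnitude of
#' the enrichments observed for transport and vesicle-transport classes),
#' log-normal protein baseline abundances, Poisson spectral counts and
#' multiplicative log-normal ion-intensity noise at 20 percent CV.
#'
#' @param n_classes number of functional (BIN) classes.
#' @param proteins_per_class proteins assigned to each class.
#' @param class_effect named vector of multiplicative acidic/alkaline
#'   abundance factors per class code; default spans 2^0.5 down to 2^-0.5.
#' @param n_replicates biological replicates per condition (>= 3 by default).
#' @param abundance_meanlog,abundance_sdlog log-normal baseline abundance.
#' @param count_scale Poisson rate per unit abundance per peptide per sample.
#' @param intensity_scale instrument response factor for intensities.
#' @param intensity_cv coefficient of variation of multiplicative intensity
#'   noise.
#' @param shared_peptide_fraction fraction of proteins receiving a peptide
#'   copied from another protein (shared, non-proteotypic).
#' @param orf_len_range planted ORF length range in residues.
#' @param flank_len_range flanking (UTR-like) sequence length range in nt.
#' @param peptide_len_range observable peptide length range in residues.
#' @param contaminant_rate,reverse_rate fraction of extra flagged rows.
#' @param conditions the two condition labels, numerator first.
#' @param seed integer seed fixing every downstream draw.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_classes = 8L, proteins_per_class = 6L,
                       class_effect = NULL, n_replicates = 3L,
                       abundance_meanlog = 0, abundance_sdlog = 1,
                       count_scale = 5, intensity_scale = 1e7,
                       intensity_cv = 0.2, shared_peptide_fraction = 0.1,
                       orf_len_range = c(60L, 150L),
                       flank_len_range = c(20L, 60L),
                       peptide_len_range = c(7L, 25L),
                       contaminant_rate = 0.02, reverse_rate = 0.01,
                       conditions = c("acidic", "alkaline"), seed = 1L) {
  stopifnot(n_classes >= 1L, n_classes < 35L, proteins_per_class >= 1L,
            n_replicates >= 1L, count_scale > 0, intensity_scale > 0,
            intensity_cv > 0, length(conditions) == 2L)
  codes <- paste0(seq_len(n_classes), ".1")
  if (is.null(class_effect)) {
    class_effect <- stats::setNames(
      2 ^ seq(0.5, -0.5, length.out = n_classes), codes)
  }
  stopifnot(all(names(class_effect) %in% codes), all(class_effect > 0))
  structure(list(
    n_classes = n_classes, proteins_per_class = proteins_per_class,
    class_codes = codes, class_effect = class_effect,
    n_replicates = as.integer(n_replicates),
    abundance_meanlog = abundance_meanlog, abundance_sdlog = abundance_sdlog,
    count_scale = count_scale, intensity_scale = intensity_scale,
    intensity_cv = intensity_cv,
    shared_peptide_fraction = shared_peptide_fraction,
    orf_len_range = as.integer(orf_len_range),
    flank_len_range = as.integer(flank_len_range),
    peptide_len_range = as.integer(peptide_len_range),
    contaminant_rate = contaminant_rate, reverse_rate = reverse_rate,
    conditions = conditions, seed = as.integer(seed)
  ), class = "sim_config")
}

# codon table for back-translation, derived from the standard genetic code
codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

random_aa <- function(n) {
  paste(sample(names(AA_AVG_MASS), n, replace = TRUE), collapse = "")
}

back_translate <- function(aa, codons) {
  res <- strsplit(aa, "", fixed = TRUE)[[1]]
  paste(vapply(res, function(a) {
    cands <- codons[[a]]
    cands[sample.int(length(cands), 1L)]
  }, character(1)), collapse = "")
}

# a donor tryptic fragment suitable for planting as a shared peptide: an
# internal 0-missed fragment ending in K so the serial LysC/trypsin digestion
# re-emits it exactly at its new location
shared_fragment <- function(aa, len_range) {
  fr <- digest_protein(aa, "lysC_then_trypsin", 0L)
  fr <- fr[fr$end < nchar(aa) & !startsWith(fr$seq, "P") &
             endsWith(fr$seq, "K") &
             nchar(fr$seq) >= len_range[1] & nchar(fr$seq) <= len_range[2], ]
  if (nrow(fr) == 0L) return(NULL)
  fr$seq[sample.int(nrow(fr), 1L)]
}

#' Simulate unigene transcripts with planted ORFs
#'
#' Each unigene carries exactly one planted ORF (random codons, no internal
#' stop) embedded between in-frame stop codons and random flanking sequence,
#' on a random strand and frame. Rejection sampling enforces that the planted
#' ORF is strictly the longest stop-free stretch across all six frames, so a
#' database build must recover it exactly. A configured fraction of proteins
#' receives one tryptic peptide copied from another protein, creating
#' genuinely shared (non-proteotypic) peptides.
#'
#' @param cfg a [sim_config()].
#' @return list with \code{transcripts} (tibble \code{id}, \code{seq}),
#'   \code{truth} (tibble \code{unigene_id}, \code{strand}, \code{frame},
#'   \code{nt_start}, \code{nt_end}, \code{aa_seq}).
#' @export
simulate_transcripts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_classes * cfg$proteins_per_class
  codons <- codons_by_aa()
  n_shared <- round(cfg$shared_peptide_fraction * n)
  hosts <- if (n_shared > 0L && n >= 2L) {
    sort(sample(2:n, min(n_shared, n - 1L)))
  } else integer()
  ids <- sprintf("UG%04d", seq_len(n))
  aa_seqs <- character(n)
  recs <- vector("list", n)
  # boundary cassette with a stop codon in every frame on both strands (it
  # is its own reverse complement); together with the in-frame TAA after the
  # ORF it stops any run from crossing the ORF boundaries in any frame
  bnd <- "TTAATTAATTAA"
  for (i in seq_len(n)) {
    frag <- if (i %in% hosts) {
      donor <- sample.int(i - 1L, 1L)  # donors are already finalised
      shared_fragment(aa_seqs[donor], c(6L, 20L))
    } else NULL
    draw_aa <- function() {
      len <- sample_range(cfg$orf_len_range)
      aa <- paste0("M", random_aa(len - 1L))
      if (!is.null(frag)) {
        ks <- which(strsplit(aa, "")[[1]] == "K")
        ks <- ks[ks < nchar(aa)]
        if (length(ks)) {
          at <- ks[sample.int(length(ks), 1L)]
          aa <- paste0(substr(aa, 1L, at), frag,
                       substr(aa, at + 1L, nchar(aa)))
        }
      }
      aa
    }
    ok <- FALSE
    for (aa_try in 1:40) {
      aa <- draw_aa()
      target <- nchar(aa)
      for (try in 1:25) {
        orf_nt <- back_translate(aa, codons)
        f5 <- paste(sample(c("A", "C", "G", "T"),
                           sample_range(cfg$flank_len_range),
                           replace = TRUE), collapse = "")
        f3 <- paste(sample(c("A", "C", "G", "T"),
                           sample_range(cfg$flank_len_range),
                           replace = TRUE), collapse = "")
        sense <- paste0(f5, bnd, orf_nt, "TAA", bnd, f3)
        strand <- sample(c("f", "r"), 1L)
        transcript <- if (strand == "f") sense else reverse_complement(sense)
        # planted ORF must be the unique longest candidate across all frames
        frames <- translate_six_frames(transcript, validate = FALSE)
        lens <- unlist(lapply(frames, function(a) {
          nchar(orf_candidates(a, "stop-to-stop", TRUE)$seq)
        }), use.names = FALSE)
        if (length(lens) && max(lens) == target &&
              sum(lens == target) == 1L) {
          s_sense <- nchar(f5) + 12L
          e_sense <- s_sense + 3L * target
          L <- nchar(sense)
          recs[[i]] <- tibble::tibble(
            unigene_id = ids[i], strand = strand, frame = s_sense %% 3L,
            nt_start = if (strand == "f") s_sense else L - e_sense,
            nt_end = if (strand == "f") e_sense else L - s_sense,
            aa_seq = aa, seq = transcript
          )
          aa_seqs[i] <- aa
          ok <- TRUE
          break
        }
      }
      if (ok) break
    }
    if (!ok) stop(sprintf("rejection sampling failed for unigene %s", ids[i]))
  }
  truth <- dplyr::bind_rows(recs)
  list(transcripts = tibble::tibble(id = truth$unigene_id, seq = truth$seq),
       truth = dplyr::select(truth, -seq))
}

lognormal_sdlog <- function(cv) sqrt(log(1 + cv^2))

# sample one integer from an inclusive range (safe for degenerate ranges,
# where sample(x, 1) would draw from 1:x)
sample_range <- function(range) {
  range[1] + sample.int(range[2] - range[1] + 1L, 1L) - 1L
}

#' Simulate a two-condition peptide evidence table with known ground truth
#'
#' Per protein, baseline abundance is log-normal; the class effect multiplies
#' the acidic/alkaline abundance ratio (applied symmetrically in log space so
#' totals stay comparable). Observable peptides come from the in-silico
#' LysC+trypsin digest; per peptide and sample the spectral count is Poisson
#' with rate proportional to condition abundance, and each observed spectrum
#' carries a log-normally perturbed intensity. Flagged contaminant and
#' reverse decoy rows are appended.
#'
#' @param cfg a [sim_config()].
#' @param db protein database tibble (e.g. from [build_protein_db()] on
#'   [simulate_transcripts()] output).
#' @return list with \code{evidence} (tibble in the MaxQuant-style dialect),
#'   \code{design}, \code{bins}, \code{truth} (protein abundances, peptide
#'   rates, class effects).
#' @export
simulate_evidence <- function(cfg, db) {
  stopifnot(inherits(cfg, "sim_config"), nrow(db) > 0L)
  set.seed(cfg$seed + 1L)
  n_prot <- nrow(db)
  class_of <- cfg$class_codes[((seq_len(n_prot) - 1L) %% cfg$n_classes) + 1L]
  bins <- tibble::tibble(unigene_id = db$unigene_id, bin_code = class_of,
                         bin_name = paste0("class_", class_of))
  effect <- unname(cfg$class_effect[class_of])
  base <- exp(stats::rnorm(n_prot, cfg$abundance_meanlog, cfg$abundance_sdlog))
  ab_acid <- base * sqrt(effect)
  ab_alk <- base / sqrt(effect)
  proteins <- tibble::tibble(
    protein_id = db$unigene_id, bin_code = class_of, baseline = base,
    effect = effect, abundance_acidic = ab_acid, abundance_alkaline = ab_alk,
    log2_effect = log2(effect)
  )
  # observable peptides and the peptide -> protein occurrence map
  dig <- digest_db(db, "lysC_then_trypsin", 0L)
  dig <- dig[nchar(dig$seq) >= cfg$peptide_len_range[1] &
               nchar(dig$seq) <= cfg$peptide_len_range[2], ]
  pep_map <- dplyr::distinct(dig, seq, parent_id)
  peps <- sort(unique(pep_map$seq))
  charge <- stats::setNames(sample(2:3, length(peps), replace = TRUE), peps)
  mass <- vapply(peps, protein_mw, numeric(1))
  mz <- stats::setNames(round((mass + charge * PROTON_MASS) / charge, 4), peps)
  idx_a <- stats::setNames(ab_acid, db$unigene_id)
  idx_b <- stats::setNames(ab_alk, db$unigene_id)
  basis <- dplyr::group_by(pep_map, seq) |>
    dplyr::summarise(basis_acidic = sum(idx_a[parent_id]),
                     basis_alkaline = sum(idx_b[parent_id]),
                     proteins = paste(sort(parent_id), collapse = ";"),
                     .groups = "drop")
  design <- tidyr::expand_grid(condition = cfg$conditions,
                               replicate = seq_len(cfg$n_replicates)) |>
    dplyr::mutate(sample_id = sprintf("%s_r%d", condition, replicate)) |>
    dplyr::select(sample_id, condition, replicate)
  sdlog <- lognormal_sdlog(cfg$intensity_cv)
  rows <- list()
  for (s in seq_len(nrow(design))) {
    cond <- design$condition[s]
    b <- if (cond == cfg$conditions[1]) basis$basis_acidic else basis$basis_alkaline
    counts <- stats::rpois(nrow(basis), cfg$count_scale * b)
    obs <- which(counts > 0L)
    if (length(obs) == 0L) next
    seqs <- rep.int(basis$seq[obs], counts[obs])
    mu <- rep.int(cfg$intensity_scale * b[obs], counts[obs])
    rows[[s]] <- tibble::tibble(
      Sequence = seqs, Charge = unname(charge[seqs]), mz = unname(mz[seqs]),
      Intensity = round(mu * exp(stats::rnorm(length(seqs), 0, sdlog)), 2),
      `Raw file` = design$sample_id[s], Reverse = "",
      `Potential contaminant` = ""
    )
  }
  evidence <- dplyr::bind_rows(rows)
  # flagged extras: contaminants (keratin-like) and reverse decoys
  n_con <- round(cfg$contaminant_rate * nrow(evidence))
  n_rev <- round(cfg$reverse_rate * nrow(evidence))
  extras <- list()
  if (n_con > 0L) {
    extras$con <- tibble::tibble(
      Sequence = rep("SGGGFGGGSGFSGGGFGGGGFGK", n_con), Charge = 2L,
      mz = 1000.5, Intensity = round(cfg$intensity_scale *
                                       exp(stats::rnorm(n_con, 0, sdlog)), 2),
      `Raw file` = sample(design$sample_id, n_con, replace = TRUE),
      Reverse = "", `Potential contaminant` = "+"
    )
  }
  if (n_rev > 0L) {
    extras$rev <- tibble::tibble(
      Sequence = rep("KVEDLTSPEANR", n_rev), Charge = 2L, mz = 700.4,
      Intensity = round(cfg$intensity_scale *
                          exp(stats::rnorm(n_rev, 0, sdlog)), 2),
      `Raw file` = sample(design$sample_id, n_rev, replace = TRUE),
      Reverse = "+", `Potential contaminant` = ""
    )
  }
  evidence <- dplyr::bind_rows(c(list(evidence), extras))
  names(evidence)[names(evidence) == "mz"] <- "m/z"
  truth <- list(
    config = unclass(cfg)[c("n_classes", "proteins_per_class", "n_replicates",
                            "count_scale", "intensity_scale", "intensity_cv",
                            "conditions", "seed")],
    class_effect = as.list(cfg$class_effect),
    proteins = proteins,
    peptides = dplyr::mutate(basis,
                             rate_acidic = cfg$count_scale * basis_acidic,
                             rate_alkaline = cfg$count_scale * basis_alkaline),
    bins = bins
  )
  list(evidence = evidence, design = design, bins = bins, truth = truth)
}

#' Closed-form expected pipeline outputs from the generator's ground truth
#'
#' Expected class-level spectral counts are sums of Poisson rates over the
#' class's peptides and replicates (each peptide counted once per class);
#' expected fot follows by normalization; expected protein log2 ratios equal
#' the planted class effects on the log2 scale.
#'
#' @param truth ground-truth list from [simulate_evidence()].
#' @return list with \code{class_counts} (tibble \code{bin_code},
#'   \code{acidic}, \code{alkaline}), \code{class_fot}, \code{protein_log2}
#'   (tibble \code{protein_id}, \code{log2_effect}).
#' @export
expected_outputs <- function(truth) {
  n_rep <- truth$config$n_replicates
  pep_class <- truth$peptides |>
    tidyr::separate_rows(proteins, sep = ";") |>
    dplyr::left_join(truth$bins, by = c(proteins = "unigene_id")) |>
    dplyr::distinct(seq, bin_code, rate_acidic, rate_alkaline)
  cls <- pep_class |>
    dplyr::group_by(bin_code) |>
    dplyr::summarise(acidic = n_rep * sum(rate_acidic),
                     alkaline = n_rep * sum(rate_alkaline), .groups = "drop")
  fot <- tibble::tibble(
    bin_code = cls$bin_code,
    fot_acidic = cls$acidic / sum(cls$acidic),
    fot_alkaline = cls$alkaline / sum(cls$alkaline)
  )
  fot$ratio_minus1 <- fot$fot_acidic / fot$fot_alkaline - 1
  list(class_counts = cls, class_fot = fot,
       protein_log2 = dplyr::select(truth$proteins, protein_id, log2_effect))
}

#' Directly simulate an ion-level quantitation matrix
#'
#' A lighter-weight generator for exercising the intensity workflow alone:
#' log-normal baselines, a per-ion log2 acidic/alkaline effect (applied
#' symmetrically), and multiplicative log-normal noise. No missingness is
#' introduced.
#'
#' @param n_ions number of ion species.
#' @param n_reps replicates per condition.
#' @param log2_effect scalar or length-\code{n_ions} vector of planted log2
#'   acidic/alkaline ratios (0 = null).
#' @param cv coefficient of variation of the multiplicative noise.
#' @param conditions two condition labels.
#' @param seed integer seed.
#' @return a raw \code{quant_matrix}.
#' @export
simulate_quant_matrix <- function(n_ions, n_reps = 4L, log2_effect = 0,
                                  cv = 0.2,
                                  conditions = c("acidic", "alkaline"),
                                  seed = 1L) {
  set.seed(seed)
  log2_effect <- rep_len(log2_effect, n_ions)
  design <- tidyr::expand_grid(condition = conditions,
                               replicate = seq_len(n_reps)) |>
    dplyr::mutate(sample_id = sprintf("%s_r%d", condition, replicate)) |>
    dplyr::select(sample_id, condition, replicate)
  base <- exp(stats::rnorm(n_ions, log(1e7), 1))
  sdlog <- lognormal_sdlog(cv)
  shift <- ifelse(design$condition == conditions[1], 0.5, -0.5)
  values <- vapply(seq_len(nrow(design)), function(s) {
    base * 2 ^ (shift[s] * log2_effect) *
      exp(stats::rnorm(n_ions, 0, sdlog))
  }, numeric(n_ions))
  dimnames(values) <- list(sprintf("ion%05d", seq_len(n_ions)),
                           design$sample_id)
  ions <- tibble::tibble(peptide_seq = rownames(values),
                         charge = 2L, mz = 500)
  structure(list(values = values, ions = ions, design = design,
                 stage = "raw", log2_effect = log2_effect),
            class = "quant_matrix")
}

#' Write a simulated bundle to disk
#'
#' Emits \code{unigenes.fna}, \code{evidence.tsv}, \code{bins.tsv},
#' \code{design.tsv} and \code{truth.json} under \code{dir}. Repeated calls
#' with the same configuration are byte-identical.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return list with the simulated objects and file paths, invisibly.
#' @export
write_sim_bundle <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- simulate_transcripts(cfg)
  db <- build_protein_db(tr$transcripts, min_aa = min(cfg$orf_len_range))
  sim <- simulate_evidence(cfg, db)
  fa <- Biostrings::DNAStringSet(tr$transcripts$seq)
  names(fa) <- tr$transcripts$id
  paths <- list(
    unigenes = file.path(dir, "unigenes.fna"),
    evidence = file.path(dir, "evidence.tsv"),
    bins = file.path(dir, "bins.tsv"),
    design = file.path(dir, "design.tsv"),
    truth = file.path(dir, "truth.json")
  )
  Biostrings::writeXStringSet(fa, paths$unigenes)
  readr::write_tsv(sim$evidence, paths$evidence, progress = FALSE)
  readr::write_tsv(sim$bins, paths$bins, progress = FALSE)
  readr::write_tsv(sim$design, paths$design, progress = FALSE)
  jsonlite::write_json(
    list(config = sim$truth$config, class_effect = sim$truth$class_effect,
         proteins = sim$truth$proteins, peptides = sim$truth$peptides,
         orfs = tr$truth),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(transcripts = tr$transcripts, orf_truth = tr$truth, db = db,
                 evidence = sim$evidence, design = sim$design,
                 bins = sim$bins, truth = sim$truth, paths = paths))
}
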