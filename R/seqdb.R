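#' @importFrom tibble tibble as_tibble
NULL

# IUPAC average residue masses (Da) for the 20 standard amino acids; a peptide
# bond has already been subtracted, so a chain mass is sum(residues) + water.
AA_AVG_MASS <- c(
  G =  57.0519, A =  71.0788, S =  87.0782, P =  97.1167, V =  99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
WATER_MASS <- 18.0153
PROTON_MASS <- 1.00728

#' Validate and normalise a transcript (unigene) nucleotide sequence
#'
#' Sequences are upper-cased; characters outside \code{A,C,G,T,N} are rejected
#' with the offending character and its position, as are sequences shorter
#' than one codon.
#'
#' @param seq nucleotide sequence (character scalar).
#' @return the validated, upper-case sequence.
#' @export
validate_transcript <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) < 3L) stop("sequence too short (< 3 nt)")
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop(sprintf("illegal character '%s' at position %d",
                 substr(seq, bad, bad), bad))
  }
  seq
}

#' Reverse-complement a nucleotide sequence
#'
#' @param seq nucleotide sequence over \code{A,C,G,T,N}.
#' @return the reverse complement as a character scalar.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# codon -> amino-acid lookup under the standard genetic code; any codon not
# in the table (i.e. containing N) translates to 'X'
codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- Biostrings::GENETIC_CODE
    tab
  }
})

translate_frame <- function(seq, offset, table = codon_table()) {
  n_codon <- (nchar(seq) - offset) %/% 3L
  if (n_codon < 1L) return("")
  starts <- offset + 3L * (seq_len(n_codon) - 1L) + 1L
  aa <- unname(table[substring(seq, starts, starts + 2L)])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Translate a transcript in all six reading frames
#'
#' Forward frames translate the sequence at offsets 0, 1, 2; reverse frames
#' translate the reverse complement at the same offsets. Stop codons render
#' as \code{*}; any codon containing \code{N} renders as \code{X}.
#'
#' @param seq nucleotide sequence (validated with [validate_transcript()]).
#' @param validate validate the input first (default TRUE).
#' @return named character vector \code{fwd0, fwd1, fwd2, rev0, rev1, rev2};
#'   frame \code{k} has length \code{floor((nchar(seq) - k) / 3)}.
#' @examples
#' translate_six_frames("ATGAAATAG")
#' @export
translate_six_frames <- function(seq, validate = TRUE) {
  if (validate) seq <- validate_transcript(seq)
  rc <- reverse_complement(seq)
  out <- c(
    fwd0 = translate_frame(seq, 0L), fwd1 = translate_frame(seq, 1L),
    fwd2 = translate_frame(seq, 2L),
    rev0 = translate_frame(rc, 0L), rev1 = translate_frame(rc, 1L),
    rev2 = translate_frame(rc, 2L)
  )
  out
}

# Maximal candidate ORF stretches within one translated frame.
# aa coordinates are 0-based half-open. Under the default policy a candidate
# is any maximal stretch free of '*' (and of 'X' when x_breaks); met-to-stop
# trims each stretch to start at its first methionine.
orf_candidates <- function(aa, policy = c("stop-to-stop", "met-to-stop"),
                           x_breaks = TRUE) {
  policy <- match.arg(policy)
  if (nchar(aa) == 0L) {
    return(tibble(aa_start = integer(), aa_end = integer(), seq = character()))
  }
  pat <- if (x_breaks) "[*X]" else "\\*"
  pieces <- strsplit(aa, "", fixed = TRUE)[[1]]
  is_break <- grepl(pat, pieces)
  runs <- rle(!is_break)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  if (!any(keep)) {
    return(tibble(aa_start = integer(), aa_end = integer(), seq = character()))
  }
  aa_start <- starts[keep] - 1L
  aa_end <- ends[keep]
  seqs <- substring(aa, aa_start + 1L, aa_end)
  if (policy == "met-to-stop") {
    moff <- regexpr("M", seqs, fixed = TRUE)
    found <- moff > 0L
    if (!any(found)) {
      return(tibble(aa_start = integer(), aa_end = integer(),
                    seq = character()))
    }
    aa_start <- aa_start[found] + (moff[found] - 1L)
    aa_end <- aa_end[found]
    seqs <- substring(aa, aa_start + 1L, aa_end)
  }
  tibble(aa_start = as.integer(aa_start), aa_end = as.integer(aa_end),
         seq = seqs)
}

#' Select the longest open reading frame across six frames
#'
#' A candidate ORF is a maximal stop-free stretch within a translated frame
#' (start codon not required, end-truncated stretches allowed) under the
#' default \code{"stop-to-stop"} policy; \code{"met-to-stop"} requires the
#' candidate to begin at a methionine. \code{X} residues terminate candidates
#' by default. Ties are broken by the fixed frame order
#' \code{fwd0, fwd1, fwd2, rev0, rev1, rev2}, then leftmost within a frame.
#' Nucleotide coordinates are reported 0-based half-open on the forward
#' strand of the parent transcript.
#'
#' @param frames named six-frame translation from [translate_six_frames()].
#' @param nt_length length of the parent transcript in nucleotides.
#' @param policy ORF definition policy.
#' @param min_len minimum ORF length in residues (default 1).
#' @param x_breaks treat \code{X} like a stop for candidate boundaries.
#' @return one-row tibble with \code{strand} (\code{"f"}/\code{"r"}),
#'   \code{frame}, \code{nt_start}, \code{nt_end}, \code{aa_seq},
#'   \code{length_aa}, or NULL when no candidate reaches \code{min_len}.
#' @export
select_longest_orf <- function(frames, nt_length,
                               policy = c("stop-to-stop", "met-to-stop"),
                               min_len = 1L, x_breaks = TRUE) {
  policy <- match.arg(policy)
  frame_order <- c("fwd0", "fwd1", "fwd2", "rev0", "rev1", "rev2")
  stopifnot(all(frame_order %in% names(frames)))
  best <- NULL
  for (i in seq_along(frame_order)) {
    fr <- frame_order[i]
    cand <- orf_candidates(frames[[fr]], policy, x_breaks)
    cand <- cand[nchar(cand$seq) >= min_len, , drop = FALSE]
    if (nrow(cand) == 0L) next
    j <- which.max(nchar(cand$seq))  # leftmost of the longest within a frame
    len <- nchar(cand$seq[j])
    if (is.null(best) || len > best$len) {
      best <- list(len = len, frame_i = i, frame = fr, cand = cand[j, ])
    }
  }
  if (is.null(best)) return(NULL)
  strand <- if (startsWith(best$frame, "fwd")) "f" else "r"
  offset <- as.integer(substring(best$frame, 4L))
  s_strand <- offset + 3L * best$cand$aa_start   # nt coords on translated strand
  e_strand <- offset + 3L * best$cand$aa_end
  if (strand == "f") {
    nt_start <- s_strand; nt_end <- e_strand
  } else {
    nt_start <- nt_length - e_strand; nt_end <- nt_length - s_strand
  }
  tibble(strand = strand, frame = offset,
         nt_start = as.integer(nt_start), nt_end = as.integer(nt_end),
         aa_seq = best$cand$seq, length_aa = nchar(best$cand$seq))
}

#' Build a protein search database from unigene nucleotide sequences
#'
#' Each unigene is translated in six frames and its longest ORF (see
#' [select_longest_orf()]) retained when it reaches \code{min_aa} residues.
#' Unigenes with no qualifying ORF are skipped.
#'
#' @param transcripts either a path to a nucleotide FASTA file or a tibble
#'   with columns \code{id}, \code{seq}.
#' @param policy,min_aa,x_breaks see [select_longest_orf()]; \code{min_aa}
#'   defaults to 30 residues, usual practice for proteogenomic databases.
#' @return tibble with one row per retained unigene: \code{unigene_id},
#'   \code{strand}, \code{frame}, \code{nt_start}, \code{nt_end},
#'   \code{aa_seq}, \code{length_aa}.
#' @export
build_protein_db <- function(transcripts, policy = "stop-to-stop",
                             min_aa = 30L, x_breaks = TRUE) {
  if (is.character(transcripts) && length(transcripts) == 1L) {
    fa <- Biostrings::readDNAStringSet(transcripts)
    transcripts <- tibble(id = sub("\\s.*$", "", names(fa)),
                          seq = as.character(fa))
  }
  stopifnot(all(c("id", "seq") %in% names(transcripts)))
  if (anyDuplicated(transcripts$id)) stop("duplicate unigene identifiers")
  rows <- lapply(seq_len(nrow(transcripts)), function(i) {
    seq <- validate_transcript(transcripts$seq[i])
    orf <- select_longest_orf(translate_six_frames(seq, validate = FALSE),
                              nchar(seq), policy = policy, min_len = min_aa,
                              x_breaks = x_breaks)
    if (is.null(orf)) return(NULL)
    cbind(tibble(unigene_id = transcripts$id[i]), orf)
  })
  dplyr::bind_rows(rows)
}

#' Write a protein database to FASTA
#'
#' Headers carry \code{<unigene_id> strand=<f|r> frame=<0|1|2> start=<nt_start>
#' end=<nt_end>}.
#'
#' @param db tibble from [build_protein_db()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_protein_fasta <- function(db, path) {
  aa <- Biostrings::AAStringSet(db$aa_seq)
  names(aa) <- sprintf("%s strand=%s frame=%d start=%d end=%d",
                       db$unigene_id, db$strand, db$frame,
                       db$nt_start, db$nt_end)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read a protein database written by [write_protein_fasta()]
#'
#' @param path protein FASTA file.
#' @return tibble in the [build_protein_db()] layout.
#' @export
read_protein_db <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  hdr <- names(aa)
  get <- function(key) sub(sprintf(".*%s=([^ ]+).*", key), "\\1", hdr)
  tibble(
    unigene_id = sub("\\s.*$", "", hdr),
    strand = get("strand"),
    frame = as.integer(get("frame")),
    nt_start = as.integer(get("start")),
    nt_end = as.integer(get("end")),
    aa_seq = as.character(aa),
    length_aa = nchar(as.character(aa))
  )
}

cleavage_sites <- function(aa, enzyme) {
  # 1-based positions i such that the enzyme cleaves between i and i+1
  n <- nchar(aa)
  if (n < 2L) return(integer())
  res <- strsplit(aa, "", fixed = TRUE)[[1]]
  pos <- seq_len(n - 1L)
  trypsin <- res[pos] %in% c("K", "R") & res[pos + 1L] != "P"
  lysc <- res[pos] == "K"
  sites <- switch(enzyme,
    trypsin = trypsin,
    lysC = lysc,
    lysC_then_trypsin = trypsin | lysc,
    stop(sprintf("unknown enzyme '%s'", enzyme))
  )
  pos[sites]
}

#' In-silico proteolytic digestion
#'
#' Trypsin cleaves after K or R except before proline; LysC cleaves after K
#' regardless of the next residue; \code{lysC_then_trypsin} (the study's
#' serial digestion) applies the union of both cleavage-site sets. Fragments
#' with 0 to \code{max_missed} missed cleavages are emitted; coordinates are
#' 0-based half-open in the parent.
#'
#' @param aa_seq protein sequence.
#' @param enzyme one of \code{"trypsin"}, \code{"lysC"},
#'   \code{"lysC_then_trypsin"}.
#' @param max_missed maximum number of missed cleavages (default 0).
#' @return tibble with \code{start}, \code{end}, \code{seq},
#'   \code{missed_cleavages}.
#' @examples
#' digest_protein("MKRPGKAR", "trypsin")
#' @export
digest_protein <- function(aa_seq, enzyme = c("lysC_then_trypsin", "trypsin",
                                              "lysC"),
                           max_missed = 0L) {
  if (length(enzyme) == 1L && !enzyme %in% c("lysC_then_trypsin", "trypsin",
                                             "lysC")) {
    stop(sprintf("unknown enzyme '%s'", enzyme))
  }
  enzyme <- match.arg(enzyme)
  stopifnot(nchar(aa_seq) > 0L, max_missed >= 0L)
  n <- nchar(aa_seq)
  bounds <- c(0L, cleavage_sites(aa_seq, enzyme), n)
  k <- length(bounds) - 1L  # number of 0-missed fragments
  out <- list()
  for (m in 0L:as.integer(max_missed)) {
    if (m + 1L > k) break
    i <- seq_len(k - m)
    out[[m + 1L]] <- tibble(
      start = bounds[i], end = bounds[i + m + 1L],
      seq = substring(aa_seq, bounds[i] + 1L, bounds[i + m + 1L]),
      missed_cleavages = m
    )
  }
  dplyr::bind_rows(out)
}

#' Digest every protein in a database
#'
#' @param db tibble from [build_protein_db()].
#' @inheritParams digest_protein
#' @return tibble with \code{parent_id} plus the [digest_protein()] columns.
#' @export
digest_db <- function(db, enzyme = "lysC_then_trypsin", max_missed = 0L) {
  dplyr::bind_rows(lapply(seq_len(nrow(db)), function(i) {
    dplyr::mutate(digest_protein(db$aa_seq[i], enzyme, max_missed),
                  parent_id = db$unigene_id[i], .before = 1L)
  }))
}

#' Average molecular weight of a protein
#'
#' Sum of IUPAC average residue masses plus one water mass (18.0153 Da).
#' Only the 20 standard residues are accepted.
#'
#' @param aa_seq protein sequence (non-empty).
#' @return molecular weight in Da.
#' @examples
#' protein_mw("GG")  # 132.12 Da
#' @export
protein_mw <- function(aa_seq) {
  stopifnot(is.character(aa_seq), length(aa_seq) == 1L)
  if (nchar(aa_seq) == 0L) stop("empty sequence")
  res <- strsplit(aa_seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(res), names(AA_AVG_MASS))
  if (length(bad)) stop(sprintf("non-standard residue '%s'", bad[1]))
  sum(AA_AVG_MASS[res]) + WATER_MASS
}

#' Report a molecular weight in kDa at the conventional precision
#'
#' @param mw_da molecular weight in Da.
#' @return kDa rounded to one decimal.
#' @export
mw_kda <- function(mw_da) round(mw_da / 1000, 1)

canonical_il <- function(x) chartr("I", "L", x)

# all (possibly overlapping) 1-based start positions of pattern in subject
find_occurrences <- function(pattern, subject) {
  out <- integer()
  from <- 1L
  n <- nchar(subject)
  repeat {
    if (from > n) break
    hit <- regexpr(pattern, substr(subject, from, n), fixed = TRUE)
    if (hit < 0L) break
    pos <- from + as.integer(hit) - 1L
    out <- c(out, pos)
    from <- pos + 1L
  }
  out
}

#' Protein sequence coverage by identified peptides
#'
#' Coverage is the fraction of residues lying under at least one occurrence of
#' any peptide as a contiguous substring of the protein; overlapping peptides
#' are counted once (interval union), and peptides absent from the protein
#' contribute nothing. Isoleucine and leucine are treated as equivalent by
#' default since mass spectrometry cannot distinguish them.
#'
#' @param aa_seq protein sequence.
#' @param peptides character vector of peptide sequences.
#' @param il_equivalent treat I and L as the same residue when matching.
#' @return list with \code{covered_residues}, \code{length_aa}, \code{percent}.
#' @export
peptide_coverage <- function(aa_seq, peptides, il_equivalent = TRUE) {
  stopifnot(nchar(aa_seq) > 0L)
  peptides <- peptides[nzchar(peptides)]
  prot <- if (il_equivalent) canonical_il(aa_seq) else aa_seq
  peps <- if (il_equivalent) canonical_il(peptides) else peptides
  starts <- integer(); widths <- integer()
  for (p in unique(peps)) {
    if (nchar(p) > nchar(prot)) next
    m <- find_occurrences(p, prot)  # overlapping occurrences included
    if (length(m)) {
      starts <- c(starts, m)
      widths <- c(widths, rep.int(nchar(p), length(m)))
    }
  }
  covered <- if (length(starts)) {
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(starts, width = widths))))
  } else 0L
  list(covered_residues = as.integer(covered), length_aa = nchar(aa_seq),
       percent = 100 * covered / nchar(aa_seq))
}

#' Coverage report for a protein database
#'
#' @param db tibble from [build_protein_db()].
#' @param peptides character vector of identified peptide sequences.
#' @param il_equivalent see [peptide_coverage()].
#' @return tibble \code{protein_id}, \code{length_aa}, \code{covered_residues},
#'   \code{percent}.
#' @export
coverage_report <- function(db, peptides, il_equivalent = TRUE) {
  dplyr::bind_rows(lapply(seq_len(nrow(db)), function(i) {
    cv <- peptide_coverage(db$aa_seq[i], peptides, il_equivalent)
    tibble(protein_id = db$unigene_id[i], length_aa = cv$length_aa,
           covered_residues = cv$covered_residues, percent = cv$percent)
  }))
}
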