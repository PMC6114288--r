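# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles deliberately take a different algorithmic route from the
# package implementation.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# longest stop-free substring oracle: enumerates every substring of every
# frame (vectorised), fixed frame order fwd0..2, rev0..2, leftmost-longest
# within a frame, strictly-greater length to displace across frames
brute_longest_orf <- function(frames, min_len = 1L) {
  frame_order <- c("fwd0", "fwd1", "fwd2", "rev0", "rev1", "rev2")
  best <- NULL
  for (fr in frame_order) {
    aa <- frames[[fr]]
    L <- nchar(aa)
    if (L == 0L) next
    idx <- expand.grid(i = seq_len(L), j = seq_len(L))
    idx <- idx[idx$j >= idx$i, ]
    subs <- substring(aa, idx$i, idx$j)
    ok <- !grepl("[*X]", subs) & nchar(subs) >= min_len
    if (!any(ok)) next
    subs <- subs[ok]; i <- idx$i[ok]
    lens <- nchar(subs)
    cand <- which(lens == max(lens))
    pick <- cand[which.min(i[cand])]
    if (is.null(best) || lens[pick] > best$len) {
      best <- list(len = lens[pick], frame = fr, aa_start = i[pick] - 1L,
                   seq = subs[pick])
    }
  }
  best
}

# coverage oracle: mark a logical vector position by position
brute_coverage <- function(aa_seq, peptides, il_equivalent = TRUE) {
  canon <- function(x) chartr("I", "L", x)
  prot <- if (il_equivalent) canon(aa_seq) else aa_seq
  peps <- if (il_equivalent) canon(peptides) else peptides
  hit <- rep(FALSE, nchar(prot))
  for (p in peps) {
    np <- nchar(p)
    if (np == 0L || np > nchar(prot)) next
    for (s in seq_len(nchar(prot) - np + 1L)) {
      if (substr(prot, s, s + np - 1L) == p) hit[s:(s + np - 1L)] <- TRUE
    }
  }
  sum(hit)
}

# replicate-presence oracle: explicit loops over peptides and conditions
brute_presence <- function(ev, design, scope = "per_condition") {
  clean <- ev[!ev$is_reverse & !ev$is_contaminant, ]
  conds <- unique(design$condition)
  keep <- character()
  for (p in unique(clean$peptide_seq)) {
    complete <- vapply(conds, function(cc) {
      reps_declared <- unique(design$replicate[design$condition == cc])
      reps_seen <- unique(clean$replicate[clean$peptide_seq == p &
                                            clean$condition == cc])
      all(reps_declared %in% reps_seen)
    }, logical(1))
    ok <- if (scope == "per_condition") any(complete) else all(complete)
    if (ok) keep <- c(keep, p)
  }
  sort(keep)
}

make_design <- function(n_reps = 3L, conditions = c("acidic", "alkaline")) {
  tibble::tibble(
    sample_id = as.vector(outer(conditions, seq_len(n_reps),
                                function(a, b) sprintf("%s_r%d", a, b))),
    condition = rep(conditions, n_reps),
    replicate = rep(seq_len(n_reps), each = length(conditions))
  )
}

make_evidence <- function(peptide_seq, condition, replicate,
                          intensity = 1e6, charge = 2L, mz = 500,
                          is_reverse = FALSE, is_contaminant = FALSE) {
  tibble::tibble(
    peptide_seq = peptide_seq, charge = charge, mz = mz,
    intensity = intensity,
    sample_id = sprintf("%s_r%d", condition, replicate),
    condition = condition, replicate = as.integer(replicate),
    is_reverse = is_reverse, is_contaminant = is_contaminant
  )
}

# verify reported ORF coordinates independently: extract the nucleotide
# interval from the transcript and re-translate it with Biostrings
verify_orf_coords <- function(orf, seq) {
  nt <- substr(seq, orf$nt_start + 1L, orf$nt_end)
  if (orf$strand == "r") {
    nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  }
  aa <- suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(nt), if.fuzzy.codon = "X",
                          no.init.codon = TRUE)))
  identical(aa, orf$aa_seq)
}
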