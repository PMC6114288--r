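test_that("six-frame translation matches the standard genetic code", {
  fr <- translate_six_frames("ATGAAATAG")
  expect_identical(fr[["fwd0"]], "MK*")
  expect_identical(fr[["fwd1"]], "*N")
  expect_identical(fr[["fwd2"]], "EI")
  expect_identical(fr[["rev0"]], "LFH")
  expect_identical(fr[["rev1"]], "YF")
  expect_identical(fr[["rev2"]], "IS")
  expect_identical(translate_six_frames("ATG")[["fwd0"]], "M")
  # codons containing N render as X
  expect_identical(translate_six_frames("ATNAAA")[["fwd0"]], "XK")
  # frame lengths follow floor((L - frame) / 3)
  s <- random_dna(17)
  fr <- translate_six_frames(s)
  expect_identical(unname(nchar(fr[c("fwd0", "fwd1", "fwd2")])),
                   c(5L, 5L, 5L))
})

test_that("translation agrees with an independent codon-table implementation", {
  withr::with_seed(11, {
    for (k in 1:5) {
      s <- random_dna(sample(30:120, 1))
      fr <- translate_six_frames(s)
      for (off in 0:2) {
        n <- (nchar(s) - off) %/% 3
        oracle <- suppressWarnings(as.character(Biostrings::translate(
          Biostrings::DNAString(substr(s, off + 1, off + 3 * n)),
          if.fuzzy.codon = "X", no.init.codon = TRUE)))
        expect_identical(fr[[paste0("fwd", off)]], oracle)
      }
    }
  })
})

test_that("transcript validation rejects short and illegal input", {
  expect_error(translate_six_frames("AT"), "too short")
  expect_error(translate_six_frames("ATGXA"), "illegal character 'X' at position 4")
  expect_identical(validate_transcript("atgaaa"), "ATGAAA")
})

test_that("reverse-complementing the input swaps strand labels", {
  withr::with_seed(7, {
    for (k in 1:5) {
      s <- random_dna(sample(30:90, 1))
      a <- translate_six_frames(s)
      b <- translate_six_frames(reverse_complement(s))
      expect_identical(unname(a[c("fwd0", "fwd1", "fwd2")]),
                       unname(b[c("rev0", "rev1", "rev2")]))
      expect_identical(unname(a[c("rev0", "rev1", "rev2")]),
                       unname(b[c("fwd0", "fwd1", "fwd2")]))
    }
  })
})

test_that("longest-ORF selection returns the unique longest stretch", {
  orf <- select_longest_orf(translate_six_frames("ATGAAATAG"), 9)
  expect_identical(orf$aa_seq, "LFH")
  expect_identical(orf$strand, "r")
  expect_identical(orf$length_aa, 3L)
  expect_true(verify_orf_coords(orf, "ATGAAATAG"))
  # a transcript that is one clean reading frame returns the whole frame
  s <- "ATGGCTGCTAAA"
  orf <- select_longest_orf(translate_six_frames(s), nchar(s))
  expect_identical(orf$aa_seq, "MAAK")
  expect_identical(orf$strand, "f")
  # no candidate above min_len -> NULL
  expect_null(select_longest_orf(translate_six_frames("ATGAAATAG"), 9,
                                 min_len = 10))
})

test_that("equal-length ORFs break ties by fixed frame order, then leftmost", {
  frames <- c(fwd0 = "*GG*", fwd1 = "AA*CC*DD", fwd2 = "*EE*",
              rev0 = "*FF*", rev1 = "HH*", rev2 = "*")
  orf <- select_longest_orf(frames, 24)
  expect_identical(orf$aa_seq, "GG")   # earliest frame wins the tie
  expect_identical(orf$strand, "f")
  expect_identical(orf$frame, 0L)
  # within one frame the leftmost of the equal-longest candidates wins
  only1 <- c(fwd0 = "*", fwd1 = "AA*CC*DD", fwd2 = "*",
             rev0 = "*", rev1 = "*", rev2 = "*")
  expect_identical(select_longest_orf(only1, 24)$aa_seq, "AA")
  frames2 <- c(fwd0 = "*", fwd1 = "*", fwd2 = "*",
               rev0 = "*KK*", rev1 = "LL*", rev2 = "*")
  orf2 <- select_longest_orf(frames2, 12)
  expect_identical(orf2$aa_seq, "KK")
  expect_identical(orf2$strand, "r")
})

test_that("longest-ORF selection equals a brute-force enumerator on random transcripts", {
  withr::with_seed(101, {
    for (k in 1:50) {
      s <- random_dna(sample(30:300, 1))
      frames <- translate_six_frames(s)
      orf <- select_longest_orf(frames, nchar(s))
      oracle <- brute_longest_orf(frames)
      expect_identical(orf$aa_seq, oracle$seq)
      expect_identical(orf$length_aa, oracle$len)
      expect_identical(paste0(ifelse(orf$strand == "f", "fwd", "rev"),
                              orf$frame), oracle$frame)
      expect_true(verify_orf_coords(orf, s))
    }
  })
})

test_that("met-to-stop policy requires a methionine start", {
  frames <- c(fwd0 = "*AMAAK*", fwd1 = "*", fwd2 = "*",
              rev0 = "*", rev1 = "*", rev2 = "*")
  loose <- select_longest_orf(frames, 21, policy = "stop-to-stop")
  strict <- select_longest_orf(frames, 21, policy = "met-to-stop")
  expect_identical(loose$aa_seq, "AMAAK")
  expect_identical(strict$aa_seq, "MAAK")
  # stretches without methionine yield no met-to-stop candidate
  frames_no_m <- c(fwd0 = "*AAK*", fwd1 = "*", fwd2 = "*",
                   rev0 = "*", rev1 = "*", rev2 = "*")
  expect_null(select_longest_orf(frames_no_m, 15, policy = "met-to-stop"))
})

test_that("a database from reverse-complemented transcripts is identical up to strand", {
  cfg <- sim_config(n_classes = 2, proteins_per_class = 3,
                    orf_len_range = c(40L, 60L), seed = 77L)
  tr <- simulate_transcripts(cfg)$transcripts
  db <- build_protein_db(tr, min_aa = 30)
  tr_rc <- tibble::tibble(id = tr$id,
                          seq = vapply(tr$seq, reverse_complement,
                                       character(1)))
  db_rc <- build_protein_db(tr_rc, min_aa = 30)
  expect_identical(db$aa_seq, db_rc$aa_seq)
  expect_true(all(db$strand != db_rc$strand))
  L <- nchar(tr$seq)
  expect_identical(db_rc$nt_start, as.integer(L - db$nt_end))
  expect_identical(db_rc$nt_end, as.integer(L - db$nt_start))
  expect_error(build_protein_db(tr[c(1, 1), ], min_aa = 3), "duplicate")
})

test_that("protein FASTA round-trips through its header annotations", {
  tr <- tibble::tibble(id = "u1", seq = "TTTATGGCTGCTAAGCCGTAA")
  db <- build_protein_db(tr, min_aa = 3)
  f <- withr::local_tempfile(fileext = ".faa")
  write_protein_fasta(db, f)
  back <- read_protein_db(f)
  expect_equal(as.data.frame(back), as.data.frame(db))
})

test_that("digestion implements the LysC and trypsin cleavage rules", {
  expect_identical(digest_protein("MKRPGKAR", "trypsin")$seq,
                   c("MK", "RPGK", "AR"))
  expect_identical(digest_protein("MKRPGKAR", "lysC")$seq,
                   c("MK", "RPGK", "AR"))
  # trypsin does not cleave K/R before proline; LysC cleaves K regardless
  expect_identical(digest_protein("AKPG", "trypsin")$seq, "AKPG")
  expect_identical(digest_protein("AKPG", "lysC")$seq, c("AK", "PG"))
  expect_identical(digest_protein("AKPG", "lysC_then_trypsin")$seq,
                   c("AK", "PG"))
  expect_identical(digest_protein("ARPG", "trypsin")$seq, "ARPG")
  expect_error(digest_protein("MKR", "pepsin"), "unknown enzyme")
})

test_that("missed-cleavage fragments join adjacent fully-cleaved fragments", {
  fr <- digest_protein("MKRPGKAR", "trypsin", max_missed = 1)
  m1 <- fr$seq[fr$missed_cleavages == 1]
  expect_identical(m1, c("MKRPGK", "RPGKAR"))
  expect_true(all(fr$seq == substring("MKRPGKAR", fr$start + 1, fr$end)))
})

test_that("zero-missed fragments partition the parent and contain no internal site", {
  withr::with_seed(23, {
    for (k in 1:20) {
      p <- random_protein(sample(20:120, 1))
      for (enz in c("trypsin", "lysC", "lysC_then_trypsin")) {
        fr <- digest_protein(p, enz, 0)
        expect_identical(paste(fr$seq, collapse = ""), p)
        # no fragment may contain an internal cleavage site of its enzyme
        internal <- vapply(fr$seq, function(s) {
          sub <- digest_protein(s, enz, 0)
          nrow(sub) > 1
        }, logical(1))
        expect_false(any(internal))
      }
    }
  })
})

test_that("molecular weight uses IUPAC average masses plus one water", {
  expect_equal(protein_mw("GG"), 132.12, tolerance = 1e-4)
  expect_equal(mw_kda(107649), 107.6)
  expect_error(protein_mw(""), "empty")
  expect_error(protein_mw("GXG"), "non-standard residue 'X'")
  # independent oracle (seqinr mass table differs in the last digits only)
  withr::with_seed(5, {
    p <- random_protein(50)
    expect_equal(protein_mw(p),
                 seqinr::pmw(strsplit(p, "")[[1]]), tolerance = 1e-4)
  })
})

test_that("molecular weight is additive up to one water mass", {
  withr::with_seed(9, {
    a <- random_protein(20); b <- random_protein(35)
    expect_equal(protein_mw(paste0(a, b)),
                 protein_mw(a) + protein_mw(b) - 18.0153, tolerance = 1e-9)
  })
})

test_that("coverage is the union of peptide occurrence intervals", {
  p <- random_protein(10)
  cv <- peptide_coverage(p, c(substr(p, 1, 4), substr(p, 3, 7)))
  expect_equal(cv$percent, 70)
  expect_equal(peptide_coverage(p, "WWWWW")$percent, 0)
  # overlapping occurrences of a repetitive peptide are all counted
  cv <- peptide_coverage("AAAAAAAAAA", "AAAA")
  expect_equal(cv$percent, 100)
})

test_that("coverage honours I/L equivalence when requested", {
  prot <- "MKILSAK"
  expect_equal(peptide_coverage(prot, "KLL", il_equivalent = TRUE)$covered_residues, 3L)
  expect_equal(peptide_coverage(prot, "KLL", il_equivalent = FALSE)$covered_residues, 0L)
})

test_that("coverage equals a position-scan oracle and is monotone", {
  withr::with_seed(31, {
    for (k in 1:40) {
      p <- random_protein(sample(20:150, 1))
      n_pep <- sample(1:8, 1)
      peps <- vapply(seq_len(n_pep), function(i) {
        w <- sample(3:12, 1)
        s <- sample(seq_len(max(1, nchar(p) - w)), 1)
        if (stats::runif(1) < 0.3) random_protein(w) else substr(p, s, s + w - 1)
      }, character(1))
      cv <- peptide_coverage(p, peps)
      expect_identical(cv$covered_residues, brute_coverage(p, peps))
      expect_gte(cv$percent, 0); expect_lte(cv$percent, 100)
      # adding a peptide never decreases coverage
      more <- peptide_coverage(p, c(peps, substr(p, 1, 5)))
      expect_gte(more$percent, cv$percent)
    }
  })
})
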