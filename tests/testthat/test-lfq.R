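two_sample_matrix <- function(values_a, values_b) {
  # one ion per element; two samples in different conditions
  design <- make_design(1)
  ev <- dplyr::bind_rows(
    make_evidence(paste0("ION", seq_along(values_a), "K"), "acidic", 1,
                  intensity = values_a),
    make_evidence(paste0("ION", seq_along(values_b), "K"), "alkaline", 1,
                  intensity = values_b)
  )
  build_quant_matrix(ev, design)
}

test_that("the quant matrix keys ions and averages repeated spectra", {
  design <- make_design(1)
  ev <- dplyr::bind_rows(
    make_evidence(rep("AAAK", 2), "acidic", 1, intensity = c(100, 300)),
    make_evidence("AAAK", "acidic", 1, intensity = 0),   # not quantified
    make_evidence("CCCK", "alkaline", 1, intensity = 50)
  )
  qm <- build_quant_matrix(ev, design)
  expect_identical(dim(qm$values), c(2L, 2L))
  expect_equal(qm$values["AAAK/2/500", "acidic_r1"], 200)  # mean of spectra
  expect_true(is.na(qm$values["AAAK/2/500", "alkaline_r1"]))
  expect_identical(qm$stage, "raw")
})

test_that("normalization divides by the sample total ion intensity", {
  qm <- two_sample_matrix(c(3e6, 1e6), c(5e5, 5e5))
  nm <- normalize_total(qm)
  expect_equal(unname(nm$values[, "acidic_r1"]), c(0.75, 0.25))
  expect_equal(unname(nm$values[, "alkaline_r1"]), c(0.5, 0.5))
  single <- two_sample_matrix(7e6, 1)
  expect_equal(unname(normalize_total(single)$values[1, 1]), 1)
  bad <- two_sample_matrix(c(1, 1), c(1, 1))
  bad$values[, "alkaline_r1"] <- NA_real_
  expect_error(normalize_total(bad), "sample 'alkaline_r1' has zero total")
})

test_that("normalized columns sum to one and match a direct recomputation", {
  withr::with_seed(71, {
    qm <- simulate_quant_matrix(20, n_reps = 3, log2_effect = 0, seed = 71)
    nm <- normalize_total(qm)
    expect_equal(unname(colSums(nm$values, na.rm = TRUE)), rep(1, 6),
                 tolerance = 1e-9)
    oracle <- sweep(qm$values, 2, colSums(qm$values, na.rm = TRUE), "/")
    expect_equal(nm$values, oracle)
  })
})

test_that("cross-treatment scaling centres each ion at its treatment mean", {
  # an ion with identical normalized value everywhere scales to 1
  qm <- simulate_quant_matrix(5, n_reps = 2, cv = 0.2, seed = 3)
  qm$values[1, ] <- 0.1
  qm$stage <- "normalized"
  sc <- scale_across_treatments(qm)
  expect_equal(unname(sc$values[1, ]), rep(1, 4))
  # treatment means 0.75 and 0.25 -> grand mean 0.5 -> scaled 1.5 and 0.5
  two <- two_sample_matrix(c(3e6, 1e6), c(1e6, 3e6))
  sc2 <- scale_across_treatments(normalize_total(two))
  expect_equal(unname(sc2$values[1, ]), c(1.5, 0.5))
  expect_equal(unname(sc2$values[2, ]), c(0.5, 1.5))
})

test_that("scaled per-ion means of treatment averages equal one", {
  withr::with_seed(73, {
    qm <- simulate_quant_matrix(50, n_reps = 4, log2_effect = 1, seed = 73)
    sc <- scale_across_treatments(normalize_total(qm))
    tm <- vapply(c("acidic", "alkaline"), function(cc) {
      cols <- sc$design$sample_id[sc$design$condition == cc]
      rowMeans(sc$values[, cols, drop = FALSE], na.rm = TRUE)
    }, numeric(nrow(sc$values)))
    expect_equal(unname(rowMeans(tm)), rep(1, nrow(sc$values)),
                 tolerance = 1e-9)
  })
})

test_that("multiplying one sample by a constant leaves downstream values unchanged", {
  qm <- simulate_quant_matrix(30, n_reps = 3, log2_effect = 0.5, seed = 79)
  qm2 <- qm
  qm2$values[, 2] <- qm2$values[, 2] * 1e3
  a <- scale_across_treatments(normalize_total(qm))
  b <- scale_across_treatments(normalize_total(qm2))
  expect_equal(a$values, b$values, tolerance = 1e-12)
})

test_that("permuting normalize and scale changes the result", {
  qm <- simulate_quant_matrix(30, n_reps = 3, log2_effect = 0.5, seed = 83)
  canonical <- scale_across_treatments(normalize_total(qm))
  permuted <- normalize_total(scale_across_treatments(qm))
  expect_false(isTRUE(all.equal(canonical$values, permuted$values)))
})

test_that("replicate averaging requires the minimum number of observations", {
  qm <- simulate_quant_matrix(3, n_reps = 3, seed = 5)
  qm$values[1, c("acidic_r1", "acidic_r2", "acidic_r3")] <- c(1.2, 0.9, 0.9)
  qm$values[2, "acidic_r3"] <- NA_real_
  qm$stage <- "scaled"
  avg <- average_replicates(qm, min_reps = 3)
  expect_equal(avg$values[1, "acidic"], 1.0)
  expect_true(is.na(avg$values[2, "acidic"]))
  expect_false(is.na(avg$values[2, "alkaline"]))
  # against a direct group-by mean
  withr::with_seed(89, {
    qm <- simulate_quant_matrix(40, n_reps = 4, seed = 89)
    qm$stage <- "scaled"
    avg <- average_replicates(qm, min_reps = 3)
    for (cc in c("acidic", "alkaline")) {
      cols <- qm$design$sample_id[qm$design$condition == cc]
      expect_equal(avg$values[, cc], rowMeans(qm$values[, cols]))
    }
  })
})

test_that("protein sums add proteotypic ions and ignore shared ones", {
  qm <- simulate_quant_matrix(3, n_reps = 3, seed = 7)
  qm$ions$peptide_seq <- c("AAAK", "CCCK", "MKLL")
  rownames(qm$values) <- qm$ions$peptide_seq
  qm$values[] <- 1
  qm$values["AAAK", c("acidic_r1", "acidic_r2", "acidic_r3")] <- 1.5
  qm$values["CCCK", c("acidic_r1", "acidic_r2", "acidic_r3")] <- 0.5
  qm$stage <- "scaled"
  avg <- average_replicates(qm, min_reps = 3)
  asn <- map_peptides(c("AAAK", "CCCK", "MKLL"),
                      tibble::tibble(unigene_id = c("P1", "P2"),
                                     aa_seq = c("MKLLAAAKCCCK", "MKLLWWW")))
  ps <- protein_sums(avg, asn)
  expect_identical(ps$protein_id, "P1")
  expect_equal(ps$acidic, 2.0)   # 1.5 + 0.5, shared MKLL excluded
  expect_equal(ps$alkaline, 2.0)
  expect_equal(ps$log2_ratio, 0)
  expect_identical(ps$n_peptides, 2L)
  # removing a non-proteotypic ion changes nothing
  qm2 <- qm; qm2$values <- qm$values[1:2, ]; qm2$ions <- qm$ions[1:2, ]
  ps2 <- protein_sums(average_replicates(qm2, 3), asn)
  expect_equal(ps2$acidic, ps$acidic)
  # a protein represented only by shared ions is omitted
  asn_shared <- map_peptides("MKLL",
                             tibble::tibble(unigene_id = c("P1", "P2"),
                                            aa_seq = c("MKLLA", "MKLLC")))
  expect_error(protein_sums(avg, asn_shared), "no proteotypic ions")
})

test_that("identical groups give zero ratio and p-value one", {
  qm <- simulate_quant_matrix(2, n_reps = 3, seed = 11)
  qm$values[1, ] <- c(1, 2, 3, 1, 2, 3)  # same triple in both conditions
  qm$values[2, ] <- rep(2, 6)            # constant everywhere
  qm$stage <- "scaled"
  dt <- differential_test(qm, level = "ion")
  expect_equal(dt$log2_ratio[1], 0)
  expect_equal(dt$p_value[1], 1)
  expect_equal(dt$p_value[2], 1)
  # constant but different groups get the smallest representable p
  qm$values[2, ] <- c(4, 4, 4, 1, 1, 1)
  dt2 <- differential_test(qm, level = "ion")
  expect_identical(dt2$p_value[2], .Machine$double.xmin)
  expect_equal(dt2$log2_ratio[2], 2)
})

test_that("null simulations yield approximately uniform p-values", {
  qm <- simulate_quant_matrix(1000, n_reps = 4, log2_effect = 0, cv = 0.2,
                              seed = 97)
  sc <- scale_across_treatments(normalize_total(qm))
  dt <- differential_test(sc, level = "ion")
  ks <- suppressWarnings(stats::ks.test(dt$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("planted two-fold ion effects are recovered", {
  n <- 1000
  effect <- rep(0, n)
  effect[1:50] <- 1; effect[51:100] <- -1
  qm <- simulate_quant_matrix(n, n_reps = 4, log2_effect = effect, cv = 0.2,
                              seed = 101)
  sc <- scale_across_treatments(normalize_total(qm))
  dt <- differential_test(sc, level = "ion")
  err <- dt$log2_ratio[1:50] - 1
  expect_lt(stats::median(abs(err)), 0.25)
  expect_lt(stats::median(abs(dt$log2_ratio[51:100] + 1)), 0.25)
})
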