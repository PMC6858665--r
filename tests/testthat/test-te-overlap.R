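te_tbl <- function(...) {
  rows <- list(...)
  tibble::tibble(
    chrom = "chr1",
    start = vapply(rows, `[[`, 1, 1),
    end = vapply(rows, `[[`, 1, 2),
    superfamily = vapply(rows, function(r) as.character(r[[3]]), ""))
}

test_that("masked fraction counts union bases within exons", {
  tx <- one_exon_tx("t", 1000, 2000)
  expect_equal(masked_fraction(tx, te_tbl(list(5000, 6000,
                                               "LTR/Gypsy")))$
                 masked_fraction, 0)
  r_full <- masked_fraction(tx, te_tbl(list(900, 2100, "LTR/Gypsy")))
  expect_equal(r_full$masked_fraction, 1)
  expect_equal(r_full$assigned_superfamily, "LTR/Gypsy")
  expect_true(r_full$is_te_lncRNA)
  # transcript-relative [0,300) and [200,500) -> union 500 of 1000
  r_half <- masked_fraction(tx, te_tbl(list(1000, 1300, "LTR/Gypsy"),
                                       list(1200, 1500, "LTR/Gypsy")))
  expect_equal(r_half$masked_fraction, 0.5)
  # spliced transcript: only exonic bases count
  tx2 <- tibble::tibble(transcript_id = "s", gene_id = "s",
                        chrom = "chr1", strand = "+",
                        start = c(0L, 600L), end = c(200L, 800L))
  r_spl <- masked_fraction(tx2, te_tbl(list(100, 700, "DNA/hAT-Ac")))
  expect_equal(r_spl$masked_fraction, (100 + 100) / 400)
})

test_that("multi-family bases are counted once, by local priority", {
  tx <- one_exon_tx("t", 0, 1000)
  # Gypsy covers 600, Copia covers 400 of which 200 also Gypsy
  r <- masked_fraction(tx, te_tbl(list(0, 600, "LTR/Gypsy"),
                                  list(400, 800, "LTR/Copia")))
  expect_equal(r$masked_bp, 800L)
  expect_equal(r$masked_fraction, 0.8)
  bp <- r$bp_by_superfamily[[1]]
  expect_equal(sum(bp), 800)
  expect_equal(unname(bp["LTR/Gypsy"]), 600) # larger local overlap wins
  expect_equal(unname(bp["LTR/Copia"]), 200)
  expect_equal(r$assigned_superfamily, "LTR/Gypsy")
  # 60/40 split without double coverage: argmax assignment
  r2 <- masked_fraction(tx, te_tbl(list(0, 600, "LTR/Gypsy"),
                                   list(600, 1000, "LTR/Copia")))
  expect_equal(r2$assigned_superfamily, "LTR/Gypsy")
  expect_equal(r2$masked_fraction, 1)
  # exact tie -> lexicographic
  r3 <- masked_fraction(tx, te_tbl(list(0, 500, "LTR/Gypsy"),
                                   list(500, 1000, "LTR/Copia")))
  expect_equal(r3$assigned_superfamily, "LTR/Copia")
})

test_that("masked fraction equals a per-base oracle on fuzzed layouts", {
  withr::with_seed(51, {
    fams <- c("LTR/Gypsy", "LTR/Copia", "DNA/hAT-Ac")
    got <- want <- numeric(1000)
    for (i in 1:1000) {
      tlen <- sample(100:400, 1)
      tstart <- sample(0:500, 1)
      tx <- one_exon_tx("t", tstart, tstart + tlen)
      nte <- sample(0:5, 1)
      te <- if (nte == 0) {
        tibble::tibble(chrom = character(), start = integer(),
                       end = integer(), superfamily = character())
      } else {
        s <- sample(0:900, nte, replace = TRUE)
        tibble::tibble(chrom = "chr1", start = s,
                       end = s + sample(30:300, nte, replace = TRUE),
                       superfamily = sample(fams, nte, replace = TRUE))
      }
      got[i] <- masked_fraction(tx, te)$masked_fraction
      tx_pos <- seq.int(tstart, tstart + tlen - 1L)
      want[i] <- length(intersect(tx_pos, bf_covered(te))) / tlen
    }
    expect_equal(got, want)
  })
})

test_that("TE-lncRNA calls respond to the overlap threshold", {
  tx <- dplyr::bind_rows(one_exon_tx("a", 0, 1000),
                         one_exon_tx("b", 2000, 3000))
  te <- te_tbl(list(0, 950, "LTR/Gypsy"))
  r <- masked_fraction(tx, te)
  expect_equal(r$is_te_lncRNA, c(TRUE, FALSE))
  r2 <- call_te_lncRNA(r, min_fraction = 0.96)
  expect_equal(r2$is_te_lncRNA, c(FALSE, FALSE))
})

test_that("superfamily enrichment reproduces composition shares", {
  tx <- dplyr::bind_rows(one_exon_tx("a", 0, 1000),
                         one_exon_tx("b", 2000, 3000))
  te <- te_tbl(list(0, 1000, "LTR/Gypsy"), list(2000, 3000, "LTR/Copia"),
               list(5000, 6000, "LTR/Gypsy"), list(7000, 8000,
                                                   "LTR/Copia"))
  r <- masked_fraction(tx, te)
  enr <- superfamily_enrichment(r, te)
  # identical composition in lncRNA and genome -> all folds 1
  expect_equal(enr$fold_ratio, c(1, 1))
  expect_equal(sum(enr$pct_of_te_lnc_bp), 100, tolerance = 1e-3)
  expect_equal(sum(enr$pct_of_genomic_te_bp), 100, tolerance = 1e-3)
  # family present in lncRNAs but absent from the annotation is flagged
  te_missing <- dplyr::filter(te, superfamily != "LTR/Copia")
  enr2 <- superfamily_enrichment(r, te_missing)
  expect_true(enr2$fold_infinite[enr2$superfamily == "LTR/Copia"])
  expect_true(is.infinite(
    enr2$fold_ratio[enr2$superfamily == "LTR/Copia"]))
})

test_that("planted DNA-transposon oversampling is recovered as ~2x fold", {
  bias <- c("DNA/CMC-EnSpm" = 2, "DNA/hAT-Ac" = 2, "DNA/MULE-MuDR" = 2,
            "DNA/PIF-Harbinger" = 2)
  cfg <- sim_config(seed = 61, genome_length = 1.2e6, n_genes = 60,
                    n_lncRNA = 150, frac_te_derived = 0.9,
                    frac_intronic = 0, n_modules = 0,
                    lnc_te_family_bias = bias)
  gen <- simulate_genome_and_annotations(cfg)
  tx <- simulate_transcripts(cfg, gen$genome, gen$ann, gen$te)
  lnc <- tx$truth$transcript_id[tx$truth$class != "coding"]
  r <- masked_fraction(dplyr::filter(tx$exons, transcript_id %in% lnc),
                       gen$te)
  grp <- enrichment_groups(superfamily_enrichment(r, gen$te))
  fold <- grp$fold_ratio[grp$te_group == "DNA transposons"]
  expect_gte(fold, 1.7)
  expect_lte(fold, 2.3)
})

test_that("the 2x2 chi-squared test matches the Pearson formula", {
  flat <- chisq_2x2(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  tab <- matrix(c(20, 5, 5, 20), 2, 2)
  got <- chisq_2x2(tab)
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(got$statistic, sum((tab - exp_tab)^2 / exp_tab))
  expect_error(chisq_2x2(matrix(c(0, 0, 5, 5), 2, 2)), "margin")
})

test_that("masked-fraction histogram conserves counts and the >=90% bin", {
  r <- tibble::tibble(masked_fraction = c(0.05, 0.95, 0.92, 1, 0),
                      is_te_lncRNA = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  h <- masked_fraction_histogram(r)
  expect_equal(sum(h$count), 4L)
  expect_equal(h$count[h$bin_low == 0.9], 3L)
  expect_equal(attr(h, "n_ge90"), 3L)
  all_full <- tibble::tibble(masked_fraction = rep(1, 5),
                             is_te_lncRNA = TRUE)
  h2 <- masked_fraction_histogram(all_full)
  expect_equal(h2$count[h2$bin_low == 0.9], 5L)
  expect_equal(sum(h2$count[h2$bin_low < 0.9]), 0L)
})
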