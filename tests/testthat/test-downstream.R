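test_that("nearest gene minimizes span distance with upstream ties", {
  ann <- toy_annotation() # gA 1000-2000 (+), gB 9500-10500 (-)
  # gap to gA = 3000, to gB = 3500
  loci <- tibble::tibble(transcript_id = "l1", chrom = "chr1",
                         strand = "+", start = 5000L, end = 6000L)
  link <- nearest_gene(loci, ann)
  expect_equal(link$gene_id, "gA")
  expect_equal(link$distance, 3000L)
  expect_equal(link$side, "upstream")
  # intronic locus touches its host gene at distance 0
  intr <- tibble::tibble(transcript_id = "l2", chrom = "chr1",
                         strand = "+", start = 1350L, end = 1650L)
  expect_equal(nearest_gene(intr, ann)$distance, 0L)
  expect_equal(nearest_gene(intr, ann)$gene_id, "gA")
  # exactly equidistant flanks resolve upstream and are flagged
  mid <- tibble::tibble(transcript_id = "l3", chrom = "chr1",
                        strand = "+", start = 5250L, end = 6250L)
  tie <- nearest_gene(mid, ann)
  expect_equal(tie$gene_id, "gA")
  expect_true(tie$tie_flag)
  # no gene on the chromosome: dropped with a warning
  off <- tibble::tibble(transcript_id = "l4", chrom = "chr9",
                        strand = "+", start = 0L, end = 100L)
  expect_warning(out <- nearest_gene(dplyr::bind_rows(loci, off), ann),
                 "dropped")
  expect_equal(nrow(out), 1L)
})

test_that("nearest gene agrees with brute force on fuzzed annotations", {
  withr::with_seed(91, {
    ok <- logical(200)
    for (i in 1:200) {
      ng <- sample(2:8, 1)
      gs <- sort(sample.int(20000L, ng))
      genes <- tibble::tibble(gene_id = paste0("g", seq_len(ng)),
                              chrom = "chr1", strand = "+",
                              start = gs, end = gs + 500L)
      ann <- gene_annotation(genes,
                             dplyr::mutate(genes, gene_id = gene_id) |>
                               dplyr::select(gene_id, chrom, start, end))
      st <- sample.int(21000L, 1)
      locus <- tibble::tibble(transcript_id = "x", chrom = "chr1",
                              strand = "+", start = st, end = st + 300L)
      got <- nearest_gene(locus, ann)
      d <- pmax(genes$start - (st + 300L), st - genes$end, 0)
      ok[i] <- got$distance == min(d)
    }
    expect_true(all(ok))
  })
})

test_that("cis correlation behaves on exact and degenerate input", {
  pairs <- tibble::tibble(lnc_log2FC = c(1, -2, 3, 0.5),
                          gene_log2FC = c(1, -2, 3, 0.5))
  cc <- cis_correlation(pairs)
  expect_equal(cc$r, 1)
  expect_equal(cc$n, 4L)
  expect_error(cis_correlation(pairs[1:2, ]), ">= 3")
  # non-finite rows are dropped before correlating
  pairs$gene_log2FC[4] <- NA
  expect_equal(cis_correlation(pairs)$n, 3L)
  # independent effects: negligible correlation at n = 500
  withr::with_seed(92, {
    indep <- tibble::tibble(lnc_log2FC = rnorm(500),
                            gene_log2FC = rnorm(500))
    expect_lt(abs(cis_correlation(indep)$r), 0.15)
  })
})

test_that("expression summaries report class means of per-transcript
          maxima", {
  fpkm <- matrix(c(1, 5, 3,
                   2, 2, 2,
                   10, 24, 2), 3, 3, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), paste0("s", 1:3)))
  cls <- tibble::tibble(transcript_id = c("a", "b", "c"),
                        class = c("lncRNA", "lncRNA", "coding"))
  out <- expression_summary(fpkm, cls)
  expect_equal(out$mean_max_fpkm[out$class == "lncRNA"], (5 + 2) / 2)
  expect_equal(out$mean_max_fpkm[out$class == "coding"], 24)
  expect_equal(out$coding_fold[out$class == "lncRNA"], 24 / 3.5)
})

test_that("expression entropy follows the definition in bits", {
  expect_equal(unname(shannon_entropy(c(1, 1, 1, 1))), 2)
  expect_equal(unname(shannon_entropy(c(0, 3, 0, 0))), 0)
  expect_equal(unname(shannon_entropy(c(2, 1, 1, 0))), 1.5)
  expect_true(is.na(shannon_entropy(c(0, 0, 0))))
  # permutation invariance and the log2(G) bound
  withr::with_seed(93, {
    m <- matrix(rexp(60), 10, 6)
    h1 <- shannon_entropy(m)
    h2 <- shannon_entropy(m[, sample(6)])
    expect_equal(h1, h2)
    expect_true(all(h1 <= log2(6) + 1e-12))
  })
  # grouped means from a sample table
  fpkm <- matrix(c(4, 4, 0, 0), 1, 4,
                 dimnames = list("t", paste0("s", 1:4)))
  samples <- tibble::tibble(sample_id = paste0("s", 1:4),
                            condition = c("heat", "heat", "cold", "cold"),
                            stage = "V3")
  gm <- expression_group_means(fpkm, samples)
  expect_equal(unname(shannon_entropy(gm)), 0)
})

test_that("Fisher enrichment equals hypergeometric enumeration", {
  tm <- tibble::tibble(term = rep(c("T1", "T2"), each = 5),
                       gene_id = c(paste0("g", 1:5), paste0("g", 11:15)))
  uni <- paste0("g", 1:20)
  out <- fisher_enrichment(paste0("g", 1:5), tm, uni)
  expect_equal(out$p_value[out$term == "T1"], 1 / choose(20, 5))
  expect_equal(out$p_value[out$term == "T2"], 1) # disjoint
  expect_equal(out$p_bonferroni,
               pmin(1, out$p_value * 2))
  expect_error(fisher_enrichment(c("g1", "zz"), tm, uni), "zz")
  # fuzz against the enumeration oracle at margins <= 50
  withr::with_seed(94, {
    got <- want <- numeric(200)
    for (i in 1:200) {
      N <- sample(10:50, 1)
      m <- sample(1:N, 1)
      k <- sample(1:N, 1)
      uni <- paste0("u", seq_len(N))
      term <- tibble::tibble(term = "T", gene_id = sample(uni, m))
      sel <- sample(uni, k)
      got[i] <- fisher_enrichment(sel, term, uni)$p_value
      want[i] <- bf_fisher_p(length(intersect(term$gene_id, sel)),
                             m, N, k)
    }
    expect_equal(got, want)
  })
})

test_that("delta-delta-Ct fold changes follow the comparative method", {
  ct <- tibble::tibble(
    role = rep(c("target", "reference"), each = 6),
    arm = rep(rep(c("treated", "control"), each = 3), 2),
    ct = c(20, 20, 20, 22, 22, 22, 18, 18, 18, 18, 18, 18))
  out <- ddct_fold_change(ct)
  expect_equal(out$ddct, -2)
  expect_equal(out$fold, 4)
  # all four cell means equal -> fold 1
  flat <- dplyr::mutate(ct, ct = 20)
  expect_equal(ddct_fold_change(flat)$fold, 1)
  # swapping arms inverts the fold exactly
  swapped <- dplyr::mutate(ct, arm = ifelse(arm == "treated", "control",
                                            "treated"))
  expect_equal(ddct_fold_change(swapped)$fold, 1 / out$fold)
  expect_error(ddct_fold_change(ct[ct$arm == "treated", ]), "missing")
})
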