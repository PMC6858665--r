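test_that("FPKM follows the definition", {
  m <- matrix(c(100, 0, 250), 3, 1,
              dimnames = list(c("a", "b", "c"), "s1"))
  lens <- c(a = 1000, b = 500, c = 500)
  f1 <- compute_fpkm(m[1, , drop = FALSE], lens["a"],
                     c(s1 = 1e6))
  expect_equal(unname(f1[1, 1]), 100)
  f <- compute_fpkm(m, lens, c(s1 = 2e7))
  expect_equal(unname(f["b", 1]), 0)
  expect_equal(unname(f["c", 1]), 25)
  expect_error(compute_fpkm(m, lens, c(s1 = 0)), "library size")
  expect_error(compute_fpkm(m, c(a = 0, b = 500, c = 500), c(s1 = 1e6)),
               "lengths")
})

test_that("polyA origin follows total-RNA-only detection", {
  samples <- tibble::tibble(sample_id = c("p1", "p2", "t1"),
                            library_type = c("polyA", "polyA", "total"))
  fpkm <- matrix(c(0, 5, 0,   0, 0, 0,   5, 5, 0), 3, 3, byrow = FALSE,
                 dimnames = list(c("x", "y", "z"), samples$sample_id))
  # x: FPKM 5 in total only -> polyA_minus; y: 5 in a polyA sample ->
  # polyA_plus; z: nothing anywhere -> polyA_plus, flagged
  o <- assign_polyA_origin(fpkm, samples)
  expect_equal(o$polyA_origin, c("polyA_minus", "polyA_plus",
                                 "polyA_plus"))
  expect_equal(o$origin_flagged, c(FALSE, FALSE, TRUE))
  expect_error(assign_polyA_origin(fpkm, samples[1:2, ]), "total")
})

test_that("coding-potential verdict intersects external evidence", {
  orf <- tibble::tibble(transcript_id = c("a", "b", "c"),
                        longest_orf_aa = c(40L, 40L, 40L))
  lens <- c(a = 600, b = 600, c = 600)
  ev <- tibble::tibble(transcript_id = c("a", "b"),
                       cpc2_score = c(-2, -2),
                       cnci_label = c("noncoding", "coding"))
  cfg <- discovery_config(require_both_predictors = FALSE)
  v <- coding_potential_verdict(orf, ev, lens, cfg)
  expect_equal(v$coding_verdict[v$transcript_id == "a"], "noncoding")
  expect_equal(v$coding_verdict[v$transcript_id == "b"], "coding")
  # c falls back to the stand-in: 40 aa in 600 nt -> coverage 0.205
  expect_equal(v$coding_verdict[v$transcript_id == "c"], "noncoding")
  expect_error(
    coding_potential_verdict(orf, ev, lens, discovery_config()),
    "missing")
  # stand-in rejects ORFs covering >= 35% of the transcript
  orf2 <- tibble::tibble(transcript_id = "d", longest_orf_aa = 80L)
  v2 <- coding_potential_verdict(orf2, NULL, c(d = 600), cfg)
  expect_equal(v2$coding_verdict, "coding") # 243/600 = 0.405
})

test_that("class codes distinguish intergenic, intronic, exon overlap", {
  ann <- toy_annotation()
  tx <- dplyr::bind_rows(
    one_exon_tx("far", 5000, 5600),         # 3-4 kb from both genes
    one_exon_tx("inA", 1350, 1650),         # inside gA's intron
    one_exon_tx("hitA", 1295, 1500),        # overlaps gA exon by 5 bp
    one_exon_tx("straddle", 900, 1100))     # crosses gA boundary
  codes <- classify_locus(tx, ann)
  got <- setNames(codes$class_code, codes$transcript_id)
  expect_equal(unname(got["far"]), "u")
  expect_equal(unname(got["inA"]), "i")
  expect_equal(unname(got["hitA"]), "excluded")
  expect_equal(unname(got["straddle"]), "excluded")
  expect_warning(classify_locus(one_exon_tx("offchrom", 0, 300,
                                            chrom = "chrX"), ann),
                 "absent")

  known <- tibble::tibble(chrom = "chr1", start = c(4900L, 5500L),
                          end = c(5700L, 5800L))
  codes2 <- classify_locus(tx, ann, known_lnc = known)
  expect_equal(codes2$class_code[codes2$transcript_id == "far"],
               "annotated_lnc_within")
  known_part <- tibble::tibble(chrom = "chr1", start = 5500L, end = 5800L)
  codes3 <- classify_locus(tx, ann, known_lnc = known_part)
  expect_equal(codes3$class_code[codes3$transcript_id == "far"],
               "annotated_lnc_overlap")
})

test_that("class codes match a per-base oracle on random placements", {
  ann <- toy_annotation()
  gene_ex <- bf_covered(ann$exons)
  gene_span <- unlist(Map(function(s, e) seq.int(s, e - 1L),
                          ann$genes$start, ann$genes$end))
  intronA <- setdiff(seq.int(1000L, 1999L), bf_covered(
    dplyr::filter(ann$exons, gene_id == "gA")))
  withr::with_seed(41, {
    got <- want <- character(500)
    for (i in 1:500) {
      st <- sample.int(11000L, 1) - 1L
      w <- sample(50:800, 1)
      tx <- one_exon_tx("t", st, st + w)
      got[i] <- classify_locus(tx, ann)$class_code
      pos <- seq.int(st, st + w - 1L)
      want[i] <- if (any(pos %in% gene_ex)) "excluded"
      else if (!any(pos %in% gene_span)) "u"
      else if (all(pos %in% intronA)) "i"
      else "excluded"
    }
    expect_identical(got, want)
  })
})

test_that("the discovery cascade applies every filter with its reason", {
  sim <- small_sim()
  spans <- transcript_spans(sim$exons)
  fpkm <- compute_fpkm(sim$counts,
                       setNames(spans$length, spans$transcript_id),
                       setNames(sim$samples$library_size,
                                sim$samples$sample_id))
  cfg <- discovery_config(require_both_predictors = FALSE)
  disc <- run_discovery(sim$exons, sim$seqs, sim$ann, fpkm, sim$samples,
                        config = cfg)
  rec <- disc$records
  truth <- sim$truth$transcripts

  # every planted coding transcript is rejected
  cod <- truth$transcript_id[truth$class == "coding"]
  expect_true(all(!rec$passed[rec$transcript_id %in% cod]))
  # at least 95% of planted lncRNAs pass (FPKM may drop a few by design)
  lnc <- truth$transcript_id[truth$class != "coding"]
  expect_gte(mean(rec$passed[rec$transcript_id %in% lnc]), 0.95)
  # any lncRNA that failed did so only on expression
  failed_lnc <- rec[rec$transcript_id %in% lnc & !rec$passed, ]
  expect_true(all(unlist(failed_lnc$rejection_reasons) == "fpkm"))
  # category counts sum to the total passed count
  s <- discovery_summary(disc)
  shares <- discovery_shares(s)
  expect_equal(shares$total_from_categories,
               s$total[s$origin == "total"])
  expect_equal(s$total[s$origin == "total"], sum(rec$passed))

  # targeted rejections carry the expected reasons
  ev <- tibble::tibble(transcript_id = rec$transcript_id,
                       pfam_best_evalue = NA_real_)
  ev$pfam_best_evalue[1] <- 1e-6
  ev$pfam_best_evalue[2] <- 1e-4
  disc2 <- run_discovery(sim$exons, sim$seqs, sim$ann, fpkm, sim$samples,
                         evidence = ev, config = cfg)
  r2 <- disc2$records
  expect_true("pfam" %in% r2$rejection_reasons[[1]])
  expect_false("pfam" %in% r2$rejection_reasons[[2]])

  short_seqs <- sim$seqs
  short_seqs$seq[match(lnc[1], short_seqs$id)] <-
    substr(short_seqs$seq[match(lnc[1], short_seqs$id)], 1, 150)
  ex150 <- sim$exons
  i <- which(ex150$transcript_id == lnc[1])
  ex150$end[i] <- ex150$start[i] + 150L
  disc3 <- run_discovery(ex150, short_seqs, sim$ann, fpkm, sim$samples,
                         config = cfg)
  expect_true("length" %in%
                disc3$records$rejection_reasons[[
                  match(lnc[1], disc3$records$transcript_id)]])
})
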