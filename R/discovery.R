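#' Configuration for the lncRNA discovery cascade
#'
#' Thresholds for the filter cascade: minimum transcript length, maximum
#' longest-ORF length, Pfam e-value exclusion, expression floor, and the
#' CPC2 score below which a transcript is called non-coding. With
#' `require_both_predictors = TRUE` both external coding-potential verdicts
#' (CPC2 score and CNCI label) must be present; with `FALSE`, transcripts
#' lacking them fall back to an internal ORF-based stand-in (non-coding iff
#' the longest ORF is below `max_orf_aa` and covers less than 35% of the
#' transcript).
#'
#' @param min_length_nt Minimum transcript length (nt).
#' @param max_orf_aa Longest-ORF ceiling (amino acids, exclusive).
#' @param min_orf_aa_to_count Minimum ORF length counted in `orf_count`.
#' @param pfam_evalue_max Reject when the best Pfam e-value is at or below
#'   this.
#' @param min_fpkm FPKM that must be exceeded in at least one sample.
#' @param cpc2_noncoding_max_score CPC2 score strictly below which the CPC2
#'   verdict is non-coding.
#' @param require_both_predictors Require external CPC2+CNCI evidence.
#' @return A list of class `discovery_config`.
#' @export
discovery_config <- function(min_length_nt = 200L, max_orf_aa = 100L,
                             min_orf_aa_to_count = 30L,
                             pfam_evalue_max = 1e-5, min_fpkm = 1.0,
                             cpc2_noncoding_max_score = -1,
                             require_both_predictors = TRUE) {
  .check(min_length_nt > 0 && max_orf_aa > 0 && pfam_evalue_max > 0 &&
           min_fpkm >= 0, "discovery_config(): thresholds must be positive")
  structure(list(min_length_nt = as.integer(min_length_nt),
                 max_orf_aa = as.integer(max_orf_aa),
                 min_orf_aa_to_count = as.integer(min_orf_aa_to_count),
                 pfam_evalue_max = pfam_evalue_max, min_fpkm = min_fpkm,
                 cpc2_noncoding_max_score = cpc2_noncoding_max_score,
                 require_both_predictors = isTRUE(require_both_predictors)),
            class = "discovery_config")
}

#' Compute FPKM from raw counts
#'
#' FPKM = count / ((length / 1e3) * (library_size / 1e6)): fragments per
#' kilobase of exon model per million mapped fragments.
#'
#' @param counts Counts tibble (`transcript_id` + sample columns) or matrix.
#' @param lengths Named vector of transcript lengths (nt), or a tibble with
#'   `transcript_id` and `length`.
#' @param library_sizes Named vector of mapped fragments per sample;
#'   defaults to column sums of `counts`.
#' @return A matrix of FPKM values with transcript rownames.
#' @export
compute_fpkm <- function(counts, lengths, library_sizes = NULL) {
  m <- .counts_matrix(counts)
  if (is.data.frame(lengths)) {
    lengths <- setNames(lengths$length, lengths$transcript_id)
  }
  .check(all(rownames(m) %in% names(lengths)),
         "compute_fpkm(): missing lengths for some transcripts")
  len <- lengths[rownames(m)]
  .check(all(len > 0), "compute_fpkm(): lengths must be > 0")
  if (is.null(library_sizes)) library_sizes <- colSums(m)
  .check(all(library_sizes > 0), "compute_fpkm(): zero library size")
  ls <- library_sizes[colnames(m)]
  sweep(sweep(m, 1, len / 1e3, "/"), 2, ls / 1e6, "/")
}

#' Assign polyA origin from library-type detection
#'
#' A transcript is `polyA_minus` iff its FPKM exceeds `min_fpkm` in at least
#' one total-RNA sample and in no polyA+ sample; otherwise `polyA_plus`.
#' Transcripts expressed nowhere are `polyA_plus` by convention and flagged
#' (they are rejected by the FPKM filter anyway).
#'
#' @param fpkm FPKM matrix (transcripts x samples).
#' @param samples Sample tibble with `sample_id` and
#'   `library_type` in `{"polyA", "total"}`.
#' @param min_fpkm Detection threshold (strictly exceeded).
#' @return Tibble with `transcript_id`, `polyA_origin`, `origin_flagged`.
#' @export
assign_polyA_origin <- function(fpkm, samples, min_fpkm = 1.0) {
  .check(all(c("polyA", "total") %in% samples$library_type),
         "assign_polyA_origin(): need both polyA and total samples")
  polya_cols <- samples$sample_id[samples$library_type == "polyA"]
  total_cols <- samples$sample_id[samples$library_type == "total"]
  in_polya <- rowSums(fpkm[, polya_cols, drop = FALSE] > min_fpkm) > 0
  in_total <- rowSums(fpkm[, total_cols, drop = FALSE] > min_fpkm) > 0
  tibble(
    transcript_id = rownames(fpkm),
    polyA_origin = unname(if_else(in_total & !in_polya, "polyA_minus",
                                  "polyA_plus")),
    origin_flagged = unname(!in_total & !in_polya)
  )
}

#' Coding-potential verdict from external evidence or ORF stand-in
#'
#' With both external verdicts present a transcript is non-coding iff its
#' CPC2 score is below the configured threshold AND its CNCI label is
#' non-coding (intersection rule). When evidence is partially absent and
#' strict mode is off, the internal stand-in is used instead; in strict mode
#' absent evidence is a configuration error.
#'
#' @param orf ORF tibble from [find_orfs_all()] (needs `transcript_id`,
#'   `longest_orf_aa`).
#' @param evidence Tibble with `transcript_id` and optional `cpc2_score`,
#'   `cnci_label` (`"coding"`/`"noncoding"`), `pfam_best_evalue`; may be
#'   `NULL`.
#' @param lengths Named vector of transcript lengths (for stand-in ORF
#'   coverage).
#' @param config A [discovery_config()].
#' @return Tibble with `transcript_id` and `coding_verdict`.
#' @export
coding_potential_verdict <- function(orf, evidence, lengths,
                                     config = discovery_config()) {
  if (is.data.frame(lengths)) {
    lengths <- setNames(lengths$length, lengths$transcript_id)
  }
  tab <- tibble(transcript_id = orf$transcript_id,
                longest_orf_aa = orf$longest_orf_aa,
                length = unname(lengths[orf$transcript_id]))
  if (!is.null(evidence)) {
    ev <- select(evidence, dplyr::any_of(c("transcript_id", "cpc2_score",
                                           "cnci_label")))
    tab <- left_join(tab, ev, by = "transcript_id")
  }
  if (!"cpc2_score" %in% names(tab)) tab$cpc2_score <- NA_real_
  if (!"cnci_label" %in% names(tab)) tab$cnci_label <- NA_character_
  have_both <- !is.na(tab$cpc2_score) & !is.na(tab$cnci_label)
  if (config$require_both_predictors && !all(have_both)) {
    abort(paste0("coding_potential_verdict(): external CPC2/CNCI evidence ",
                 "missing for ", sum(!have_both), " transcript(s) under ",
                 "require_both_predictors = TRUE"))
  }
  ext_nc <- tab$cpc2_score < config$cpc2_noncoding_max_score &
    tab$cnci_label == "noncoding"
  # stand-in: short longest ORF that covers < 35% of the transcript
  orf_cov <- (3 * (tab$longest_orf_aa + 1)) / tab$length
  standin_nc <- tab$longest_orf_aa < config$max_orf_aa & orf_cov < 0.35
  verdict <- if_else(have_both, ext_nc, standin_nc)
  tibble(transcript_id = tab$transcript_id,
         coding_verdict = if_else(verdict, "noncoding", "coding"))
}

#' Assign genomic class codes relative to a gene annotation
#'
#' gffcompare-style class codes for lncRNA candidacy: `u` when the
#' transcript span overlaps no gene span (intergenic), `i` when every
#' transcript base lies within introns of a single gene with no exon
#' overlap, and `excluded` when any base overlaps a gene exon (or the
#' transcript straddles a gene boundary without being intron-contained).
#' When a known-lncRNA annotation is supplied, `u`/`i` candidates falling
#' within or overlapping a known lncRNA locus are relabeled
#' `annotated_lnc_within` / `annotated_lnc_overlap`.
#'
#' @param transcripts Per-exon tibble (see [read_gtf()]).
#' @param ann A [gene_annotation()].
#' @param known_lnc Optional tibble of known lncRNA loci (`chrom`, `start`,
#'   `end`).
#' @return Tibble with `transcript_id` and `class_code`.
#' @export
classify_locus <- function(transcripts, ann, known_lnc = NULL) {
  spans <- transcript_spans(transcripts)
  missing_chrom <- setdiff(spans$chrom, ann$genes$chrom)
  if (length(missing_chrom)) {
    warn(paste0("classify_locus(): chromosome(s) absent from annotation, ",
                "treating their transcripts as 'u': ",
                paste(missing_chrom, collapse = ", ")))
  }
  code <- vapply(seq_len(nrow(spans)), function(i) {
    sp <- spans[i, ]
    tex <- filter(transcripts, .data$transcript_id == sp$transcript_id)
    genes <- filter(ann$genes, .data$chrom == sp$chrom,
                    .data$start < sp$end, .data$end > sp$start)
    if (nrow(genes) == 0) return("u")
    gex <- filter(ann$exons, .data$gene_id %in% genes$gene_id)
    exon_bp <- interval_overlap_bp(select(tex, "chrom", "start", "end"),
                                   select(gex, "chrom", "start", "end"))
    if (exon_bp > 0) return("excluded")
    # intronic: all bases inside introns of a single overlapping gene
    for (g in genes$gene_id) {
      gin <- filter(ann$introns, .data$gene_id == g)
      if (nrow(gin) == 0) next
      inside <- interval_overlap_bp(select(tex, "chrom", "start", "end"),
                                    select(gin, "chrom", "start", "end"))
      if (inside == sp$length) return("i")
    }
    "excluded"
  }, "")
  if (!is.null(known_lnc) && nrow(known_lnc)) {
    for (i in which(code %in% c("u", "i"))) {
      sp <- spans[i, ]
      kl <- filter(known_lnc, .data$chrom == sp$chrom,
                   .data$start < sp$end, .data$end > sp$start)
      if (nrow(kl) == 0) next
      within <- any(kl$start <= sp$start & kl$end >= sp$end)
      code[i] <- if (within) "annotated_lnc_within" else
        "annotated_lnc_overlap"
    }
  }
  tibble(transcript_id = spans$transcript_id, class_code = code)
}

#' Run the full lncRNA discovery cascade
#'
#' Applies, in order, the length, coding-potential, Pfam, class-code and
#' FPKM filters; the order affects only the recorded rejection reasons, not
#' membership. A transcript passes iff its length is at least
#' `min_length_nt`, its coding-potential verdict is non-coding, it has no
#' Pfam hit at e-value at or below `pfam_evalue_max`, its longest ORF is
#' shorter than `max_orf_aa`, its class code is `u`, `i` or an
#' annotated-lncRNA code, and its FPKM exceeds `min_fpkm` in at least one
#' sample.
#'
#' @param transcripts Per-exon tibble (see [read_gtf()]).
#' @param seqs Tibble with `id`, `seq` (spliced transcript sequences).
#' @param ann A [gene_annotation()].
#' @param fpkm FPKM matrix from [compute_fpkm()].
#' @param samples Sample tibble (see [read_samples()]).
#' @param evidence Optional external evidence tibble (see
#'   [coding_potential_verdict()]).
#' @param known_lnc Optional known-lncRNA loci.
#' @param config A [discovery_config()].
#' @return An object of class `lnc_discovery`: list with `records` (one row
#'   per transcript: verdict trail, class code, polyA origin, ORF stats, max
#'   FPKM, `passed`, `rejection_reasons`) and `config`.
#' @export
run_discovery <- function(transcripts, seqs, ann, fpkm, samples,
                          evidence = NULL, known_lnc = NULL,
                          config = discovery_config()) {
  spans <- transcript_spans(transcripts)
  lengths <- setNames(spans$length, spans$transcript_id)
  orf <- find_orfs_all(seqs, min_aa = config$min_orf_aa_to_count)
  verdict <- coding_potential_verdict(orf, evidence, lengths, config)
  codes <- classify_locus(transcripts, ann, known_lnc)
  origin <- assign_polyA_origin(fpkm, samples, config$min_fpkm)
  pfam <- rep(NA_real_, nrow(spans))
  if (!is.null(evidence) && "pfam_best_evalue" %in% names(evidence)) {
    pfam <- evidence$pfam_best_evalue[
      match(spans$transcript_id, evidence$transcript_id)]
  }
  rec <- spans |>
    left_join(orf, by = "transcript_id") |>
    left_join(verdict, by = "transcript_id") |>
    left_join(codes, by = "transcript_id") |>
    left_join(origin, by = "transcript_id") |>
    mutate(pfam_best_evalue = pfam,
           max_fpkm = apply(fpkm[.data$transcript_id, , drop = FALSE], 1,
                            max))
  ok_class <- c("u", "i", "annotated_lnc_within", "annotated_lnc_overlap")
  reasons <- purrr::pmap(
    list(rec$length, rec$coding_verdict, rec$pfam_best_evalue,
         rec$longest_orf_aa, rec$class_code, rec$max_fpkm),
    function(len, cv, pf, orf_aa, cc, mf) {
      r <- character()
      if (len < config$min_length_nt) r <- c(r, "length")
      if (cv != "noncoding") r <- c(r, "coding_potential")
      if (!is.na(pf) && pf <= config$pfam_evalue_max) r <- c(r, "pfam")
      if (orf_aa >= config$max_orf_aa) r <- c(r, "orf")
      if (!cc %in% ok_class) r <- c(r, "class_code")
      if (!(mf > config$min_fpkm)) r <- c(r, "fpkm")
      r
    })
  rec$rejection_reasons <- reasons
  rec$passed <- lengths(reasons) == 0
  structure(list(records = rec, config = config), class = "lnc_discovery")
}

#' @export
print.lnc_discovery <- function(x, ...) {
  cat("<lnc_discovery> ", nrow(x$records), " transcripts, ",
      sum(x$records$passed), " lncRNAs passed\n", sep = "")
  invisible(x)
}

#' Category accounting of discovered lncRNAs
#'
#' Tabulates passed lncRNAs per polyA origin and genomic category
#' (lincRNA = class `u`, intronic = class `i`, fall-within / overlap with
#' annotated lncRNAs), with a total row; categories row-sum to the totals.
#' When a TE-overlap result is supplied a `te_lncRNA` count and `pct_te`
#' share per origin are added.
#'
#' @param discovery A [run_discovery()] result, or its `records` tibble.
#' @param te_result Optional per-transcript tibble from [masked_fraction()].
#' @return A tibble shaped like a discovery-summary table: one row per
#'   origin plus `"total"`.
#' @export
discovery_summary <- function(discovery, te_result = NULL) {
  rec <- if (inherits(discovery, "lnc_discovery")) discovery$records else
    discovery
  passed <- filter(rec, .data$passed)
  per <- passed |>
    group_by(origin = .data$polyA_origin) |>
    summarise(
      total = n(),
      lincRNA = sum(.data$class_code == "u"),
      intronic = sum(.data$class_code == "i"),
      annotated_within = sum(.data$class_code == "annotated_lnc_within"),
      annotated_overlap = sum(.data$class_code == "annotated_lnc_overlap"),
      .groups = "drop"
    )
  for (orig in c("polyA_minus", "polyA_plus")) {
    if (!orig %in% per$origin) {
      per <- bind_rows(per, tibble(origin = orig, total = 0L, lincRNA = 0L,
                                   intronic = 0L, annotated_within = 0L,
                                   annotated_overlap = 0L))
    }
  }
  per <- arrange(per, .data$origin)
  tot <- summarise(per, origin = "total",
                   across(c("total", "lincRNA", "intronic",
                            "annotated_within", "annotated_overlap"), sum))
  out <- bind_rows(per, tot)
  if (!is.null(te_result)) {
    te_ids <- te_result$transcript_id[te_result$is_te_lncRNA]
    te_n <- vapply(seq_len(nrow(out)), function(i) {
      ids <- if (out$origin[i] == "total") passed$transcript_id else
        passed$transcript_id[passed$polyA_origin == out$origin[i]]
      sum(ids %in% te_ids)
    }, 1L)
    out$te_lncRNA <- te_n
    out$pct_te <- ifelse(out$total > 0, 100 * te_n / out$total, NA_real_)
  }
  out
}

#' Shares derived from a discovery-summary table
#'
#' Worked-example arithmetic on a discovery summary (origin x category
#' counts): the total reconstructed by summing the per-origin category
#' counts, the polyA-minus share among lincRNAs, and (when TE counts are
#' present) the TE-lncRNA share of all lncRNAs.
#'
#' @param summary A tibble shaped like [discovery_summary()] output (rows
#'   `polyA_minus`, `polyA_plus`, `total`).
#' @return A one-row tibble: `total_from_categories`,
#'   `polyA_minus_lincRNA_pct`, and `te_lncRNA_pct` when available.
#' @export
discovery_shares <- function(summary) {
  cats <- c("lincRNA", "intronic", "annotated_within", "annotated_overlap")
  per <- filter(summary, .data$origin != "total")
  tot_row <- filter(summary, .data$origin == "total")
  out <- tibble(
    total_from_categories = sum(as.matrix(per[, cats])),
    polyA_minus_lincRNA_pct =
      100 * per$lincRNA[per$origin == "polyA_minus"] / sum(per$lincRNA)
  )
  if ("te_lncRNA" %in% names(summary)) {
    out$te_lncRNA_pct <- 100 * tot_row$te_lncRNA / tot_row$total
  }
  out
}
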