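#' Per-transcript TE masked fraction and superfamily attribution
#'
#' Computes, for each transcript, the fraction of its (exonic) length
#' covered by transposable-element intervals, the covered bases per TE
#' superfamily, and an assigned superfamily. Bases covered by several
#' superfamilies are counted once toward `masked_bp` and attributed to the
#' family with the larger local (per-transcript) overlap, ties broken
#' lexicographically, so `masked_fraction` never exceeds 1. Overlap is
#' strand-agnostic, matching orientation-free repeat masking.
#'
#' @param transcripts Per-exon tibble (see [read_gtf()]).
#' @param te TE annotation tibble (`chrom`, `start`, `end`, `superfamily`).
#' @param min_fraction Masked fraction strictly above which a transcript is
#'   called a TE-lncRNA (default: any overlap).
#' @return A tibble with one row per transcript: `transcript_id`, `length`,
#'   `masked_bp`, `masked_fraction`, `assigned_superfamily` (`NA` when
#'   unmasked), `is_te_lncRNA`, and a list-column `bp_by_superfamily`.
#' @export
masked_fraction <- function(transcripts, te, min_fraction = 0) {
  spans <- transcript_spans(transcripts)
  fams <- sort(unique(te$superfamily))
  res <- purrr::map(seq_len(nrow(spans)), function(i) {
    sp <- spans[i, ]
    tex <- transcripts |>
      filter(.data$transcript_id == sp$transcript_id) |>
      select("chrom", "start", "end")
    tloc <- filter(te, .data$chrom == sp$chrom,
                   .data$start < sp$end, .data$end > sp$start)
    if (nrow(tloc) == 0) {
      return(list(masked = 0L, by_fam = setNames(numeric(0), character(0))))
    }
    masked <- interval_overlap_bp(tex, select(tloc, "chrom", "start", "end"))
    raw <- vapply(split(tloc, tloc$superfamily), function(tf) {
      interval_overlap_bp(tex, select(tf, "chrom", "start", "end"))
    }, 1L)
    raw <- raw[raw > 0]
    if (sum(raw) > masked && length(raw) > 1) {
      # families overlap each other within this transcript: assign shared
      # bases once, per base, to the family with the larger local overlap
      prio <- unlist(lapply(sort(unique(raw), decreasing = TRUE),
                            function(v) sort(names(raw)[raw == v])))
      # genomic positions of the transcript's exonic bases
      exon_pos <- unlist(purrr::map2(tex$start, tex$end - 1L, seq.int))
      owner <- rep(NA_character_, length(exon_pos))
      for (fam in prio) {
        tf <- filter(tloc, .data$superfamily == fam)
        cov <- rep(FALSE, length(exon_pos))
        for (j in seq_len(nrow(tf))) {
          cov <- cov | (exon_pos >= tf$start[j] & exon_pos < tf$end[j])
        }
        free <- cov & is.na(owner)
        owner[free] <- fam
      }
      by_fam <- table(owner[!is.na(owner)])
      by_fam <- setNames(as.numeric(by_fam), names(by_fam))
    } else {
      by_fam <- setNames(as.numeric(raw), names(raw))
    }
    list(masked = masked, by_fam = by_fam)
  })
  masked_bp <- vapply(res, function(r) as.integer(r$masked), 1L)
  by_fam <- purrr::map(res, "by_fam")
  assigned <- vapply(by_fam, function(b) {
    if (!length(b)) return(NA_character_)
    mx <- max(b)
    sort(names(b)[b == mx])[[1]] # tie -> lexicographic
  }, "")
  out <- tibble(
    transcript_id = spans$transcript_id,
    length = spans$length,
    masked_bp = masked_bp,
    masked_fraction = masked_bp / spans$length,
    assigned_superfamily = assigned,
    bp_by_superfamily = by_fam
  )
  out$is_te_lncRNA <- out$masked_fraction > min_fraction
  out
}

#' Re-call TE-lncRNAs at a different overlap threshold
#'
#' @param result Tibble from [masked_fraction()].
#' @param min_fraction Masked fraction strictly above which a transcript is
#'   a TE-lncRNA.
#' @return `result` with `is_te_lncRNA` (and `assigned_superfamily`)
#'   refreshed.
#' @export
call_te_lncRNA <- function(result, min_fraction = 0) {
  result$is_te_lncRNA <- result$masked_fraction > min_fraction
  result$assigned_superfamily <- vapply(result$bp_by_superfamily,
    function(b) {
      if (!length(b)) return(NA_character_)
      sort(names(b)[b == max(b)])[[1]]
    }, "")
  result
}

# internal: superfamily label -> grouped class
.te_group <- function(fam) {
  dplyr::case_when(
    grepl("^(LTR|LINE|SINE)", fam) ~ "retroelements",
    grepl("^DNA", fam) ~ "DNA transposons",
    grepl("Helitron", fam, ignore.case = TRUE) ~ "helitrons",
    TRUE ~ "unclassified"
  )
}

#' Superfamily composition of TE-lncRNA bases vs genomic TE bases
#'
#' For each TE superfamily: the number of TE-lncRNAs assigned to it, the
#' masked bases attributable to it across TE-lncRNAs, its share of all
#' TE-lncRNA masked bases, its share of genomic TE bases (union of annotated
#' intervals per family), and the fold ratio of the two shares. A family
#' absent from the genome but present among TE-lncRNAs is reported with an
#' infinite fold and flagged.
#'
#' @param result Tibble from [masked_fraction()] (TE-lncRNAs are rows with
#'   `is_te_lncRNA`).
#' @param te TE annotation tibble.
#' @return A tibble of class `te_enrichment`, one row per superfamily:
#'   `superfamily`, `te_group`, `te_lnc_count`, `te_lnc_bp`,
#'   `pct_of_te_lnc_bp`, `genomic_bp`, `pct_of_genomic_te_bp`,
#'   `fold_ratio`, `fold_infinite`.
#' @export
superfamily_enrichment <- function(result, te) {
  telnc <- filter(result, .data$is_te_lncRNA)
  .check(nrow(telnc) > 0, "superfamily_enrichment(): no TE-lncRNAs")
  lnc_bp <- unlist(telnc$bp_by_superfamily)
  lnc_bp <- tapply(lnc_bp, names(lnc_bp), sum)
  counts <- table(telnc$assigned_superfamily)
  gen_bp <- vapply(split(te, te$superfamily), function(tf) {
    sum(vapply(split(tf, tf$chrom), .union_bp, 1))
  }, 1)
  fams <- sort(union(names(lnc_bp), names(gen_bp)))
  out <- tibble(
    superfamily = fams,
    te_group = .te_group(fams),
    te_lnc_count = as.integer(ifelse(fams %in% names(counts),
                                     counts[fams], 0L)),
    te_lnc_bp = as.numeric(ifelse(fams %in% names(lnc_bp),
                                  lnc_bp[fams], 0)),
    genomic_bp = as.numeric(ifelse(fams %in% names(gen_bp),
                                   gen_bp[fams], 0))
  )
  out$pct_of_te_lnc_bp <- 100 * out$te_lnc_bp / sum(out$te_lnc_bp)
  out$pct_of_genomic_te_bp <- 100 * out$genomic_bp / sum(out$genomic_bp)
  out$fold_ratio <- out$pct_of_te_lnc_bp / out$pct_of_genomic_te_bp
  out$fold_infinite <- out$te_lnc_bp > 0 & out$genomic_bp == 0
  structure(out, class = c("te_enrichment", class(out)))
}

#' Aggregate a superfamily enrichment table to grouped TE classes
#'
#' Sums counts and base shares over retroelements, DNA transposons,
#' helitrons and unclassified elements, recomputing fold ratios per group.
#'
#' @param enrichment A [superfamily_enrichment()] table (or any tibble with
#'   its columns).
#' @return A tibble with one row per TE group.
#' @export
enrichment_groups <- function(enrichment) {
  enrichment |>
    group_by(te_group = .data$te_group) |>
    summarise(te_lnc_count = sum(.data$te_lnc_count),
              te_lnc_bp = sum(.data$te_lnc_bp),
              genomic_bp = sum(.data$genomic_bp),
              pct_of_te_lnc_bp = sum(.data$pct_of_te_lnc_bp),
              pct_of_genomic_te_bp = sum(.data$pct_of_genomic_te_bp),
              .groups = "drop") |>
    mutate(fold_ratio = .data$pct_of_te_lnc_bp /
             .data$pct_of_genomic_te_bp)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Without continuity correction, df = 1, upper-tail p-value.
#'
#' @param table 2x2 matrix of nonnegative counts with positive margins.
#' @return Tibble with `statistic` and `p_value`.
#' @export
chisq_2x2 <- function(table) {
  .check(is.matrix(table) && all(dim(table) == 2) && all(table >= 0),
         "chisq_2x2(): need a 2x2 matrix of nonnegative counts")
  .check(all(rowSums(table) > 0) && all(colSums(table) > 0),
         "chisq_2x2(): zero margin")
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  tibble(statistic = unname(ct$statistic), p_value = unname(ct$p.value))
}

#' Histogram of TE masked fractions
#'
#' Bins the masked fractions of TE-lncRNAs into right-closed bins of the
#' given width; the count of transcripts masked over at least 90% of their
#' length is reported separately as attribute `n_ge90` (and the bins sum to
#' the number of TE-lncRNAs).
#'
#' @param result Tibble from [masked_fraction()].
#' @param bin_width Bin width on the fraction scale.
#' @return Tibble with `bin_low`, `bin_high`, `count`; attribute `n_ge90`.
#' @export
masked_fraction_histogram <- function(result, bin_width = 0.1) {
  fr <- result$masked_fraction[result$is_te_lncRNA]
  breaks <- seq(0, 1, by = bin_width)
  cuts <- cut(fr, breaks = breaks, right = TRUE, include.lowest = FALSE)
  counts <- as.integer(table(cuts))
  out <- tibble(bin_low = head(breaks, -1), bin_high = breaks[-1],
                count = counts)
  attr(out, "n_ge90") <- sum(fr >= 0.9)
  out
}
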