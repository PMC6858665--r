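#' Nearest gene for each lncRNA locus
#'
#' Gap distance between genomic spans (0 when overlapping or book-ended),
#' minimized over all genes on the chromosome; equidistant flanks resolve
#' to the upstream gene and are flagged. Sides are genomic: a gene ending
#' at or before the lncRNA start is `upstream` (on the plus strand;
#' reversed for minus-strand lncRNAs), one starting at or after its end is
#' `downstream`, and distance-0 genes are labeled by which side of the
#' lncRNA start they begin on.
#'
#' @param loci Tibble of lncRNA spans: `transcript_id`, `chrom`, `strand`,
#'   `start`, `end` (e.g. from [transcript_spans()]).
#' @param ann A [gene_annotation()].
#' @return Tibble: `transcript_id`, `gene_id`, `distance`, `side`,
#'   `tie_flag`. Loci on gene-free chromosomes are absent (with a warning).
#' @export
nearest_gene <- function(loci, ann) {
  genes <- ann$genes
  out <- purrr::map(seq_len(nrow(loci)), function(i) {
    l <- loci[i, ]
    g <- filter(genes, .data$chrom == l$chrom)
    if (nrow(g) == 0) return(NULL)
    d <- pmax(g$start - l$end, l$start - g$end, 0)
    dmin <- min(d)
    cand <- g[d == dmin, , drop = FALSE]
    before <- cand$end <= l$start | (dmin == 0 & cand$start <= l$start)
    is_upstream <- if (identical(l$strand, "-")) !before else before
    tie <- nrow(cand) > 1 && length(unique(is_upstream)) > 1
    pick <- if (any(is_upstream)) which(is_upstream)[1] else 1L
    tibble(transcript_id = l$transcript_id, gene_id = cand$gene_id[pick],
           distance = as.integer(dmin),
           side = if (is_upstream[pick]) "upstream" else "downstream",
           tie_flag = tie)
  })
  dropped <- sum(vapply(out, is.null, TRUE))
  if (dropped > 0) {
    warn(paste0("nearest_gene(): ", dropped,
                " locus/loci on gene-free chromosomes were dropped"))
  }
  bind_rows(out)
}

#' Correlation of lncRNA and nearest-gene fold changes
#'
#' Pearson correlation over pooled (lncRNA log2FC, gene log2FC) pairs
#' across contrasts, with a t-distribution p-value (`df = n - 2`).
#'
#' @param pairs Tibble with columns `lnc_log2FC` and `gene_log2FC` (one row
#'   per lncRNA-gene-contrast combination); non-finite rows are dropped.
#' @return List with `r`, `p_value`, `n`, and the paired tibble used.
#' @export
cis_correlation <- function(pairs) {
  ok <- is.finite(pairs$lnc_log2FC) & is.finite(pairs$gene_log2FC)
  pairs <- pairs[ok, , drop = FALSE]
  .check(nrow(pairs) >= 3, "cis_correlation(): need >= 3 finite pairs")
  ct <- stats::cor.test(pairs$lnc_log2FC, pairs$gene_log2FC,
                        method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(pairs),
       pairs = as_tibble(pairs))
}

#' Per-class means of per-transcript maximum FPKM
#'
#' For each transcript the maximum FPKM across samples; per class the
#' arithmetic mean of those maxima, with the fold by which the `coding`
#' class exceeds each class when present.
#'
#' @param fpkm FPKM matrix (transcripts x samples).
#' @param classes Tibble with `transcript_id` and `class`.
#' @return Tibble: `class`, `n`, `mean_max_fpkm`, `coding_fold`.
#' @export
expression_summary <- function(fpkm, classes) {
  mx <- tibble(transcript_id = rownames(fpkm),
               max_fpkm = apply(fpkm, 1, max))
  out <- classes |>
    inner_join(mx, by = "transcript_id") |>
    group_by(.data$class) |>
    summarise(n = n(), mean_max_fpkm = mean(.data$max_fpkm),
              .groups = "drop")
  if ("coding" %in% out$class) {
    cod <- out$mean_max_fpkm[out$class == "coding"]
    out$coding_fold <- cod / out$mean_max_fpkm
  }
  out
}

#' Shannon entropy of expression across condition groups
#'
#' With group means `m_g`, `p_g = m_g / sum(m_g)` and
#' `H = -sum p_g log2 p_g` (0 log 0 = 0): high entropy means broad
#' expression, 0 means expression confined to one group. All-zero rows are
#' `NA`.
#'
#' @param group_means Matrix (transcripts x groups) of mean expression per
#'   group, or a numeric vector for one transcript.
#' @return Named numeric vector of entropies in bits.
#' @export
shannon_entropy <- function(group_means) {
  if (is.null(dim(group_means))) {
    group_means <- matrix(group_means, nrow = 1)
  }
  apply(group_means, 1, function(m) {
    s <- sum(m)
    if (s <= 0) return(NA_real_)
    p <- m / s
    p <- p[p > 0]
    -sum(p * log2(p))
  })
}

#' Group-mean expression per (condition, stage) group
#'
#' @param fpkm FPKM matrix (transcripts x samples).
#' @param samples Sample tibble with `sample_id`, `condition`, `stage`.
#' @param grouping Character vector of sample columns defining groups.
#' @return Matrix (transcripts x groups) of group means.
#' @export
expression_group_means <- function(fpkm, samples,
                                   grouping = c("condition", "stage")) {
  key <- do.call(paste, c(samples[grouping], sep = "_"))
  groups <- split(samples$sample_id, key)
  out <- vapply(groups, function(ids) {
    rowMeans(fpkm[, ids, drop = FALSE])
  }, numeric(nrow(fpkm)))
  if (nrow(fpkm) == 1) {
    out <- matrix(out, nrow = 1, dimnames = list(rownames(fpkm),
                                                 names(groups)))
  } else {
    rownames(out) <- rownames(fpkm)
  }
  out
}

#' Fisher exact term enrichment with Bonferroni control
#'
#' One-sided (enrichment) Fisher exact p-value per term from the 2x2
#' selected-by-in-term table, computed from the hypergeometric upper tail;
#' Bonferroni adjustment multiplies by the number of tested terms, capped
#' at 1. Terms with no selected member get p = 1.
#'
#' @param selected Character vector of selected gene ids (must lie in the
#'   universe).
#' @param term_map Tibble with columns `term` and `gene_id`.
#' @param universe Character vector of all gene ids.
#' @param alpha Experiment-wide significance level for the enriched flag.
#' @return Tibble: `term`, `n_term`, `n_overlap`, `p_value`,
#'   `p_bonferroni`, `enriched`.
#' @export
fisher_enrichment <- function(selected, term_map, universe, alpha = 0.05) {
  bad <- setdiff(selected, universe)
  if (length(bad)) {
    abort(paste0("fisher_enrichment(): selected genes outside universe: ",
                 paste(head(bad, 5), collapse = ", "),
                 if (length(bad) > 5) " ..." else ""))
  }
  terms <- split(term_map$gene_id, term_map$term)
  terms <- purrr::map(terms, intersect, y = universe)
  N <- length(unique(universe))
  k <- length(unique(selected))
  out <- purrr::imap(terms, function(genes, tm) {
    m <- length(unique(genes))
    q <- length(intersect(genes, selected))
    p <- if (q == 0) 1 else phyper(q - 1, m, N - m, k, lower.tail = FALSE)
    tibble(term = tm, n_term = m, n_overlap = q, p_value = p)
  }) |> bind_rows()
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  out$enriched <- out$p_bonferroni < alpha
  arrange(out, .data$p_value, .data$term)
}

#' Comparative delta-delta-Ct fold change
#'
#' `ddCt = (mean Ct_target,treated - mean Ct_ref,treated) -
#' (mean Ct_target,control - mean Ct_ref,control)`; fold change =
#' `2^(-ddCt)`. The standard error of ddCt is propagated from the four
#' cells' replicate variances and mapped to the fold scale by the delta
#' method.
#'
#' @param ct Tibble with columns `role` (`"target"`/`"reference"`), `arm`
#'   (`"treated"`/`"control"`), and `ct` (replicate Ct values; >= 1 per
#'   cell).
#' @return One-row tibble: `ddct`, `fold`, `se_ddct`, `se_fold`.
#' @export
ddct_fold_change <- function(ct) {
  cells <- expand.grid(role = c("target", "reference"),
                       arm = c("treated", "control"),
                       stringsAsFactors = FALSE)
  stats_tab <- purrr::pmap(cells, function(role, arm) {
    v <- ct$ct[ct$role == role & ct$arm == arm]
    .check(length(v) >= 1,
           paste0("ddct_fold_change(): missing Ct cell ", role, "/", arm))
    tibble(role = role, arm = arm, m = mean(v),
           vm = if (length(v) > 1) var(v) / length(v) else 0)
  }) |> bind_rows()
  g <- function(role, arm) stats_tab[stats_tab$role == role &
                                       stats_tab$arm == arm, ]
  ddct <- (g("target", "treated")$m - g("reference", "treated")$m) -
    (g("target", "control")$m - g("reference", "control")$m)
  se <- sqrt(sum(stats_tab$vm))
  fold <- 2^(-ddct)
  tibble(ddct = ddct, fold = fold, se_ddct = se,
         se_fold = fold * log(2) * se)
}
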