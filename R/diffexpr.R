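#' Median-of-ratios size factors
#'
#' For each sample, the median over transcripts (with nonzero counts in all
#' samples) of the ratio of that sample's count to the transcript's
#' geometric mean; factors are then rescaled to geometric mean 1. When no
#' transcript is nonzero everywhere, library-size ratios are used with a
#' warning.
#'
#' @param counts Counts tibble or matrix (transcripts x samples).
#' @return Named numeric vector of per-sample size factors.
#' @export
median_ratio_size_factors <- function(counts) {
  m <- .counts_matrix(counts)
  keep <- rowSums(m == 0) == 0
  if (!any(keep)) {
    warn(paste0("median_ratio_size_factors(): no transcript with nonzero ",
                "counts in all samples; falling back to library-size ",
                "ratios"))
    f <- colSums(m)
  } else {
    mm <- m[keep, , drop = FALSE]
    geo <- exp(rowMeans(log(mm)))
    f <- apply(mm / geo, 2, median)
  }
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(m))
}

#' Declare a stress-vs-control contrast
#'
#' @param name Contrast name, e.g. `"heat_V3"`.
#' @param treatment,control Character vectors of sample ids (disjoint, at
#'   least 2 replicates each).
#' @return A list of class `contrast_spec`.
#' @export
contrast_spec <- function(name, treatment, control) {
  .check(length(intersect(treatment, control)) == 0,
         "contrast_spec(): treatment and control must be disjoint")
  .check(length(treatment) >= 2 && length(control) >= 2,
         "contrast_spec(): need >= 2 replicates per arm")
  structure(list(name = name, treatment = treatment, control = control),
            class = "contrast_spec")
}

#' Negative-binomial Wald test for one contrast
#'
#' A shrinkage-free NB Wald test: per-transcript dispersion is estimated by
#' method of moments on size-factor-normalized counts pooled across the two
#' arms (within-arm residual variance; floored at 1e-8), the log2 fold
#' change comes from arm means with a pseudo-count of 0.5, and the Wald
#' statistic is the log2FC over a delta-method standard error with
#' per-sample NB variance `mu/s + alpha*mu^2`, referred two-sided to a t
#' distribution with `n1 + n0 - 2` degrees of freedom (the residual df of
#' the variance estimate, which keeps the test calibrated at the 2-3
#' replicates per arm typical of these designs; a normal reference is
#' anticonservative by the z-vs-t mismatch there). All-zero transcripts
#' get `log2FC = 0`, `p = 1`.
#'
#' @param counts Counts tibble or matrix.
#' @param spec A [contrast_spec()].
#' @param factors Size factors from [median_ratio_size_factors()];
#'   computed from the contrast's samples when `NULL`.
#' @return An object of class `lnc_contrast`: tibble with `transcript_id`,
#'   `base_mean`, `log2FC`, `se`, `stat`, `p_value` plus attributes `name`
#'   and `n` per arm.
#' @export
nb_wald_test <- function(counts, spec, factors = NULL) {
  m <- .counts_matrix(counts)
  .check(all(c(spec$treatment, spec$control) %in% colnames(m)),
         "nb_wald_test(): contrast samples missing from counts")
  m <- m[, c(spec$treatment, spec$control), drop = FALSE]
  if (is.null(factors)) factors <- median_ratio_size_factors(m)
  s <- factors[colnames(m)]
  q <- sweep(m, 2, s, "/")
  trt <- spec$treatment
  ctl <- spec$control
  n1 <- length(trt); n0 <- length(ctl)
  m1 <- rowMeans(q[, trt, drop = FALSE])
  m0 <- rowMeans(q[, ctl, drop = FALSE])
  base_mean <- rowMeans(q)
  # method-of-moments dispersion from pooled within-arm residual variance
  ss <- rowSums((q[, trt, drop = FALSE] - m1)^2) +
    rowSums((q[, ctl, drop = FALSE] - m0)^2)
  v <- ss / (n1 + n0 - 2)
  mu_bar <- (m1 + m0) / 2
  alpha <- pmax((v - mu_bar) / mu_bar^2, 1e-8)
  alpha[!is.finite(alpha)] <- 1e-8
  lfc <- log2((m1 + 0.5) / (m0 + 0.5))
  # delta method: var(mean_g) = sum_j (mu_g / s_j + alpha mu_g^2) / n_g^2
  v1 <- (m1 * sum(1 / s[trt]) / n1^2) + alpha * m1^2 / n1
  v0 <- (m0 * sum(1 / s[ctl]) / n0^2) + alpha * m0^2 / n0
  ln2sq <- log(2)^2
  se <- sqrt(v1 / ((m1 + 0.5)^2 * ln2sq) + v0 / ((m0 + 0.5)^2 * ln2sq))
  stat <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * pt(-abs(stat), df = n1 + n0 - 2)
  zero <- rowSums(m) == 0
  lfc[zero] <- 0; stat[zero] <- 0; p[zero] <- 1; se[zero] <- NA_real_
  out <- tibble(transcript_id = rownames(m),
                base_mean = unname(base_mean), log2FC = unname(lfc),
                se = unname(se), stat = unname(stat),
                p_value = unname(p))
  structure(out, name = spec$name, n_treatment = n1, n_control = n0,
            class = c("lnc_contrast", class(out)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Monotone step-up FDR adjustment, capped at 1, order-preserving with the
#' input; `NA`/`NaN` p-values propagate and are excluded from the ranking.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
benjamini_hochberg <- function(p) {
  .check(all(is.na(p) | (p >= 0 & p <= 1)),
         "benjamini_hochberg(): p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Call differential expression
#'
#' `up` when `log2FC > lfc_min` and `padj < padj_max`; `down`
#' symmetrically; else `ns`. Adds BH-adjusted p-values when absent.
#'
#' @param result An [nb_wald_test()] result (or tibble with `log2FC`,
#'   `p_value`).
#' @param lfc_min Absolute log2 fold-change threshold (strict).
#' @param padj_max Adjusted-p threshold (strict).
#' @return `result` with `padj` and `call` columns.
#' @export
call_de <- function(result, lfc_min = 1.0, padj_max = 0.05) {
  if (!"padj" %in% names(result)) {
    result$padj <- benjamini_hochberg(result$p_value)
  }
  result$call <- dplyr::case_when(
    result$log2FC > lfc_min & result$padj < padj_max ~ "up",
    result$log2FC < -lfc_min & result$padj < padj_max ~ "down",
    TRUE ~ "ns"
  )
  result
}

#' Run a set of contrasts end to end
#'
#' @param counts Counts tibble or matrix.
#' @param specs List of [contrast_spec()] objects.
#' @param lfc_min,padj_max Passed to [call_de()].
#' @return Named list of called [nb_wald_test()] results.
#' @export
run_contrasts <- function(counts, specs, lfc_min = 1.0, padj_max = 0.05) {
  res <- purrr::map(specs, function(sp) {
    call_de(nb_wald_test(counts, sp), lfc_min = lfc_min,
            padj_max = padj_max)
  })
  setNames(res, vapply(specs, function(sp) sp$name, ""))
}

#' Summarize DE counts and cross-contrast sharing
#'
#' Per contrast and transcript class: up/down counts (a Table-3-shaped
#' summary); plus pairwise shared-DE counts between contrasts, per-contrast
#' exclusive counts, and the non-redundant union of DE transcripts.
#'
#' @param results Named list of called contrast results ([run_contrasts()]).
#' @param classes Tibble with `transcript_id` and `class` (e.g. `coding`,
#'   `lncRNA`, `TE_lncRNA`); when `NULL` all transcripts form one class.
#' @return A list with `summary` (contrast x class up/down tibble),
#'   `sharing` (pairwise shared counts), `exclusive` (per-contrast DE found
#'   nowhere else), and `n_union`.
#' @export
de_overlap_summary <- function(results, classes = NULL) {
  .check(length(results) >= 1, "de_overlap_summary(): no contrasts")
  de_sets <- purrr::map(results, function(r) {
    r$transcript_id[r$call != "ns"]
  })
  long <- purrr::imap(results, function(r, nm) {
    r <- filter(r, .data$call != "ns")
    r$contrast <- nm
    select(r, "contrast", "transcript_id", "call")
  }) |> bind_rows()
  if (is.null(classes)) {
    classes <- tibble(transcript_id = unique(long$transcript_id),
                      class = "all")
  }
  summary <- long |>
    left_join(classes, by = "transcript_id") |>
    group_by(.data$contrast, .data$class) |>
    summarise(up = sum(.data$call == "up"),
              down = sum(.data$call == "down"), .groups = "drop")
  nms <- names(de_sets)
  sharing <- NULL
  if (length(nms) >= 2) {
    pairs <- utils::combn(nms, 2)
    sharing <- tibble(
      contrast_a = pairs[1, ], contrast_b = pairs[2, ],
      shared = vapply(seq_len(ncol(pairs)), function(k) {
        length(intersect(de_sets[[pairs[1, k]]], de_sets[[pairs[2, k]]]))
      }, 1L)
    )
  }
  exclusive <- tibble(
    contrast = nms,
    n_de = unname(lengths(de_sets)),
    n_exclusive = vapply(nms, function(nm) {
      others <- unique(unlist(de_sets[setdiff(nms, nm)]))
      sum(!de_sets[[nm]] %in% others)
    }, 1L, USE.NAMES = FALSE)
  )
  list(summary = summary, sharing = sharing, exclusive = exclusive,
       n_union = length(unique(unlist(de_sets))))
}
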