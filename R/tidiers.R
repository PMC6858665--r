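#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_hline
#'   geom_vline geom_tile labs scale_fill_gradient2 theme_minimal
#' @export
ggplot2::autoplot

#' Tidy a contrast result
#'
#' @param x An [nb_wald_test()] result.
#' @param ... Unused.
#' @return The per-transcript result as a plain tibble.
#' @method tidy lnc_contrast
#' @export
tidy.lnc_contrast <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "lnc_contrast")
  out
}

#' One-row summary of a contrast result
#'
#' @param x An [nb_wald_test()] result (called or not; calls are added at
#'   default thresholds when absent).
#' @param ... Unused.
#' @return Tibble: `contrast`, `n_tested`, `n_up`, `n_down`.
#' @method glance lnc_contrast
#' @export
glance.lnc_contrast <- function(x, ...) {
  if (!"call" %in% names(x)) x <- call_de(x)
  tibble(contrast = attr(x, "name") %||% NA_character_,
         n_tested = nrow(x),
         n_up = sum(x$call == "up"), n_down = sum(x$call == "down"))
}

#' Tidy a discovery result
#'
#' @param x A [run_discovery()] result.
#' @param ... Unused.
#' @return The records tibble with rejection reasons flattened to a
#'   comma-separated string.
#' @method tidy lnc_discovery
#' @export
tidy.lnc_discovery <- function(x, ...) {
  x$records |>
    mutate(rejection_reasons = vapply(.data$rejection_reasons, paste, "",
                                      collapse = ","))
}

#' One-row summary of a discovery result
#'
#' @param x A [run_discovery()] result.
#' @param ... Unused.
#' @return Tibble with totals per filter outcome.
#' @method glance lnc_discovery
#' @export
glance.lnc_discovery <- function(x, ...) {
  r <- x$records
  tibble(n_transcripts = nrow(r), n_passed = sum(r$passed),
         n_polyA_minus = sum(r$passed & r$polyA_origin == "polyA_minus"),
         n_intergenic = sum(r$passed & r$class_code == "u"),
         n_intronic = sum(r$passed & r$class_code == "i"))
}

#' Tidy a co-expression network
#'
#' @param x A [build_network()] result.
#' @param ... Unused.
#' @return Tibble: `transcript_id`, `module`, `kim`, own-module `kme`.
#' @method tidy coexpr_network
#' @export
tidy.coexpr_network <- function(x, ...) {
  own_kme <- vapply(seq_along(x$modules), function(i) {
    m <- x$modules[i]
    if (m == "grey") return(NA_real_)
    x$kme[names(x$modules)[i], m]
  }, 1)
  tibble(transcript_id = names(x$modules), module = unname(x$modules),
         kim = unname(x$kim[names(x$modules)]), kme = own_kme)
}

#' One-row summary of a co-expression network
#'
#' @param x A [build_network()] result.
#' @param ... Unused.
#' @return Tibble: `n_transcripts`, `n_modules`, `n_grey`, `n_hubs`.
#' @method glance coexpr_network
#' @export
glance.coexpr_network <- function(x, ...) {
  tibble(n_transcripts = nrow(x$expr),
         n_modules = length(setdiff(unique(x$modules), "grey")),
         n_grey = sum(x$modules == "grey"),
         n_hubs = nrow(x$hubs))
}

#' Volcano plot of a contrast result
#'
#' @param object An [nb_wald_test()] result.
#' @param lfc_min,padj_max Thresholds drawn as guides (and used to call DE
#'   when calls are absent).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lnc_contrast
#' @export
autoplot.lnc_contrast <- function(object, lfc_min = 1, padj_max = 0.05,
                                  ...) {
  if (!"call" %in% names(object)) {
    object <- call_de(object, lfc_min, padj_max)
  }
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$log2FC, y = -log10(.data$padj),
                 colour = .data$call)) +
    geom_point(size = 0.8, alpha = 0.7) +
    geom_vline(xintercept = c(-lfc_min, lfc_min), linetype = 2) +
    geom_hline(yintercept = -log10(padj_max), linetype = 2) +
    labs(x = "log2 fold change", y = "-log10 adjusted p",
         title = attr(object, "name")) +
    theme_minimal()
}

#' Histogram of TE masked fractions
#'
#' @param result A [masked_fraction()] result.
#' @param bin_width Bin width on the fraction scale.
#' @return A ggplot object.
#' @export
plot_masked_fraction <- function(result, bin_width = 0.1) {
  h <- masked_fraction_histogram(result, bin_width)
  ggplot(h, aes(x = (.data$bin_low + .data$bin_high) / 2,
                y = .data$count)) +
    geom_col(width = bin_width * 0.9, fill = "steelblue") +
    labs(x = "fraction of lncRNA length masked by TEs",
         y = "lncRNAs") +
    theme_minimal()
}

#' Module-trait correlation heat map
#'
#' @param module_trait Tibble from [module_trait_correlation()] (or a
#'   `coexpr_network`, whose table is used).
#' @return A ggplot object.
#' @export
plot_module_trait <- function(module_trait) {
  if (inherits(module_trait, "coexpr_network")) {
    module_trait <- module_trait$module_trait
  }
  ggplot(module_trait, aes(x = .data$trait, y = .data$profile,
                           fill = .data$r)) +
    geom_tile() +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(x = "trait", y = "module", fill = "r") +
    theme_minimal()
}

#' Superfamily composition comparison plot
#'
#' @param object A [superfamily_enrichment()] table.
#' @param ... Unused.
#' @return A ggplot object comparing TE-lncRNA vs genomic base shares.
#' @method autoplot te_enrichment
#' @export
autoplot.te_enrichment <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            c("pct_of_te_lnc_bp", "pct_of_genomic_te_bp"),
                            names_to = "set", values_to = "pct")
  ggplot(df, aes(x = .data$superfamily, y = .data$pct,
                 fill = .data$set)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "% of bases") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
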