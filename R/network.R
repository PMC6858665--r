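#' Configuration for the co-expression network stage
#'
#' @param beta Soft-threshold power applied to absolute Pearson
#'   correlations (unsigned network).
#' @param prefilter_min_r2 Optional pairwise r-squared retention threshold:
#'   when not `NULL`, only transcripts with at least one partner at or
#'   above it are kept before building the network.
#' @param min_module_size Smallest cluster kept as a module; smaller
#'   clusters become `"grey"`.
#' @param cut_height Flat cut height on the 1 - TOM dissimilarity tree.
#'   Unrelated transcripts sit near 1 on this scale (their adjacency
#'   |r|^beta is essentially 0), so the default cuts just below that.
#' @param hub_kim_top_frac Intramodular-connectivity rank fraction for hub
#'   candidacy.
#' @param hub_kme_min Module-membership (kME) floor for hubs (strict).
#' @param hub_gs_p_max Gene-significance p ceiling for hubs (strict),
#'   against the module's best-correlated trait.
#' @return A list of class `network_config`.
#' @export
network_config <- function(beta = 12, prefilter_min_r2 = NULL,
                           min_module_size = 20L, cut_height = 0.99,
                           hub_kim_top_frac = 0.10, hub_kme_min = 0.9,
                           hub_gs_p_max = 0.01) {
  .check(beta >= 1, "network_config(): beta must be >= 1")
  .check(hub_kim_top_frac > 0 && hub_kim_top_frac <= 1,
         "network_config(): hub_kim_top_frac must be in (0, 1]")
  structure(list(beta = beta, prefilter_min_r2 = prefilter_min_r2,
                 min_module_size = as.integer(min_module_size),
                 cut_height = cut_height,
                 hub_kim_top_frac = hub_kim_top_frac,
                 hub_kme_min = hub_kme_min, hub_gs_p_max = hub_gs_p_max),
            class = "network_config")
}

#' Variance-stabilizing-style transform of counts
#'
#' `log2(count / size_factor + 1)`, a simple stabilization of normalized
#' counts adequate for correlation-based network inference at these scales.
#'
#' @param counts Counts tibble or matrix.
#' @param factors Size factors; computed when `NULL`.
#' @return Matrix of transformed values; rows with zero variance carry
#'   attribute `zero_variance` (their ids) and should be excluded from
#'   correlation.
#' @export
vst_transform <- function(counts, factors = NULL) {
  m <- .counts_matrix(counts)
  if (is.null(factors)) factors <- median_ratio_size_factors(m)
  x <- log2(sweep(m, 2, factors[colnames(m)], "/") + 1)
  zv <- rownames(x)[apply(x, 1, function(r) var(r) == 0)]
  attr(x, "zero_variance") <- zv
  x
}

#' Unsigned soft-thresholded adjacency
#'
#' `a_ij = |pearson(x_i, x_j)|^beta`, diagonal 1.
#'
#' @param expr Expression matrix (transcripts x samples), at least 3
#'   samples, zero-variance rows removed.
#' @param beta Soft-threshold power (>= 1).
#' @return Symmetric adjacency matrix with entries in `[0, 1]`.
#' @export
soft_adjacency <- function(expr, beta = 12) {
  .check(beta >= 1, "soft_adjacency(): beta must be >= 1")
  .check(ncol(expr) >= 3, "soft_adjacency(): need >= 3 samples")
  a <- abs(cor(t(expr)))^beta
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_u a_iu` (sums over `u != i, j`), `TOM_ii = 1`: the standard
#' unsigned formula measuring shared network neighborhoods.
#'
#' @param adjacency Adjacency matrix from [soft_adjacency()].
#' @return TOM similarity matrix, symmetric, diagonal 1.
#' @export
tom_similarity <- function(adjacency) {
  a <- adjacency
  diag(a) <- 0
  k <- rowSums(a)
  shared <- a %*% a # sum_u a_iu a_uj, includes u = i, j with zero diag
  kmin <- outer(k, k, pmin)
  tom <- (shared + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect modules from a TOM matrix
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, a flat cut at
#' `cut_height`, and relabeling of clusters below `min_module_size` as
#' `"grey"`. Modules are named `"M1"`, `"M2"`, ... in order of decreasing
#' size (ties broken by the smallest member index) so labels are
#' deterministic and invariant to input order.
#'
#' @param tom TOM similarity matrix.
#' @param config A [network_config()].
#' @return Named character vector: module label per transcript.
#' @export
detect_modules <- function(tom, config = network_config()) {
  d <- as.dist(1 - tom)
  hc <- hclust(d, method = "average")
  raw <- cutree(hc, h = config$cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= config$min_module_size]
  labels <- rep("grey", length(raw))
  if (length(keep)) {
    first_member <- vapply(keep, function(k) min(which(raw == k)), 1L)
    ord <- keep[order(-as.integer(sizes[keep]), first_member)]
    for (i in seq_along(ord)) {
      labels[raw == ord[i]] <- paste0("M", i)
    }
  } else {
    warn("detect_modules(): no cluster reached min_module_size; all grey")
  }
  setNames(labels, rownames(tom))
}

#' Module eigengenes
#'
#' First principal component of the row-standardized member expression
#' across samples, unit-normalized, sign chosen so the eigengene correlates
#' non-negatively with the members' mean profile. Single-member modules
#' return the standardized member profile.
#'
#' @param expr Expression matrix (transcripts x samples).
#' @param modules Module labels from [detect_modules()]; `"grey"` is
#'   skipped.
#' @return Matrix (modules x samples) of eigengenes.
#' @export
module_eigengenes <- function(expr, modules) {
  mods <- setdiff(sort(unique(modules)), "grey")
  .check(length(mods) > 0, "module_eigengenes(): no non-grey modules")
  eg <- vapply(mods, function(m) {
    x <- expr[names(modules)[modules == m], , drop = FALSE]
    xs <- t(scale(t(x)))
    if (nrow(xs) == 1) return(as.numeric(xs))
    sv <- svd(xs, nu = 0, nv = 1)
    e <- sv$v[, 1]
    if (cor(e, colMeans(xs)) < 0) e <- -e
    e
  }, numeric(ncol(expr)))
  out <- t(eg)
  colnames(out) <- colnames(expr)
  out
}

#' Module-trait (and gene-trait) correlations
#'
#' Pearson correlation of each profile (eigengene or transcript) with each
#' per-sample trait indicator; two-sided p from the t transform with
#' `df = n - 2`. Constant traits or profiles yield `NA` rows.
#'
#' @param profiles Matrix (profiles x samples): eigengenes for module-trait
#'   results, expression rows for per-transcript gene significance.
#' @param traits Matrix or tibble (samples x traits) of indicators.
#' @return Tidy tibble: `profile`, `trait`, `r`, `r2`, `p_value`.
#' @export
module_trait_correlation <- function(profiles, traits) {
  tm <- as.matrix(traits)
  .check(ncol(profiles) == nrow(tm),
         "module_trait_correlation(): sample dimensions disagree")
  n <- ncol(profiles)
  # constant traits/profiles yield NA correlations (absent), by design
  r <- suppressWarnings(cor(t(profiles), tm))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  out <- as_tibble(as.table(r), .name_repair = "minimal")
  names(out) <- c("profile", "trait", "r")
  out$r2 <- out$r^2
  out$p_value <- as.vector(p)
  out
}

#' Module membership (kME) and intramodular connectivity (kIM)
#'
#' `kME(t, M)` is the Pearson correlation of transcript `t` with module
#' `M`'s eigengene; `kIM(t)` is the sum of adjacencies from `t` to the
#' other members of its own module (`NA` for grey transcripts).
#'
#' @param expr Expression matrix (transcripts x samples).
#' @param adjacency Adjacency matrix.
#' @param modules Module labels.
#' @param eigengenes Matrix from [module_eigengenes()].
#' @return List with `kme` (transcripts x modules matrix) and `kim` (named
#'   vector).
#' @export
kme_kim <- function(expr, adjacency, modules, eigengenes) {
  kme <- suppressWarnings(cor(t(expr), t(eigengenes)))
  kim <- setNames(rep(NA_real_, nrow(expr)), rownames(expr))
  for (m in setdiff(unique(modules), "grey")) {
    ids <- names(modules)[modules == m]
    am <- adjacency[ids, ids, drop = FALSE]
    diag(am) <- 0
    kim[ids] <- rowSums(am)
  }
  list(kme = kme, kim = kim)
}

#' Identify hub transcripts
#'
#' A module member is a hub iff its intramodular connectivity ranks within
#' the top `hub_kim_top_frac` of the module (rank <= ceiling(frac x size)),
#' its membership for its own module exceeds `hub_kme_min`, and its
#' gene-significance p against the module's best-correlated trait is below
#' `hub_gs_p_max`.
#'
#' @param modules Module labels.
#' @param kme,kim From [kme_kim()].
#' @param gene_sig Gene-trait tibble from [module_trait_correlation()] on
#'   expression rows.
#' @param module_trait Module-trait tibble from
#'   [module_trait_correlation()] on eigengenes.
#' @param config A [network_config()].
#' @param classes Optional tibble `transcript_id`, `class` (and optionally
#'   `tf_family`) to annotate hubs.
#' @return Tibble of hubs: `transcript_id`, `module`, `kim`, `kim_rank`,
#'   `kme`, `best_trait`, `gs_r`, `gs_p`, plus class columns when given.
#' @export
find_hubs <- function(modules, kme, kim, gene_sig, module_trait,
                      config = network_config(), classes = NULL) {
  best <- module_trait |>
    filter(!is.na(.data$r)) |>
    group_by(.data$profile) |>
    arrange(desc(abs(.data$r)), .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    select(module = "profile", best_trait = "trait")
  hubs <- purrr::map(setdiff(sort(unique(modules)), "grey"), function(m) {
    ids <- names(modules)[modules == m]
    bt <- best$best_trait[best$module == m]
    if (!length(bt)) return(NULL)
    km <- kim[ids]
    rk <- rank(-km, ties.method = "min")
    gs <- filter(gene_sig, .data$profile %in% ids, .data$trait == bt)
    tibble(
      transcript_id = ids, module = m, kim = unname(km),
      kim_rank = as.integer(rk), kme = unname(kme[ids, m]),
      best_trait = bt,
      gs_r = gs$r[match(ids, gs$profile)],
      gs_p = gs$p_value[match(ids, gs$profile)],
      module_size = length(ids)
    ) |>
      filter(.data$kim_rank <=
               ceiling(config$hub_kim_top_frac * length(ids)),
             .data$kme > config$hub_kme_min,
             .data$gs_p < config$hub_gs_p_max)
  }) |> bind_rows()
  if (!is.null(classes) && nrow(hubs)) {
    hubs <- left_join(hubs, classes, by = "transcript_id")
  }
  hubs
}

#' Build the full co-expression network
#'
#' Convenience wrapper running transform, optional r-squared prefilter,
#' adjacency, TOM, module detection, eigengenes, module-trait correlation,
#' kME/kIM and hub detection.
#'
#' @param counts Counts tibble or matrix (transcripts x samples).
#' @param traits Samples x traits indicator matrix/tibble.
#' @param config A [network_config()].
#' @param classes Optional class annotation for hubs (see [find_hubs()]).
#' @return An object of class `coexpr_network`: list with `expr`,
#'   `adjacency`, `tom`, `modules`, `eigengenes`, `module_trait`,
#'   `gene_significance`, `kme`, `kim`, `hubs`, `config`.
#' @export
build_network <- function(counts, traits, config = network_config(),
                          classes = NULL) {
  x <- vst_transform(counts)
  zv <- attr(x, "zero_variance")
  x <- x[setdiff(rownames(x), zv), , drop = FALSE]
  if (!is.null(config$prefilter_min_r2)) {
    r2 <- cor(t(x))^2
    diag(r2) <- 0
    keep <- apply(r2, 1, max) >= config$prefilter_min_r2
    x <- x[keep, , drop = FALSE]
  }
  adj <- soft_adjacency(x, config$beta)
  tom <- tom_similarity(adj)
  modules <- detect_modules(tom, config)
  gs <- module_trait_correlation(x, traits)
  if (all(modules == "grey")) {
    eg <- NULL
    mt <- tibble(profile = character(), trait = character(),
                 r = numeric(), r2 = numeric(), p_value = numeric())
    kk <- list(kme = NULL,
               kim = setNames(rep(NA_real_, nrow(x)), rownames(x)))
    hubs <- tibble(transcript_id = character(), module = character(),
                   kim = numeric(), kim_rank = integer(),
                   kme = numeric(), best_trait = character(),
                   gs_r = numeric(), gs_p = numeric(),
                   module_size = integer())
  } else {
    eg <- module_eigengenes(x, modules)
    mt <- module_trait_correlation(eg, traits)
    kk <- kme_kim(x, adj, modules, eg)
    hubs <- find_hubs(modules, kk$kme, kk$kim, gs, mt, config, classes)
  }
  structure(list(expr = x, adjacency = adj, tom = tom, modules = modules,
                 eigengenes = eg, module_trait = mt,
                 gene_significance = gs, kme = kk$kme, kim = kk$kim,
                 hubs = hubs, config = config),
            class = "coexpr_network")
}

#' @export
print.coexpr_network <- function(x, ...) {
  nmod <- length(setdiff(unique(x$modules), "grey"))
  cat("<coexpr_network> ", nrow(x$expr), " transcripts, ", nmod,
      " modules, ", nrow(x$hubs), " hubs\n", sep = "")
  invisible(x)
}

#' Export an edge list above a TOM threshold
#'
#' @param network A [build_network()] result.
#' @param min_tom Minimum TOM weight for an edge.
#' @return Tibble `node1`, `node2`, `weight`, upper-triangle edges only.
#' @export
network_edges <- function(network, min_tom = 0.1) {
  tom <- network$tom
  idx <- which(upper.tri(tom) & tom >= min_tom, arr.ind = TRUE)
  tibble(node1 = rownames(tom)[idx[, 1]], node2 = colnames(tom)[idx[, 2]],
         weight = tom[idx])
}
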