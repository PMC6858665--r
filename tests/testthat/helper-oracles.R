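# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately avoid the implementation's code paths.

# per-base set of covered positions for an interval tibble
bf_covered <- function(x) {
  if (nrow(x) == 0) return(integer())
  unique(unlist(Map(function(s, e) seq.int(s, e - 1L), x$start, x$end)))
}

# random interval tibble on one chromosome
rand_intervals <- function(n, max_pos = 1000L, chrom = "chr1") {
  s <- sample.int(max_pos, n, replace = TRUE) - 1L
  w <- sample.int(50L, n, replace = TRUE)
  tibble::tibble(chrom = chrom, start = s, end = s + w)
}

# ORF oracle via translation: leftmost-longest M...* runs per frame
bf_orf <- function(seq, min_aa = 30L) {
  n <- nchar(seq)
  best <- 0L
  count <- 0L
  for (f in 0:2) {
    len <- ((n - f) %/% 3L) * 3L
    if (len < 6L) next
    sub <- substr(seq, f + 1L, f + len)
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(sub), if.fuzzy.codon = "X",
      no.init.codon = TRUE))
    m <- gregexpr("M[^*]*\\*", aa)[[1]]
    if (m[1] == -1L) next
    lens <- attr(m, "match.length") - 1L
    count <- count + sum(lens >= min_aa)
    best <- max(best, max(lens))
  }
  list(orf_count = count, longest_orf_aa = best)
}

# Benjamini-Hochberg from the definition: min over k >= rank of p(k)*n/k
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  sorted <- p[o] * n / seq_len(n)
  adj_sorted <- rev(cummin(rev(sorted)))
  adj[o] <- pmin(1, adj_sorted)
  adj
}

# TOM from the definition by triple loop
bf_tom <- function(a) {
  n <- nrow(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { out[i, j] <- 1; next }
      s <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) s <- s + a[i, u] * a[u, j]
      }
      ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
      out[i, j] <- (s + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  out
}

# one-sided Fisher p by enumerating the hypergeometric tail with choose()
bf_fisher_p <- function(q, m, N, k) {
  if (q == 0) return(1)
  xs <- q:min(m, k)
  sum(choose(m, xs) * choose(N - m, k - xs)) / choose(N, k)
}

# random counts matrix with optional planted fold change in the first arm
sim_counts_matrix <- function(n, n1, n0, mu_meanlog = log(100),
                              mu_sdlog = 1, alpha = 0.1, lfc = 0,
                              mu_fixed = NULL) {
  mu <- if (is.null(mu_fixed)) rlnorm(n, mu_meanlog, mu_sdlog) else
    rep(mu_fixed, n)
  trt <- matrix(rnbinom(n * n1, mu = rep(mu * 2^lfc, n1),
                        size = 1 / alpha), n, n1)
  ctl <- matrix(rnbinom(n * n0, mu = rep(mu, n0), size = 1 / alpha),
                n, n0)
  m <- cbind(trt, ctl)
  rownames(m) <- paste0("t", seq_len(n))
  colnames(m) <- c(paste0("T", seq_len(n1)), paste0("C", seq_len(n0)))
  m
}

null_contrast <- function(n1 = 3, n0 = 3) {
  contrast_spec("test", paste0("T", seq_len(n1)), paste0("C", seq_len(n0)))
}

# small deterministic gene annotation: genes with 2-3 exons on chr1
toy_annotation <- function() {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB"), chrom = "chr1", strand = c("+", "-"),
    start = c(1000L, 9500L), end = c(2000L, 10500L))
  exons <- tibble::tibble(
    gene_id = c("gA", "gA", "gB"), chrom = "chr1",
    start = c(1000L, 1700L, 9500L), end = c(1300L, 2000L, 10500L))
  gene_annotation(genes, exons)
}

# single-exon transcript tibble helper
one_exon_tx <- function(id, start, end, chrom = "chr1", strand = "+") {
  tibble::tibble(transcript_id = id, gene_id = id, chrom = chrom,
                 strand = strand, start = as.integer(start),
                 end = as.integer(end))
}

# shared small simulated dataset (cached per test run)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 301, genome_length = 6e5, n_genes = 60,
                        n_lncRNA = 60, n_modules = 2, module_size = 15)
      cache <<- simulate_dataset(cfg)
    }
    cache
  }
})
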