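#' Configuration for the synthetic dataset generator
#'
#' Defines the study conditions the generator emulates: a single toy
#' chromosome carrying protein-coding genes and non-overlapping TE
#' intervals whose superfamily composition mirrors a maize-like genome
#' (Gypsy ~0.60, Copia ~0.32 of TE bases, DNA transposons ~0.06), lncRNAs
#' planted intergenic / intronic / TE-derived, a polyA+/total-RNA sample
#' design over stress conditions and seedling stages, negative-binomial
#' counts with planted differential expression, trait-driven co-expression
#' modules with designated hub transcripts, and nearest-gene effect sharing
#' for cis-correlation.
#'
#' @param seed Integer seed fixing all randomness.
#' @param genome_length Chromosome length (bp).
#' @param n_genes Number of protein-coding genes.
#' @param n_lncRNA Number of planted lncRNAs.
#' @param frac_te_derived Fraction of lncRNAs copied from TE intervals.
#' @param frac_intronic Fraction of lncRNAs placed fully inside introns.
#' @param frac_total_rna_only Fraction of lncRNAs detectable only in
#'   total-RNA samples (zero counts in polyA+ libraries).
#' @param te_genome_fraction Fraction of the genome covered by TEs.
#' @param te_superfamily_weights Named proportions of TE bases per
#'   superfamily (sum to at most 1).
#' @param lnc_te_family_bias Optional named multipliers on the probability
#'   that a TE-derived lncRNA originates from a family (planted
#'   superfamily enrichment); `NULL` means proportional to family bases.
#' @param stages,stress_conditions Sample design factors.
#' @param n_samples_per_group PolyA+ replicates per (condition, stage).
#' @param n_total_rna_per_stage Total-RNA control replicates per stage.
#' @param mean_fpkm_coding Median base FPKM of coding transcripts.
#' @param lnc_fpkm_ratio,te_lnc_fpkm_ratio Base-FPKM multipliers for
#'   lncRNAs / TE-lncRNAs relative to coding.
#' @param fpkm_sdlog Log-normal spread of base FPKM.
#' @param library_size_range Range of per-sample mapped fragments.
#' @param de_fraction Fraction of transcripts with planted differential
#'   expression.
#' @param de_log2fc Planted absolute log2 fold change.
#' @param de_share_prob Probability a planted DE effect is shared with a
#'   second contrast.
#' @param nb_dispersion NB dispersion alpha (variance mu + alpha mu^2).
#' @param n_modules,module_size,module_cor Planted co-expression modules:
#'   count, members each, and target within-module correlation.
#' @param module_sd_log2 Log2-scale standard deviation of the module
#'   signal.
#' @param module_trait_cor Correlation of each module's latent factor with
#'   its assigned (condition, stage) indicator.
#' @param cis_effect_r Target population correlation between planted
#'   lncRNA log2FCs and their nearest genes' log2FCs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome_length = 2e6, n_genes = 200L,
                       n_lncRNA = 150L, frac_te_derived = 0.65,
                       frac_intronic = 0.05, frac_total_rna_only = 0.4,
                       te_genome_fraction = 0.45,
                       te_superfamily_weights = c(
                         "LTR/Gypsy" = 0.596, "LTR/Copia" = 0.324,
                         "DNA/CMC-EnSpm" = 0.020, "DNA/hAT-Ac" = 0.015,
                         "DNA/MULE-MuDR" = 0.013,
                         "DNA/PIF-Harbinger" = 0.012,
                         "RC/Helitron" = 0.012, "LINE/L1" = 0.006,
                         "SINE" = 0.002),
                       lnc_te_family_bias = NULL,
                       stages = c("V3", "V4", "V6"),
                       stress_conditions = c("heat", "cold", "drought",
                                             "salt"),
                       n_samples_per_group = 2L,
                       n_total_rna_per_stage = 2L,
                       mean_fpkm_coding = 8, lnc_fpkm_ratio = 0.25,
                       te_lnc_fpkm_ratio = 1 / 6, fpkm_sdlog = 0.6,
                       library_size_range = c(4.5e6, 5.5e6),
                       de_fraction = 0.15, de_log2fc = 2,
                       de_share_prob = 0.3, nb_dispersion = 0.1,
                       n_modules = 3L, module_size = 30L,
                       module_cor = 0.9, module_sd_log2 = 2.5,
                       module_trait_cor = 0.7, cis_effect_r = 0.5) {
  props <- c(frac_te_derived, frac_intronic, frac_total_rna_only,
             te_genome_fraction, de_fraction, module_cor, de_share_prob)
  .check(all(props >= 0 & props <= 1),
         "sim_config(): proportions must lie in [0, 1]")
  .check(sum(te_superfamily_weights) <= 1 + 1e-9,
         "sim_config(): te_superfamily_weights must sum to <= 1")
  .check(seed == as.integer(seed) && abs(seed) < 2^31 - 10,
         "sim_config(): seed must be a 32-bit integer")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

# internal: complement of an interval set within [0, L)
.complement_intervals <- function(intervals, L, chrom) {
  if (nrow(intervals) == 0) {
    return(tibble(chrom = chrom, start = 0L, end = as.integer(L)))
  }
  m <- merge_intervals(mutate(intervals, chrom = chrom))
  starts <- c(0L, m$end)
  ends <- c(m$start, as.integer(L))
  tibble(chrom = chrom, start = starts, end = ends) |>
    filter(.data$start < .data$end)
}

# internal: pick a placement of width w inside free segments; returns start
# or NA. Segments weighted by capacity.
.place_in_free <- function(free, w) {
  cap <- free$end - free$start - w + 1
  ok <- which(cap > 0)
  if (!length(ok)) return(NA_integer_)
  seg <- if (length(ok) == 1) ok else
    sample(ok, 1, prob = cap[ok] / sum(cap[ok]))
  free$start[seg] + sample.int(cap[seg], 1) - 1L
}

# internal: overwrite genome characters at spliced exon positions with a
# transcript sequence (reverse-complemented for minus strand)
.write_spliced <- function(genome_chars, exons, strand, spliced) {
  gen_seq <- if (strand == "-") {
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(spliced)))
  } else spliced
  pos <- unlist(purrr::map2(exons$start, exons$end - 1L, seq.int)) + 1L
  genome_chars[pos] <- strsplit(gen_seq, "")[[1]]
  genome_chars
}

# internal: random coding-free codon soup of n codons (no stop codons)
.sense_codons <- function(n) {
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases,
                                paste0))
  sense <- setdiff(all_codons, c("TAA", "TAG", "TGA"))
  paste0(sample(sense, n, replace = TRUE), collapse = "")
}

# internal: lncRNA sequence admissibility: longest ORF under 100 aa and
# ORF coverage under 35% (confidently non-coding by the declared rule)
.lnc_seq_ok <- function(seq, max_orf_aa = 100L) {
  o <- find_orfs(seq)
  o$longest_orf_aa < max_orf_aa &&
    (3 * (o$longest_orf_aa + 1)) / nchar(seq) < 0.35
}

#' Simulate a toy genome with gene and TE annotations
#'
#' Places non-overlapping protein-coding genes (three exons each, with a
#' planted ORF of at least 150 aa written into the genome) and then packs
#' non-overlapping TE intervals into the intergenic space so that each
#' superfamily's total length matches its configured share of TE bases.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (tibble `id`, `seq`), `ann` (a
#'   [gene_annotation()]), `te` (TE tibble) and `gene_meta` (per-gene
#'   strand and planted ORF length).
#' @export
simulate_genome_and_annotations <- function(config = sim_config()) {
  withr::with_seed(config$seed, {
    L <- as.integer(config$genome_length)
    chrom <- "chr1"
    gchars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

    # --- genes ---
    ng <- config$n_genes
    exon_lens <- matrix(sample(200:600, 3 * ng, replace = TRUE), ncol = 3)
    intron_lens <- matrix(sample(100:300, 2 * ng, replace = TRUE),
                          ncol = 2)
    spans <- rowSums(exon_lens) + rowSums(intron_lens)
    # genes sit in islands separated by wide intergenic seas, so large
    # retrotransposons have contiguous room (gene-island architecture)
    n_islands <- max(1L, ceiling(ng / 5))
    island_of <- rep(seq_len(n_islands), each = 5L, length.out = ng)
    intra <- sample(200:600, ng, replace = TRUE)
    sea_budget <- L - sum(spans) - sum(intra) - (n_islands + 1) * 1000L
    if (sea_budget < 0) {
      abort("simulate_genome_and_annotations(): genes do not fit; increase genome_length")
    }
    seas <- 1000L + as.vector(stats::rmultinom(1, sea_budget,
                                               rep(1, n_islands + 1)))
    starts <- integer(ng)
    pos <- seas[1]
    for (i in seq_len(ng)) {
      pos <- pos + intra[i]
      starts[i] <- pos
      pos <- pos + spans[i]
      if (i == ng || island_of[i + 1] != island_of[i]) {
        pos <- pos + seas[island_of[i] + 1]
      }
    }
    gene_ids <- sprintf("g%03d", seq_len(ng))
    strands <- sample(c("+", "-"), ng, replace = TRUE)
    exon_rows <- purrr::map(seq_len(ng), function(i) {
      s <- starts[i]
      e1 <- c(s, s + exon_lens[i, 1] + intron_lens[i, 1])
      e1 <- c(e1, e1[2] + exon_lens[i, 2] + intron_lens[i, 2])
      tibble(gene_id = gene_ids[i], chrom = chrom, start = e1,
             end = e1 + exon_lens[i, ])
    })
    exons <- bind_rows(exon_rows)
    genes <- exons |>
      group_by(.data$gene_id) |>
      summarise(chrom = first(.data$chrom), start = min(.data$start),
                end = max(.data$end), .groups = "drop") |>
      mutate(strand = strands[match(.data$gene_id, gene_ids)]) |>
      select("gene_id", "chrom", "strand", "start", "end")

    # plant an ORF >= 150 aa into each gene's spliced sequence
    orf_aa <- integer(ng)
    for (i in seq_len(ng)) {
      splen <- sum(exon_lens[i, ])
      max_aa <- (splen - 40L) %/% 3L - 2L
      aa <- sample(150:min(260L, max_aa), 1)
      orf_aa[i] <- aa
      orf_seq <- paste0("ATG", .sense_codons(aa - 1L),
                        sample(c("TAA", "TAG", "TGA"), 1))
      orf_nt <- nchar(orf_seq)
      utr5 <- sample.int(splen - orf_nt - 10L, 1)
      spliced <- paste0(
        paste0(sample(c("A", "C", "G", "T"), utr5, replace = TRUE),
               collapse = ""),
        orf_seq,
        paste0(sample(c("A", "C", "G", "T"), splen - utr5 - orf_nt,
                      replace = TRUE), collapse = ""))
      gchars <- .write_spliced(gchars, exon_rows[[i]], strands[i], spliced)
    }

    # --- transposable elements ---
    w <- config$te_superfamily_weights / sum(config$te_superfamily_weights)
    te_total <- round(config$te_genome_fraction * L)
    len_range <- function(fam) {
      if (grepl("^LTR/Gypsy", fam)) return(c(5000, 12000))
      if (grepl("^LTR", fam)) return(c(4000, 10000))
      if (grepl("^LINE", fam)) return(c(2000, 5000))
      if (grepl("^SINE", fam)) return(c(150, 400))
      if (grepl("Helitron", fam)) return(c(1000, 6000))
      c(500, 3000)
    }
    te_rows <- purrr::imap(w, function(wt, fam) {
      target <- round(wt * te_total)
      rng <- len_range(fam)
      lens <- integer(0)
      while (sum(lens) < target) {
        lens <- c(lens, sample(rng[1]:rng[2], 1))
      }
      excess <- sum(lens) - target
      lens[length(lens)] <- lens[length(lens)] - excess
      if (lens[length(lens)] < 100) {
        lens <- lens[-length(lens)]
      }
      tibble(superfamily = fam, width = lens)
    }) |> bind_rows()
    # place widest elements first so large retrotransposons find room
    te_rows <- te_rows[order(-te_rows$width), ]
    gene_blocks <- mutate(genes, start = pmax(0L, .data$start - 200L),
                          end = pmin(L, .data$end + 200L))
    free <- .complement_intervals(
      select(gene_blocks, "chrom", "start", "end"), L, chrom)
    placed <- vector("list", nrow(te_rows))
    for (i in seq_len(nrow(te_rows))) {
      wdt <- te_rows$width[i]
      st <- .place_in_free(free, wdt)
      if (is.na(st)) {
        abort("simulate_genome_and_annotations(): TE packing infeasible; increase genome_length or reduce te_genome_fraction")
      }
      placed[[i]] <- tibble(chrom = chrom, start = st, end = st + wdt,
                            superfamily = te_rows$superfamily[i])
      seg <- which(free$start <= st & free$end >= st + wdt)[1]
      old <- free[seg, ]
      free <- free[-seg, ]
      free <- bind_rows(free,
                        tibble(chrom = chrom, start = old$start, end = st),
                        tibble(chrom = chrom, start = st + wdt,
                               end = old$end)) |>
        filter(.data$end - .data$start > 0)
    }
    te <- bind_rows(placed) |> arrange(.data$start)

    genome <- tibble(id = chrom, seq = paste0(gchars, collapse = ""))
    ann <- gene_annotation(genes, select(exons, "gene_id", "chrom",
                                         "start", "end"))
    list(genome = genome, ann = ann, te = te,
         gene_meta = tibble(gene_id = gene_ids, strand = strands,
                            planted_orf_aa = orf_aa))
  })
}

#' Simulate transcript models with planted classes
#'
#' One coding transcript per gene (carrying the planted ORF), plus
#' lncRNAs: TE-derived lncRNAs copy at least 90% of their sequence from a
#' single TE interval and sit intergenic; a configured fraction is placed
#' fully inside introns; the rest are intergenic and TE-free. Every lncRNA
#' is rejection-sampled until it is at least 200 nt with a longest ORF
#' under 100 aa covering under 35% of its length, so planted lncRNAs
#' satisfy the discovery definition by construction.
#'
#' @param config A [sim_config()].
#' @param genome,ann,te From [simulate_genome_and_annotations()].
#' @return List with `exons` (per-exon tibble for all transcripts), `seqs`
#'   (tibble `id`, `seq`) and `truth` (per-transcript tibble:
#'   `transcript_id`, `class`, `superfamily`, `intronic`,
#'   `polyA_origin`).
#' @export
simulate_transcripts <- function(config, genome, ann, te) {
  withr::with_seed(config$seed + 1L, {
    chrom <- genome$id[[1]]
    L <- nchar(genome$seq[[1]])
    n_lnc <- config$n_lncRNA
    n_te <- round(config$frac_te_derived * n_lnc)
    n_intr <- round(config$frac_intronic * n_lnc)
    n_free <- n_lnc - n_te - n_intr
    .check(n_free >= 0, "simulate_transcripts(): class fractions exceed 1")

    coding_exons <- ann$exons |>
      left_join(select(ann$genes, "gene_id", "strand"), by = "gene_id") |>
      mutate(transcript_id = paste0(.data$gene_id, ".t1")) |>
      select("transcript_id", "gene_id", "chrom", "strand", "start", "end")

    draw_len <- function() {
      min(1500L, max(200L, round(rlnorm(1, log(380), 0.45))))
    }
    occupied <- tibble(chrom = character(), start = integer(),
                       end = integer())
    no_overlap <- function(st, en) {
      !any(occupied$start < en & occupied$end > st)
    }
    lnc_seq_at <- function(st, en, strand) {
      s <- substring(genome$seq[[1]], st + 1L, en)
      if (strand == "-") {
        s <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(s)))
      }
      s
    }

    lnc <- list(); truth_rows <- list(); k <- 0L

    # TE-derived lncRNAs
    if (n_te > 0) {
      bias <- rep(1, nrow(te))
      if (!is.null(config$lnc_te_family_bias)) {
        b <- config$lnc_te_family_bias
        hit <- te$superfamily %in% names(b)
        bias[hit] <- b[te$superfamily[hit]]
      }
      wts <- (te$end - te$start) * bias
      for (i in seq_len(n_te)) {
        placedok <- FALSE
        for (try in 1:500) {
          len <- draw_len()
          elig <- which(te$end - te$start >= len)
          if (!length(elig)) next
          row <- if (length(elig) == 1) elig else
            sample(elig, 1, prob = wts[elig] / sum(wts[elig]))
          tw <- te$end[row] - te$start[row]
          overhang <- if (runif(1) < 0.25) {
            sample.int(max(1L, floor(0.1 * len) - 1L), 1)
          } else 0L
          st <- te$start[row] - overhang +
            sample.int(tw - (len - overhang) + 1L, 1) - 1L
          st <- max(0L, st)
          en <- st + len
          if (en > L || !no_overlap(st, en)) next
          strand <- sample(c("+", "-"), 1)
          sq <- lnc_seq_at(st, en, strand)
          if (!.lnc_seq_ok(sq)) next
          k <- k + 1L
          id <- sprintf("lnc%03d", k)
          lnc[[k]] <- tibble(transcript_id = id, gene_id = id,
                             chrom = chrom, strand = strand, start = st,
                             end = en)
          truth_rows[[k]] <- tibble(transcript_id = id,
                                    class = "TE_lncRNA",
                                    superfamily = te$superfamily[row],
                                    intronic = FALSE)
          occupied <- bind_rows(occupied, tibble(chrom = chrom,
                                                 start = st, end = en))
          placedok <- TRUE
          break
        }
        if (!placedok) {
          abort("simulate_transcripts(): TE-lncRNA placement retry cap hit; use a longer genome")
        }
      }
    }

    # intronic lncRNAs
    if (n_intr > 0) {
      introns <- ann$introns
      for (i in seq_len(n_intr)) {
        placedok <- FALSE
        for (try in 1:500) {
          len <- draw_len()
          elig <- which(introns$end - introns$start >= len + 4L)
          if (!length(elig)) next
          row <- elig[sample.int(length(elig), 1)]
          st <- introns$start[row] + 1L +
            sample.int(introns$end[row] - introns$start[row] - len - 1L, 1)
          en <- st + len
          if (!no_overlap(st, en)) next
          strand <- sample(c("+", "-"), 1)
          sq <- lnc_seq_at(st, en, strand)
          if (!.lnc_seq_ok(sq)) next
          k <- k + 1L
          id <- sprintf("lnc%03d", k)
          lnc[[k]] <- tibble(transcript_id = id, gene_id = id,
                             chrom = chrom, strand = strand, start = st,
                             end = en)
          truth_rows[[k]] <- tibble(transcript_id = id, class = "lncRNA",
                                    superfamily = NA_character_,
                                    intronic = TRUE)
          occupied <- bind_rows(occupied, tibble(chrom = chrom,
                                                 start = st, end = en))
          placedok <- TRUE
          break
        }
        if (!placedok) {
          abort("simulate_transcripts(): intronic lncRNA placement retry cap hit; increase intron sizes")
        }
      }
    }

    # intergenic TE-free lncRNAs
    if (n_free > 0) {
      blocked <- bind_rows(
        mutate(select(ann$genes, "chrom", "start", "end"),
               start = pmax(0L, .data$start - 100L),
               end = pmin(L, .data$end + 100L)),
        select(te, "chrom", "start", "end"))
      for (i in seq_len(n_free)) {
        placedok <- FALSE
        for (try in 1:500) {
          len <- draw_len()
          free <- .complement_intervals(bind_rows(blocked, occupied), L,
                                        chrom)
          st <- .place_in_free(free, len)
          if (is.na(st)) next
          en <- st + len
          strand <- sample(c("+", "-"), 1)
          sq <- lnc_seq_at(st, en, strand)
          if (!.lnc_seq_ok(sq)) next
          k <- k + 1L
          id <- sprintf("lnc%03d", k)
          lnc[[k]] <- tibble(transcript_id = id, gene_id = id,
                             chrom = chrom, strand = strand, start = st,
                             end = en)
          truth_rows[[k]] <- tibble(transcript_id = id, class = "lncRNA",
                                    superfamily = NA_character_,
                                    intronic = FALSE)
          occupied <- bind_rows(occupied, tibble(chrom = chrom,
                                                 start = st, end = en))
          placedok <- TRUE
          break
        }
        if (!placedok) {
          abort("simulate_transcripts(): intergenic lncRNA placement retry cap hit; use a longer genome")
        }
      }
    }

    lnc_exons <- bind_rows(lnc)
    exons <- bind_rows(coding_exons, lnc_exons)
    seqs <- extract_transcript_seqs(exons, genome)
    truth <- bind_rows(
      tibble(transcript_id = unique(coding_exons$transcript_id),
             class = "coding", superfamily = NA_character_,
             intronic = FALSE),
      bind_rows(truth_rows))
    lnc_ids <- truth$transcript_id[truth$class != "coding"]
    total_only <- sample(lnc_ids,
                         round(config$frac_total_rna_only *
                                 length(lnc_ids)))
    truth$polyA_origin <- if_else(
      truth$transcript_id %in% total_only, "polyA_minus", "polyA_plus")
    list(exons = exons, seqs = seqs, truth = truth)
  })
}

#' Simulate a count matrix with planted DE, modules and cis effects
#'
#' Counts are negative binomial with log-normal base expression (coding
#' transcripts expressed severalfold above lncRNAs), planted log2
#' fold-change shifts in treatment groups, trait-driven latent factors
#' shared by module members (hubs follow the latent factor with loading
#' 1), zero counts for total-RNA-only lncRNAs in polyA+ libraries, and
#' nearest-gene effect sharing for DE lncRNAs tuned to the configured
#' cis correlation.
#'
#' @param config A [sim_config()].
#' @param transcripts The list from [simulate_transcripts()].
#' @param ann A [gene_annotation()] (for nearest-gene cis planting; `NULL`
#'   disables it).
#' @return List with `counts` (tibble), `samples` (tibble), and `truth`
#'   extended with `base_fpkm`, `module`, `is_hub` plus tables
#'   `de_effects`, `cis_pairs`, `module_traits` and `latents`.
#' @export
simulate_counts <- function(config, transcripts, ann = NULL) {
  withr::with_seed(config$seed + 2L, {
    truth <- transcripts$truth
    spans <- transcript_spans(transcripts$exons)
    lens <- setNames(spans$length, spans$transcript_id)
    ids <- truth$transcript_id
    nt <- length(ids)

    # sample design
    polya <- expand.grid(replicate = seq_len(config$n_samples_per_group),
                         condition = c("control",
                                       config$stress_conditions),
                         stage = config$stages,
                         stringsAsFactors = FALSE) |>
      mutate(library_type = "polyA")
    total <- expand.grid(replicate = seq_len(config$n_total_rna_per_stage),
                         condition = "control", stage = config$stages,
                         stringsAsFactors = FALSE) |>
      mutate(library_type = "total")
    samples <- bind_rows(polya, total) |>
      mutate(sample_id = sprintf("%s_%s_%s_r%d", .data$stage,
                                 .data$condition,
                                 if_else(.data$library_type == "polyA",
                                         "pA", "tot"), .data$replicate),
             is_control = .data$condition == "control",
             library_size = round(runif(n(), config$library_size_range[1],
                                        config$library_size_range[2]))) |>
      select("sample_id", "library_type", "condition", "stage",
             "is_control", "replicate", "library_size") |>
      as_tibble()
    ns <- nrow(samples)

    # base expression (FPKM scale)
    mult <- dplyr::case_when(
      truth$class == "coding" ~ 1,
      truth$class == "TE_lncRNA" ~ config$te_lnc_fpkm_ratio,
      TRUE ~ config$lnc_fpkm_ratio)
    base_fpkm <- rlnorm(nt, meanlog = log(config$mean_fpkm_coding * mult),
                        sdlog = config$fpkm_sdlog)
    truth$base_fpkm <- base_fpkm

    # modules: trait-driven latent factors; first member of each is a hub
    n_mem <- config$n_modules * config$module_size
    eligible <- ids[truth$polyA_origin == "polyA_plus" & base_fpkm >= 1]
    .check(length(eligible) >= n_mem,
           "simulate_counts(): not enough expressed polyA+ transcripts for the requested modules")
    members <- sample(eligible, n_mem)
    truth$module <- NA_character_
    truth$is_hub <- FALSE
    combos <- expand.grid(condition = config$stress_conditions,
                          stage = config$stages,
                          stringsAsFactors = FALSE)
    combos <- combos[sample.int(nrow(combos), config$n_modules), ,
                     drop = FALSE]
    w <- config$module_trait_cor
    latents <- matrix(0, config$n_modules, ns)
    colnames(latents) <- samples$sample_id
    if (config$n_modules > 0) {
      rownames(latents) <- paste0("mod", seq_len(config$n_modules))
    }
    module_traits <- tibble(module = rownames(latents) %||% character(0),
                            condition = combos$condition,
                            stage = combos$stage)
    log2mu_off <- matrix(0, nt, ns, dimnames = list(ids,
                                                    samples$sample_id))
    rho <- config$module_cor
    for (m in seq_len(config$n_modules)) {
      mem <- members[((m - 1) * config$module_size + 1):
                       (m * config$module_size)]
      # the hub follows the latent factor with loading 1; use the
      # best-measured member so counting noise stays small around it
      mem <- mem[order(-base_fpkm[match(mem, ids)])]
      truth$module[match(mem, ids)] <- rownames(latents)[m]
      truth$is_hub[match(mem[1], ids)] <- TRUE
      ind <- as.numeric(samples$condition == combos$condition[m] &
                          samples$stage == combos$stage[m])
      z <- w * as.numeric(scale(ind)) + sqrt(1 - w^2) * rnorm(ns)
      latents[m, ] <- z
      for (j in seq_along(mem)) {
        load <- if (j == 1) z else
          sqrt(rho) * z + sqrt(1 - rho) * rnorm(ns)
        log2mu_off[mem[j], ] <- log2mu_off[mem[j], ] +
          config$module_sd_log2 * load
      }
    }

    # planted differential expression on non-module polyA+ transcripts
    pool <- ids[is.na(truth$module) & truth$polyA_origin == "polyA_plus"]
    n_de <- min(length(pool), round(config$de_fraction * nt))
    de_ids <- sample(pool, n_de)
    all_contrasts <- expand.grid(condition = config$stress_conditions,
                                 stage = config$stages,
                                 stringsAsFactors = FALSE)
    de_rows <- purrr::map(de_ids, function(id) {
      sgn <- sample(c(-1, 1), 1)
      pick <- sample.int(nrow(all_contrasts), 1)
      rows <- all_contrasts[pick, , drop = FALSE]
      if (runif(1) < config$de_share_prob) {
        extra <- sample(setdiff(seq_len(nrow(all_contrasts)), pick), 1)
        rows <- rbind(rows, all_contrasts[extra, , drop = FALSE])
      }
      tibble(transcript_id = id, condition = rows$condition,
             stage = rows$stage, log2fc = sgn * config$de_log2fc)
    })
    de_effects <- bind_rows(de_rows)

    # cis effect sharing with nearest genes of DE lncRNAs
    cis_pairs <- tibble(transcript_id = character(), gene_id = character(),
                        condition = character(), stage = character(),
                        lnc_log2fc = numeric(), gene_log2fc = numeric())
    if (!is.null(ann)) {
      de_lnc <- intersect(de_ids,
                          ids[truth$class %in% c("lncRNA", "TE_lncRNA")])
      if (length(de_lnc)) {
        loci <- filter(spans, .data$transcript_id %in% de_lnc)
        links <- suppressWarnings(nearest_gene(loci, ann))
        r <- config$cis_effect_r
        a <- 0.5
        sd_e <- a * config$de_log2fc * sqrt(1 / r^2 - 1)
        used_genes <- character()
        cis_rows <- list()
        for (i in seq_len(nrow(links))) {
          lid <- links$transcript_id[i]
          gid <- paste0(links$gene_id[i], ".t1")
          if (!gid %in% ids || gid %in% used_genes) next
          if (!is.na(truth$module[match(gid, ids)])) next
          if (gid %in% de_ids) next
          used_genes <- c(used_genes, gid)
          eff <- filter(de_effects, .data$transcript_id == lid)
          cis_rows[[length(cis_rows) + 1]] <-
            tibble(transcript_id = lid, gene_id = gid,
                   condition = eff$condition, stage = eff$stage,
                   lnc_log2fc = eff$log2fc,
                   gene_log2fc = a * eff$log2fc +
                     rnorm(nrow(eff), 0, sd_e))
        }
        cis_pairs <- bind_rows(cis_rows)
      }
    }

    # assemble per-sample log2 mean and draw NB counts
    lt <- lens[ids] / 1e3
    base_mu <- outer(base_fpkm * lt, samples$library_size / 1e6)
    dimnames(base_mu) <- dimnames(log2mu_off)
    log2mu <- log2(base_mu) + log2mu_off
    apply_effects <- function(tab, col) {
      for (i in seq_len(nrow(tab))) {
        cols <- samples$sample_id[samples$condition == tab$condition[i] &
                                    samples$stage == tab$stage[i]]
        log2mu[tab$transcript_id[i], cols] <<-
          log2mu[tab$transcript_id[i], cols] + tab[[col]][i]
      }
    }
    apply_effects(de_effects, "log2fc")
    if (nrow(cis_pairs)) {
      gene_eff <- cis_pairs |>
        select(transcript_id = "gene_id", "condition", "stage",
               log2fc = "gene_log2fc")
      apply_effects(gene_eff, "log2fc")
    }
    mu <- 2^log2mu
    # total-RNA-only lncRNAs are invisible to polyA+ libraries
    polya_cols <- samples$sample_id[samples$library_type == "polyA"]
    mu[ids[truth$polyA_origin == "polyA_minus"], polya_cols] <- 0
    counts <- matrix(rnbinom(nt * ns, mu = mu,
                             size = 1 / config$nb_dispersion),
                     nt, ns, dimnames = dimnames(mu))
    counts_tbl <- bind_cols(tibble(transcript_id = ids),
                            as_tibble(counts))
    list(counts = counts_tbl, samples = samples,
         truth = list(transcripts = truth, de_effects = de_effects,
                      cis_pairs = cis_pairs,
                      module_traits = module_traits,
                      latents = latents))
  })
}

#' Simulate a complete dataset and write it to disk
#'
#' Runs [simulate_genome_and_annotations()], [simulate_transcripts()] and
#' [simulate_counts()] under the configured seed, and (optionally) writes
#' genome FASTA, gene GFF3, TE BED4, transcript GTF + FASTA, counts and
#' sample TSVs and a ground-truth JSON. Outputs are byte-identical across
#' runs with the same configuration.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (`NULL` to skip writing).
#' @return An object of class `lnc_sim`: list with `config`, `genome`,
#'   `ann`, `te`, `exons`, `seqs`, `counts`, `samples`, `truth`.
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  gen <- simulate_genome_and_annotations(config)
  tx <- simulate_transcripts(config, gen$genome, gen$ann, gen$te)
  cnt <- simulate_counts(config, tx, ann = gen$ann)
  sim <- structure(
    list(config = config, genome = gen$genome, ann = gen$ann, te = gen$te,
         exons = tx$exons, seqs = tx$seqs, counts = cnt$counts,
         samples = cnt$samples, truth = cnt$truth),
    class = "lnc_sim")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(sim$genome, file.path(dir, "genome.fa"))
    write_gff3_genes(sim$ann, file.path(dir, "genes.gff3"))
    write_te_bed(sim$te, file.path(dir, "te.bed"))
    write_gtf(sim$exons, file.path(dir, "transcripts.gtf"))
    write_fasta(sim$seqs, file.path(dir, "transcripts.fa"))
    readr::write_tsv(sim$counts, file.path(dir, "counts.tsv"),
                     progress = FALSE)
    readr::write_tsv(sim$samples, file.path(dir, "samples.tsv"),
                     progress = FALSE)
    truth_json <- list(
      transcripts = sim$truth$transcripts,
      de_effects = sim$truth$de_effects,
      cis_pairs = sim$truth$cis_pairs,
      module_traits = sim$truth$module_traits,
      latents = as.data.frame(sim$truth$latents) |>
        tibble::rownames_to_column("module"))
    jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                         digits = NA, na = "null")
  }
  sim
}

#' @export
print.lnc_sim <- function(x, ...) {
  cat("<lnc_sim> ", nrow(x$truth$transcripts), " transcripts (",
      sum(x$truth$transcripts$class != "coding"), " lncRNAs), ",
      nrow(x$samples), " samples, seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}
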