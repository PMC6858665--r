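#' Pipeline configuration
#'
#' Bundles the stage configurations and thresholds used by
#' [pipeline_run()].
#'
#' @param discovery A [discovery_config()]; the default disables the
#'   external-evidence requirement so the internal ORF stand-in is used
#'   when no CPC2/CNCI tables are supplied.
#' @param network A [network_config()].
#' @param lfc_min,padj_max DE call thresholds.
#' @param evidence Optional external evidence tibble (see
#'   [coding_potential_verdict()]).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(discovery = discovery_config(
                              require_both_predictors = FALSE),
                            network = network_config(),
                            lfc_min = 1.0, padj_max = 0.05,
                            evidence = NULL) {
  structure(list(discovery = discovery, network = network,
                 lfc_min = lfc_min, padj_max = padj_max,
                 evidence = evidence),
            class = "pipeline_config")
}

#' Simulate a dataset directory
#'
#' Thin orchestration wrapper over [simulate_dataset()] that also writes a
#' run manifest. Identical configurations produce byte-identical
#' directories.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return The `lnc_sim` object, invisibly.
#' @export
pipeline_simulate <- function(config = sim_config(), dir) {
  sim <- simulate_dataset(config, dir)
  manifest <- list(stage = "simulate", seed = config$seed,
                   config_hash = rlang::hash(unclass(config)),
                   package = "lncstress",
                   version = as.character(utils::packageVersion(
                     "lncstress")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(sim)
}

# internal: TSV writer with a provenance header line
.write_stage_tsv <- function(df, path, stage, hash) {
  writeLines(sprintf("# stage=%s config=%s", stage, hash), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

# internal: read a stage TSV back, skipping the provenance header
.read_stage_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Run pipeline stages over a dataset directory
#'
#' Reads the dataset files written by [pipeline_simulate()] (or arranged
#' in the same layout) and runs the requested stages in dependency order:
#' `discover` (lncRNA filter cascade), `te` (TE overlap and superfamily
#' enrichment), `de` (per-contrast NB Wald tests), `network` (modules,
#' eigengenes, module-trait correlations), `hubs` (hub table), `report`
#' (accounting tables + run manifest). A stage whose prerequisite was
#' neither requested nor previously run fails with an error naming the
#' missing stage. Outputs land in `<dir>/results` as TSVs headed by the
#' producing stage and configuration hash.
#'
#' @param dir Dataset directory.
#' @param stages Subset of
#'   `c("discover", "te", "de", "network", "hubs", "report")`.
#' @param config A [pipeline_config()].
#' @return A list with the in-memory results of the stages run.
#' @export
pipeline_run <- function(dir,
                         stages = c("discover", "te", "de", "network",
                                    "hubs", "report"),
                         config = pipeline_config()) {
  stages <- match.arg(stages, several.ok = TRUE)
  resdir <- file.path(dir, "results")
  dir.create(resdir, recursive = TRUE, showWarnings = FALSE)
  hash <- rlang::hash(unclass(config))

  need <- function(path, stage, wanted) {
    if (!file.exists(path)) {
      abort(paste0("pipeline_run(): stage '", wanted,
                   "' requires outputs of stage '", stage,
                   "'; run it first or include it in `stages` (missing ",
                   path, ")"))
    }
    path
  }
  for (f in c("transcripts.gtf", "transcripts.fa", "genes.gff3", "te.bed",
              "counts.tsv", "samples.tsv")) {
    .check(file.exists(file.path(dir, f)),
           paste0("pipeline_run(): dataset file missing: ", f))
  }

  exons <- read_gtf(file.path(dir, "transcripts.gtf"))
  seqs <- read_fasta(file.path(dir, "transcripts.fa"))
  ann <- read_gff3_genes(file.path(dir, "genes.gff3"))
  te <- read_te_annotation(file.path(dir, "te.bed"), "bed")
  counts <- read_counts(file.path(dir, "counts.tsv"))
  samples <- read_samples(file.path(dir, "samples.tsv"))
  spans <- transcript_spans(exons)
  fpkm <- compute_fpkm(counts, setNames(spans$length, spans$transcript_id),
                       setNames(samples$library_size, samples$sample_id))
  out <- list()

  # --- discover ---
  if ("discover" %in% stages) {
    disc <- run_discovery(exons, seqs, ann, fpkm, samples,
                          evidence = config$evidence,
                          config = config$discovery)
    rec_flat <- disc$records |>
      mutate(rejection_reasons = vapply(.data$rejection_reasons, paste,
                                        "", collapse = ",")) |>
      select(-dplyr::any_of(c("longest_start", "longest_end")))
    .write_stage_tsv(rec_flat, file.path(resdir, "discovery_records.tsv"),
                     "discover", hash)
    out$discovery <- disc
  } else if (any(c("te", "de", "network", "hubs", "report") %in% stages)) {
    p <- need(file.path(resdir, "discovery_records.tsv"), "discover",
              setdiff(stages, "discover")[1])
    rec <- .read_stage_tsv(p)
    rec$passed <- as.logical(rec$passed)
    out$discovery <- structure(list(records = rec,
                                    config = config$discovery),
                               class = "lnc_discovery")
  }
  records <- out$discovery$records
  lnc_ids <- records$transcript_id[records$passed]

  # --- te ---
  if ("te" %in% stages) {
    lnc_exons <- filter(exons, .data$transcript_id %in% lnc_ids)
    te_res <- masked_fraction(lnc_exons, te)
    flat <- select(te_res, -"bp_by_superfamily")
    .write_stage_tsv(flat, file.path(resdir, "te_overlap.tsv"), "te", hash)
    enr <- superfamily_enrichment(te_res, te)
    .write_stage_tsv(as_tibble(enr), file.path(resdir, "te_enrichment.tsv"),
                     "te", hash)
    out$te <- te_res
    out$enrichment <- enr
  } else if (any(c("network", "hubs", "report") %in% stages)) {
    p <- need(file.path(resdir, "te_overlap.tsv"), "te",
              intersect(stages, c("network", "hubs", "report"))[1])
    out$te <- .read_stage_tsv(p)
  }

  classes <- tibble(transcript_id = records$transcript_id) |>
    mutate(class = dplyr::case_when(
      !.data$transcript_id %in% lnc_ids ~ "coding",
      .data$transcript_id %in%
        out$te$transcript_id[out$te$is_te_lncRNA] ~ "TE_lncRNA",
      TRUE ~ "lncRNA"))

  # --- de ---
  if ("de" %in% stages) {
    pa <- filter(samples, .data$library_type == "polyA")
    ctr <- filter(pa, .data$is_control)
    specs <- pa |>
      filter(!.data$is_control) |>
      distinct(.data$condition, .data$stage) |>
      purrr::pmap(function(condition, stage) {
        trt <- pa$sample_id[pa$condition == condition &
                              pa$stage == stage]
        ctl <- ctr$sample_id[ctr$stage == stage]
        if (length(trt) < 2 || length(ctl) < 2) return(NULL)
        contrast_spec(paste0(condition, "_", stage), trt, ctl)
      })
    specs <- specs[!vapply(specs, is.null, TRUE)]
    cm <- .counts_matrix(counts)[, pa$sample_id, drop = FALSE]
    de <- run_contrasts(cm, specs, lfc_min = config$lfc_min,
                        padj_max = config$padj_max)
    for (nm in names(de)) {
      .write_stage_tsv(as_tibble(de[[nm]]),
                       file.path(resdir, paste0("de_", nm, ".tsv")),
                       "de", hash)
    }
    out$de <- de
    out$de_summary <- de_overlap_summary(de, classes)
  }

  # --- network (+ hubs) ---
  if (any(c("network", "hubs") %in% stages)) {
    pa <- filter(samples, .data$library_type == "polyA")
    cm <- .counts_matrix(counts)[, pa$sample_id, drop = FALSE]
    cm <- cm[rowSums(cm) > 0, , drop = FALSE]
    combos <- pa |>
      filter(!.data$is_control) |>
      distinct(.data$condition, .data$stage)
    traits <- vapply(seq_len(nrow(combos)), function(i) {
      as.numeric(pa$condition == combos$condition[i] &
                   pa$stage == combos$stage[i])
    }, numeric(nrow(pa)))
    colnames(traits) <- paste0(combos$condition, "_", combos$stage)
    rownames(traits) <- pa$sample_id
    net <- build_network(cm, traits, config = config$network,
                         classes = classes)
    .write_stage_tsv(tibble(transcript_id = names(net$modules),
                            module = unname(net$modules)),
                     file.path(resdir, "modules.tsv"), "network", hash)
    .write_stage_tsv(net$module_trait,
                     file.path(resdir, "module_trait.tsv"), "network",
                     hash)
    eg_tbl <- if (is.null(net$eigengenes)) {
      tibble(module = character())
    } else {
      as_tibble(net$eigengenes, rownames = "module")
    }
    .write_stage_tsv(eg_tbl, file.path(resdir, "eigengenes.tsv"),
                     "network", hash)
    out$network <- net
    if ("hubs" %in% stages) {
      .write_stage_tsv(net$hubs, file.path(resdir, "hubs.tsv"), "hubs",
                       hash)
    }
  }

  # --- report ---
  if ("report" %in% stages) {
    tab1 <- discovery_summary(out$discovery, te_result = out$te)
    .write_stage_tsv(tab1, file.path(resdir, "table1_discovery.tsv"),
                     "report", hash)
    if (!is.null(out$enrichment)) {
      .write_stage_tsv(enrichment_groups(out$enrichment),
                       file.path(resdir, "table2_te_groups.tsv"),
                       "report", hash)
    }
    if (!is.null(out$de_summary)) {
      .write_stage_tsv(out$de_summary$summary,
                       file.path(resdir, "table3_de.tsv"), "report", hash)
    }
    manifest <- list(stages = stages, config_hash = hash,
                     package = "lncstress",
                     version = as.character(utils::packageVersion(
                       "lncstress")))
    jsonlite::write_json(manifest, file.path(resdir, "manifest.json"),
                         auto_unbox = TRUE)
    out$table1 <- tab1
  }
  out
}
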