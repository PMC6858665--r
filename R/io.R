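#' Read transcript models from a GTF file
#'
#' Parses exon features from a GTF file into a per-exon tibble using the
#' package's internal 0-based half-open coordinate convention (GTF itself is
#' 1-based inclusive; the shift happens here and only here). Lines are
#' validated before parsing so malformed rows are reported by line number.
#'
#' @param path Path to a GTF file whose exon features carry `transcript_id`
#'   and `gene_id` attributes.
#' @return A tibble with one row per exon, columns `transcript_id`,
#'   `gene_id`, `chrom`, `strand`, `start`, `end`, sorted by transcript and
#'   start. Round-trips with [write_gtf()].
#' @export
read_gtf <- function(path) {
  .check(file.exists(path), paste0("GTF file not found: ", path))
  lines <- readLines(path)
  body <- !grepl("^#", lines) & nzchar(trimws(lines))
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, 1L)
  if (any(nf < 9)) {
    bad <- which(body)[which(nf < 9)[1]]
    abort(paste0("malformed GTF line ", bad, " in ", path,
                 ": expected 9 tab-separated fields"))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) {
    return(tibble(transcript_id = character(), gene_id = character(),
                  chrom = character(), strand = character(),
                  start = integer(), end = integer()))
  }
  tid <- as.character(gr$transcript_id)
  if (anyNA(tid)) {
    abort("GTF exon feature without a transcript_id attribute")
  }
  gid <- if (!is.null(gr$gene_id)) as.character(gr$gene_id) else tid
  out <- tibble(
    transcript_id = tid,
    gene_id = gid,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = as.integer(GenomicRanges::start(gr) - 1L),
    end = as.integer(GenomicRanges::end(gr))
  )
  out$strand[out$strand == "*"] <- "."
  arrange(out, .data$chrom, .data$transcript_id, .data$start)
}

#' Write transcript models to a GTF file
#'
#' Emits one exon feature per row with `transcript_id`/`gene_id` attributes,
#' in deterministic (chrom, transcript, start) order, converting the internal
#' 0-based half-open coordinates back to GTF's 1-based inclusive convention.
#'
#' @param exons Per-exon tibble as returned by [read_gtf()].
#' @param path Output file path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(exons, path, source = "lncstress") {
  .check_intervals(exons, "exons")
  ex <- arrange(exons, .data$chrom, .data$transcript_id, .data$start)
  strand <- ifelse(ex$strand %in% c("+", "-"), ex$strand, ".")
  lines <- sprintf(
    "%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    ex$chrom, source, ex$start + 1L, ex$end, strand, ex$gene_id,
    ex$transcript_id
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace token of each header)
#'   and `seq` (uppercased sequence).
#' @export
read_fasta <- function(path) {
  .check(file.exists(path), paste0("FASTA file not found: ", path))
  ss <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, "", 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    abort(paste0("duplicate FASTA id(s): ", paste(dup, collapse = ", ")))
  }
  tibble(id = ids, seq = unname(toupper(as.character(ss))))
}

#' Write a FASTA file
#'
#' @param seqs Tibble with columns `id` and `seq`.
#' @param path Output file path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  .check(all(c("id", "seq") %in% names(seqs)),
         "`seqs` needs columns id and seq")
  ss <- Biostrings::BStringSet(setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(ss, path, width = as.integer(width))
  invisible(path)
}

#' Read a transposable-element annotation
#'
#' Reads TE intervals with superfamily labels from either a BED4 file
#' (0-based half-open, column 4 = superfamily) or a RepeatMasker `.out`
#' table (1-based inclusive query coordinates, whitespace-separated, with
#' the repeat class/family in column 11). Both are normalized to the
#' internal 0-based half-open convention.
#'
#' @param path Path to the annotation file.
#' @param dialect `"bed"` or `"repeatmasker_out"`.
#' @return A tibble with columns `chrom`, `start`, `end`, `superfamily`.
#' @export
read_te_annotation <- function(path, dialect = c("bed", "repeatmasker_out")) {
  dialect <- match.arg(dialect)
  .check(file.exists(path), paste0("TE annotation not found: ", path))
  if (dialect == "bed") {
    tab <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                           progress = FALSE)
    .check(ncol(tab) >= 4, "BED4 TE annotation needs at least 4 columns")
    out <- tibble(
      chrom = as.character(tab[[1]]),
      start = as.integer(tab[[2]]),
      end = as.integer(tab[[3]]),
      superfamily = as.character(tab[[4]])
    )
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    # header lines of .out start with "SW"/"score" banners; skip them
    is_head <- grepl("^\\s*(SW|score)", lines)
    lines <- lines[!is_head]
    fields <- strsplit(trimws(lines), "\\s+")
    .check(all(vapply(fields, length, 1L) >= 11),
           "RepeatMasker .out rows need at least 11 fields")
    qbeg <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 6L)))
    qend <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 7L)))
    if (anyNA(qbeg) || anyNA(qend)) {
      abort("RepeatMasker .out: non-numeric query coordinates")
    }
    out <- tibble(
      chrom = vapply(fields, `[[`, "", 5L),
      start = qbeg - 1L,
      end = qend,
      superfamily = vapply(fields, `[[`, "", 11L)
    )
  }
  .check_intervals(out, "te annotation")
  out
}

#' Write a BED4 transposable-element annotation
#'
#' @param te Tibble with columns `chrom`, `start`, `end`, `superfamily`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_te_bed <- function(te, path) {
  .check_intervals(te, "te")
  te <- arrange(te, .data$chrom, .data$start, .data$superfamily)
  writeLines(sprintf("%s\t%d\t%d\t%s", te$chrom, te$start, te$end,
                     te$superfamily), path)
  invisible(path)
}

#' Assemble a gene annotation from gene spans and exons
#'
#' Derives introns as the within-gene complement of sorted exons.
#'
#' @param genes Tibble with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end` (gene spans, 0-based half-open).
#' @param exons Tibble with columns `gene_id`, `chrom`, `start`, `end`.
#' @return An object of class `gene_annotation`: a list with tibbles
#'   `genes`, `exons` and derived `introns`.
#' @export
gene_annotation <- function(genes, exons) {
  .check_intervals(genes, "genes")
  .check_intervals(exons, "exons")
  exons <- arrange(exons, .data$gene_id, .data$start)
  introns <- exons |>
    group_by(.data$gene_id) |>
    reframe_introns() |>
    ungroup()
  structure(list(genes = as_tibble(genes), exons = as_tibble(exons),
                 introns = introns),
            class = "gene_annotation")
}

# internal: per-gene introns with chrom carried along
reframe_introns <- function(grouped_exons) {
  grouped_exons |>
    summarise(chrom = first(.data$chrom),
              introns = list(.introns_of(.data$start, .data$end)),
              .groups = "drop") |>
    tidyr::unnest("introns")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("<gene_annotation> ", nrow(x$genes), " genes, ", nrow(x$exons),
      " exons, ", nrow(x$introns), " introns\n", sep = "")
  invisible(x)
}

#' Read a gene annotation from GFF3
#'
#' Expects `gene` and `exon` features, with exon `Parent` naming the gene.
#'
#' @param path Path to a GFF3 file.
#' @return A [gene_annotation()] object.
#' @export
read_gff3_genes <- function(path) {
  .check(file.exists(path), paste0("GFF3 file not found: ", path))
  gr <- rtracklayer::import(path, format = "gff3")
  g <- gr[gr$type == "gene"]
  e <- gr[gr$type == "exon"]
  genes <- tibble(
    gene_id = as.character(g$ID),
    chrom = as.character(GenomicRanges::seqnames(g)),
    strand = as.character(GenomicRanges::strand(g)),
    start = as.integer(GenomicRanges::start(g) - 1L),
    end = as.integer(GenomicRanges::end(g))
  )
  parent <- vapply(as.list(e$Parent), function(p) p[[1]], "")
  exons <- tibble(
    gene_id = parent,
    chrom = as.character(GenomicRanges::seqnames(e)),
    start = as.integer(GenomicRanges::start(e) - 1L),
    end = as.integer(GenomicRanges::end(e))
  )
  gene_annotation(genes, exons)
}

#' Write a gene annotation to GFF3
#'
#' @param ann A [gene_annotation()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(ann, path) {
  g <- arrange(ann$genes, .data$chrom, .data$start, .data$gene_id)
  e <- arrange(ann$exons, .data$chrom, .data$start, .data$gene_id)
  gl <- sprintf("%s\tlncstress\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                g$chrom, g$start + 1L, g$end, g$strand, g$gene_id)
  strand_of <- setNames(g$strand, g$gene_id)
  el <- sprintf("%s\tlncstress\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                e$chrom, e$start + 1L, e$end,
                unname(strand_of[e$gene_id]), e$gene_id)
  writeLines(c("##gff-version 3", gl, el), path)
  invisible(path)
}

#' Splice transcript sequences from a genome
#'
#' Concatenates exon substrings in genomic order and reverse-complements
#' minus-strand transcripts, yielding 5'-to-3' spliced sequences.
#'
#' @param exons Per-exon tibble (see [read_gtf()]).
#' @param genome Tibble with columns `id`, `seq` (one row per chromosome).
#' @return Tibble with columns `id` (transcript id) and `seq`.
#' @export
extract_transcript_seqs <- function(exons, genome) {
  gmap <- setNames(genome$seq, genome$id)
  .check(all(exons$chrom %in% names(gmap)),
         "extract_transcript_seqs(): exon chrom absent from genome")
  ex <- arrange(exons, .data$transcript_id, .data$start)
  parts <- substring(gmap[ex$chrom], ex$start + 1L, ex$end)
  spliced <- vapply(split(parts, ex$transcript_id), paste0, "",
                    collapse = "")
  strands <- vapply(split(ex$strand, ex$transcript_id), `[[`, "", 1L)
  neg <- strands == "-"
  if (any(neg)) {
    spliced[neg] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(spliced[neg]))
    )
  }
  tibble(id = names(spliced), seq = unname(spliced))
}

#' Read a counts matrix from TSV
#'
#' @param path TSV with a `transcript_id` column followed by one column per
#'   sample.
#' @return A tibble (transcripts x samples).
#' @export
read_counts <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a sample metadata table from TSV
#'
#' @param path TSV with columns `sample_id`, `library_type`, `condition`,
#'   `stage`, `is_control`, `library_size`.
#' @return A tibble.
#' @export
read_samples <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

# internal: counts tibble -> integer matrix with transcript_id rownames
.counts_matrix <- function(counts) {
  if (is.matrix(counts)) return(counts)
  m <- as.matrix(counts[setdiff(names(counts), "transcript_id")])
  rownames(m) <- counts$transcript_id
  m
}
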