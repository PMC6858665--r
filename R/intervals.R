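#' Merge genomic intervals into a disjoint sorted set
#'
#' Collapses a set of (possibly overlapping or book-ended) intervals on one
#' chromosome into the minimal disjoint sorted set covering the same bases.
#' All coordinates are 0-based half-open, the single internal convention of
#' the package; conversion from 1-based formats happens only in readers.
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open). All rows must share one chromosome.
#' @return A tibble with columns `chrom`, `start`, `end`, pairwise disjoint
#'   and sorted by `start`.
#' @examples
#' merge_intervals(tibble::tibble(chrom = "chr1",
#'                                start = c(0, 200), end = c(300, 500)))
#' @export
merge_intervals <- function(intervals) {
  .check_intervals(intervals)
  if (nrow(intervals) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  .check(length(unique(intervals$chrom)) == 1L,
         "merge_intervals(): all intervals must be on one chromosome")
  red <- IRanges::reduce(.as_iranges(intervals))
  .from_iranges(red, chrom = intervals$chrom[[1]])
}

#' Count bases shared by two interval sets
#'
#' Returns the number of bases in the intersection of the per-base unions of
#' two interval sets on the same chromosome. Strand is ignored, matching
#' orientation-free repeat masking.
#'
#' @param a,b Data frames with columns `chrom`, `start`, `end` (0-based
#'   half-open), each on a single shared chromosome. Either may be empty.
#' @return Integer number of overlapping bases.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
#' b <- tibble::tibble(chrom = "chr1", start = 50, end = 150)
#' interval_overlap_bp(a, b) # 50
#' @export
interval_overlap_bp <- function(a, b) {
  .check_intervals(a, "a")
  .check_intervals(b, "b")
  if (nrow(a) == 0 || nrow(b) == 0) return(0L)
  chroms <- unique(c(a$chrom, b$chrom))
  .check(length(chroms) == 1L,
         "interval_overlap_bp(): `a` and `b` must share one chromosome")
  ia <- IRanges::reduce(.as_iranges(a))
  ib <- IRanges::reduce(.as_iranges(b))
  as.integer(sum(IRanges::width(IRanges::intersect(ia, ib))))
}

#' Transcript spans from an exon table
#'
#' Collapses a per-exon table to one row per transcript with the genomic
#' span and spliced length (sum of exon widths).
#'
#' @param exons Data frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `start`, `end` (0-based half-open), one row per exon.
#' @return A tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `start`, `end`, `length`.
#' @export
transcript_spans <- function(exons) {
  .check_intervals(exons, "exons")
  exons |>
    group_by(.data$transcript_id) |>
    summarise(
      gene_id = first(.data$gene_id),
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      length = sum(.data$end - .data$start), # before start/end collapse
      start = min(.data$start),
      end = max(.data$end),
      .groups = "drop"
    ) |>
    select("transcript_id", "gene_id", "chrom", "strand", "start", "end",
           "length")
}

# internal: gaps between sorted exons of one gene = introns (0-based half-open)
.introns_of <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  if (length(starts) < 2) {
    return(tibble(start = integer(), end = integer()))
  }
  tibble(start = ends[-length(ends)], end = starts[-1]) |>
    filter(.data$start < .data$end)
}
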