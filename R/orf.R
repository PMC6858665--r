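#' Find open reading frames in a transcript sequence
#'
#' Scans the given (annotated) strand only, in all three frames. An ORF is
#' an ATG followed by an in-frame stop codon wholly within the sequence;
#' nested starts sharing a stop are collapsed to the longest (earliest ATG
#' after the previous stop in that frame). The reported amino-acid length
#' excludes the stop codon but includes the initial methionine.
#'
#' `min_aa` only affects `orf_count` (ORFs at least that long); the longest
#' ORF is reported regardless, since the lncRNA pass/fail rule uses only
#' `longest_orf_aa`.
#'
#' @param seq Nucleotide string over `A`,`C`,`G`,`T`,`N`.
#' @param min_aa Minimum amino-acid length for an ORF to count toward
#'   `orf_count`.
#' @return A tibble with one row: `orf_count`, `longest_orf_aa`,
#'   `longest_start`, `longest_end` (0-based half-open span on the
#'   transcript, `NA` when no ORF exists).
#' @examples
#' find_orfs("ATGAAATAG") # one 2-aa ORF
#' @export
find_orfs <- function(seq, min_aa = 30L) {
  .check(is.character(seq) && length(seq) == 1L, "`seq` must be one string")
  seq <- toupper(seq)
  n <- nchar(seq)
  best_aa <- 0L; best_start <- NA_integer_; best_end <- NA_integer_
  count <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < 2L) next
    pos <- f + 3L * (seq_len(ncod) - 1L) + 1L # 1-based codon starts
    codons <- substring(seq, pos, pos + 2L)
    is_atg <- codons == "ATG"
    is_stop <- codons %in% stops
    if (!any(is_atg) || !any(is_stop)) next
    stop_idx <- which(is_stop)
    atg_idx <- which(is_atg)
    prev_stop <- 0L
    for (s in stop_idx) {
      starts <- atg_idx[atg_idx > prev_stop & atg_idx < s]
      prev_stop <- s
      if (!length(starts)) next
      a <- starts[[1]] # earliest ATG after previous stop = longest ORF
      aa <- s - a
      if (aa >= min_aa) count <- count + 1L
      if (aa > best_aa) {
        best_aa <- aa
        best_start <- pos[a] - 1L          # 0-based
        best_end <- pos[s] + 2L            # includes stop codon
      }
    }
  }
  tibble(orf_count = count, longest_orf_aa = best_aa,
         longest_start = best_start, longest_end = best_end)
}

#' Find ORFs for many transcripts
#'
#' @param seqs Tibble with columns `id` and `seq`.
#' @param min_aa Passed to [find_orfs()].
#' @return A tibble with one row per transcript: `transcript_id` plus the
#'   [find_orfs()] columns.
#' @export
find_orfs_all <- function(seqs, min_aa = 30L) {
  res <- purrr::map(seqs$seq, find_orfs, min_aa = min_aa)
  bind_cols(tibble(transcript_id = seqs$id), bind_rows(res))
}
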