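#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join bind_rows bind_cols n distinct rename pull across
#'   row_number desc if_else first count anti_join semi_join
#' @importFrom stats cor median pnorm pt phyper rnbinom rlnorm rnorm runif
#'   sd setNames var hclust cutree as.dist p.adjust chisq.test quantile
#' @importFrom utils head tail
NULL

# internal: stop unless condition holds
.check <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

# internal: validate an interval tibble (chrom, start, end[, strand])
.check_intervals <- function(x, arg = "intervals") {
  .check(is.data.frame(x), paste0("`", arg, "` must be a data frame"))
  .check(all(c("chrom", "start", "end") %in% names(x)),
         paste0("`", arg, "` needs columns chrom, start, end"))
  if (nrow(x)) {
    .check(all(!is.na(x$chrom) & nzchar(x$chrom)),
           paste0("`", arg, "`: chrom must be non-empty"))
    .check(all(x$start >= 0), paste0("`", arg, "`: start must be >= 0"))
    .check(all(x$start < x$end), paste0("`", arg, "`: need start < end"))
  }
  invisible(TRUE)
}

# internal: width of a set of (possibly overlapping) intervals after union
.union_bp <- function(x) {
  if (nrow(x) == 0) return(0L)
  sum(IRanges::width(IRanges::reduce(.as_iranges(x))))
}

# internal: interval tibble -> IRanges (0-based half-open -> 1-based closed)
.as_iranges <- function(x) {
  IRanges::IRanges(start = x$start + 1L, end = x$end)
}

# internal: IRanges -> interval tibble columns start/end (0-based half-open)
.from_iranges <- function(ir, chrom = NA_character_) {
  tibble(
    chrom = chrom,
    start = as.integer(IRanges::start(ir) - 1L),
    end   = as.integer(IRanges::end(ir))
  )
}
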