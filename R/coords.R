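#' @keywords internal
"_PACKAGE"

# Internal coordinate convention: 0-based, half-open [start, end).
# Overlap length between two half-open intervals is
#   max(0, min(e1, e2) - max(s1, s2))
# with no off-by-one corrections anywhere. GFF3/GTF I/O converts to and
# from the 1-based inclusive convention of those formats at the boundary.

STRANDS <- c("+", "-")

#' Overlap length between half-open intervals (vectorised)
#'
#' @param s1,e1 start/end of the first interval set (0-based, half-open)
#' @param s2,e2 start/end of the second interval set
#' @return integer vector of overlap lengths in nt (0 when disjoint)
#' @keywords internal
overlap_len <- function(s1, e1, s2, e2) {
  pmax(0L, as.integer(pmin(e1, e2) - pmax(s1, s2)))
}

check_interval <- function(start, end, what = "interval") {
  if (any(is.na(start)) || any(is.na(end)))
    stop(what, ": start/end must not be NA", call. = FALSE)
  if (any(start < 0)) stop(what, ": start must be >= 0", call. = FALSE)
  if (any(end <= start)) stop(what, ": end must be > start", call. = FALSE)
  invisible(TRUE)
}

check_strand <- function(strand, what = "strand") {
  if (!all(strand %in% STRANDS))
    stop(what, ": strand must be '+' or '-'", call. = FALSE)
  invisible(TRUE)
}

# GRanges view of a 0-based half-open table (chrom, start, end, strand).
# Used only for indexed overlap queries; coordinates convert as
# [start, end) -> 1-based [start + 1, end].
as_granges0 <- function(df, seqlengths = NULL) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand,
    seqlengths = seqlengths
  )
}
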