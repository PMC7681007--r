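#' Build a coverage set from genomic intervals
#'
#' Intervals (0-based half-open) are merged so the set has no self-overlap.
#' Accepts a data.frame with `chrom`, `start`, `end` columns, a `GRanges`, or
#' a path to a BED file.
#'
#' @param x intervals as described above.
#' @return a `GRanges` with reduced (merged) ranges, class-tagged
#'   `siq_coverage` in its metadata.
#' @export
coverage_set <- function(x) {
  gr <- if (methods::is(x, "GRanges")) {
    x
  } else if (is.character(x) && length(x) == 1L) {
    rtracklayer::import(x, format = "bed")
  } else if (is.data.frame(x)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(x)),
              all(x$end > x$start))
    GenomicRanges::GRanges(x$chrom,
                           IRanges::IRanges(start = x$start + 1, end = x$end))
  } else {
    stop("cannot interpret coverage input")
  }
  GenomicRanges::reduce(gr)
}

# bins (0-based ids, unique per genome) touched by a coverage set
.bin_ids <- function(gr, genome, bin_width) {
  offsets <- c(0, cumsum(ceiling(genome / bin_width)))
  names(offsets) <- c(names(genome), "..end")
  ids <- integer(0)
  for (chr in names(genome)) {
    sel <- as.character(GenomicRanges::seqnames(gr)) == chr
    if (!any(sel)) next
    st <- GenomicRanges::start(gr[sel]) - 1L   # back to 0-based
    en <- GenomicRanges::end(gr[sel])          # half-open end
    n_bins <- ceiling(genome[[chr]] / bin_width)
    from <- pmax(st %/% bin_width, 0)
    to <- pmin((en - 1) %/% bin_width, n_bins - 1)
    keep <- from <= to
    ids <- c(ids, unlist(mapply(seq, from[keep], to[keep],
                                SIMPLIFY = FALSE), use.names = FALSE) +
               offsets[[chr]])
  }
  unique(as.integer(ids))
}

#' Overlap of two coverage sets with hypergeometric significance
#'
#' Both sets are reduced to indicator sets over genome bins of width
#' `bin_width` (a bin is in a set if any interval touches it), making the
#' hypergeometric urn model exact: drawing `|B|` bins from `N` with `|A|`
#' marked, the observed overlap is compared against its expectation
#' `|A||B|/N` and the upper tail `P(X >= observed)` is computed.
#'
#' @param a,b coverage sets (anything [coverage_set()] accepts).
#' @param genome named vector of chromosome sizes (bp) defining the bin
#'   universe.
#' @param bin_width bin width in bp (conventionally the track interval
#'   width).
#' @return a list: `observed`, `expected`, `fold` (observed/expected, `NA`
#'   when a set is empty), `p` (hypergeometric upper tail), plus `n_a`,
#'   `n_b`, `universe`.
#' @export
overlap_stats <- function(a, b, genome, bin_width) {
  stopifnot(is.numeric(genome), !is.null(names(genome)), bin_width > 0)
  A <- .bin_ids(coverage_set(a), genome, bin_width)
  B <- .bin_ids(coverage_set(b), genome, bin_width)
  N <- sum(ceiling(genome / bin_width))
  obs <- length(intersect(A, B))
  if (length(A) == 0L || length(B) == 0L) {
    return(list(observed = obs, expected = 0, fold = NA_real_, p = NA_real_,
                n_a = length(A), n_b = length(B), universe = N))
  }
  expected <- length(A) * length(B) / N
  p <- stats::phyper(obs - 1L, length(A), N - length(A), length(B),
                     lower.tail = FALSE)
  list(observed = obs, expected = expected, fold = obs / expected, p = p,
       n_a = length(A), n_b = length(B), universe = N)
}
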