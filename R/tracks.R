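#' Read paired-end fragments from a BED-like file
#'
#' Expects at least three tab-separated columns (chrom, start, end) in
#' 0-based half-open coordinates; fragment length is `end - start`. Lines
#' with `end <= start` are rejected (counted, not fatal); non-numeric
#' coordinates are an error naming the first offending line. For single-end
#' data supply `fixed_length` to assign all fragments one length.
#'
#' @param path BED-like text file.
#' @param fixed_length optional constant fragment length (bp) overriding
#'   `end - start` (single-end workflows).
#' @return a `siq_fragments` data.table with columns `chrom`, `start`,
#'   `length`; `attr(, "n_rejected")` counts dropped lines.
#' @export
read_fragments <- function(path, fixed_length = NULL) {
  if (!file.exists(path)) stop("no such fragment file: ", path)
  if (file.size(path) == 0L) {
    warning("empty fragment file: ", path)
    return(fragment_set(character(), integer(), integer()))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          fill = TRUE, colClasses = list(character = 1))
  if (ncol(dt) < 3L) stop("need >= 3 tab-separated columns in ", path)
  st <- suppressWarnings(as.numeric(dt[[2L]]))
  en <- suppressWarnings(as.numeric(dt[[3L]]))
  bad <- which(!is.finite(st) | !is.finite(en))
  if (length(bad)) {
    stop("malformed line ", bad[1L], " in ", path,
         ": non-numeric start/end")
  }
  if (any(st < 0)) {
    stop("malformed line ", which(st < 0)[1L], " in ", path,
         ": negative start")
  }
  keep <- en > st
  n_rej <- sum(!keep)
  if (n_rej > 0) {
    warning(n_rej, " line(s) with end <= start rejected in ", path)
  }
  len <- if (is.null(fixed_length)) en - st else rep(fixed_length, length(st))
  fragment_set(dt[[1L]][keep], st[keep], len[keep], n_rejected = n_rej)
}

#' Construct a fragment set in memory
#'
#' @param chrom,start,length parallel vectors (start 0-based, length in bp).
#' @param n_rejected bookkeeping count of rejected source lines.
#' @return a `siq_fragments` data.table.
#' @export
fragment_set <- function(chrom, start, length, n_rejected = 0L) {
  stopifnot(all(start >= 0), all(length > 0))
  dt <- data.table::data.table(chrom = as.character(chrom),
                               start = as.integer(start),
                               length = as.integer(length))
  data.table::setattr(dt, "n_rejected", as.integer(n_rejected))
  data.table::setattr(dt, "class", c("siq_fragments", class(dt)))
  dt
}

#' Write a fragment set as BED3
#'
#' @param frags a `siq_fragments`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(frags, path) {
  out <- data.table::data.table(frags$chrom, frags$start,
                                frags$start + frags$length)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Mean sequenced fragment length
#'
#' The average length `<L>` used to convert per-base efficiency into
#' per-fragment units.
#'
#' @param frags a `siq_fragments`.
#' @return mean length in bp.
#' @export
mean_fragment_length <- function(frags) {
  if (nrow(frags) == 0L) stop("cannot take <L> of an empty fragment set")
  mean(frags$length)
}

#' Bin fragments over (genomic interval, fragment length)
#'
#' A fragment is assigned by its start only: x-bin
#' `floor(start / interval_width)` on its chromosome, and L-bin
#' `floor(length / length_bin_width)`. Total count is conserved.
#'
#' @param frags a `siq_fragments`.
#' @param interval_width genomic interval width (bp).
#' @param length_bin_width fragment-length bin width (bp), default 10.
#' @return a `siq_track2d`: data.table of `(chrom, xbin, lbin, count)` with
#'   widths and the fragment total in attributes.
#' @export
bin2d <- function(frags, interval_width, length_bin_width = 10) {
  stopifnot(interval_width > 0, length_bin_width > 0)
  if (nrow(frags) == 0L) {
    dt <- data.table::data.table(chrom = character(), xbin = integer(),
                                 lbin = integer(), count = integer())
  } else {
    dt <- data.table::data.table(
      chrom = frags$chrom,
      xbin = as.integer(frags$start %/% interval_width),
      lbin = as.integer(frags$length %/% length_bin_width))
    dt <- dt[, list(count = .N), by = c("chrom", "xbin", "lbin")]
    data.table::setkeyv(dt, c("chrom", "xbin", "lbin"))
  }
  structure(dt, interval_width = interval_width,
            length_bin_width = length_bin_width,
            n_fragments = if (nrow(frags)) nrow(frags) else 0L,
            class = c("siq_track2d", class(data.table::data.table())))
}

.check_same_geometry <- function(a, b) {
  if (attr(a, "interval_width") != attr(b, "interval_width") ||
      !identical(attr(a, "length_bin_width"), attr(b, "length_bin_width"))) {
    stop("geometry mismatch: tracks were binned at different widths")
  }
  invisible(TRUE)
}

#' Two-dimensional siQ-ChIP efficiency
#'
#' `e(x, L) = alpha * IP(x, L) / input(x, L)` over the union of occupied
#' bins (the chromosome universe is the union of chromosomes seen in either
#' sample; bins absent from one sample count 0). Bins where either sample has
#' no fragments are evaluated to zero; bins with IP coverage but no input
#' coverage are additionally flagged, since they are the symptom of a
#' too-small interval width.
#'
#' @param ip,input `siq_track2d` count tracks with identical geometry.
#' @param alpha a `siq_alpha` or a bare numeric alpha.
#' @return a `siq_eff2d` data.table with columns `chrom, xbin, lbin, ip,
#'   input, value, flag`.
#' @export
efficiency2d <- function(ip, input, alpha) {
  .check_same_geometry(ip, input)
  a <- if (inherits(alpha, "siq_alpha")) alpha$alpha else as.numeric(alpha)
  stopifnot(is.finite(a), a > 0)
  ipd <- data.table::copy(data.table::as.data.table(ip))
  ind <- data.table::copy(data.table::as.data.table(input))
  data.table::setnames(ipd, "count", "ip")
  data.table::setnames(ind, "count", "input")
  m <- merge(ipd, ind, by = c("chrom", "xbin", "lbin"), all = TRUE)
  m[is.na(m$ip), "ip"] <- 0L
  m[is.na(m$input), "input"] <- 0L
  m$value <- ifelse(m$ip > 0L & m$input > 0L, a * m$ip / m$input, 0)
  m$flag <- m$ip > 0L & m$input == 0L
  structure(m, interval_width = attr(ip, "interval_width"),
            length_bin_width = attr(ip, "length_bin_width"),
            alpha = a,
            class = c("siq_eff2d", class(data.table::data.table())))
}

#' Project a 2D efficiency onto the genome axis
#'
#' Collapses the fragment-length axis by the input-count-weighted mean of
#' `e(x, L)` over L-bins, yielding the browser-ready per-base efficiency
#' `e(x)`; the weighted mean preserves the per-base interpretation and
#' reduces to the scalar IP/input ratio when L is constant. The per-fragment
#' variant multiplies by the mean fragment length `<L>` (conventionally taken
#' from the IP fragment set, whose capture is being reported).
#'
#' @param e2d a `siq_eff2d`.
#' @param mean_length `<L>` in bp; required for `unit = "per-fragment"` and
#'   recorded on the track either way when given.
#' @param unit `"per-base"` (default) or `"per-fragment"`.
#' @return a `siq_track`: data.table `(chrom, xbin, value, flag)` with
#'   interval width, unit and `<L>` in attributes. `flag` marks bins all of
#'   whose IP coverage fell where input had none.
#' @export
project1d <- function(e2d, mean_length = NULL,
                      unit = c("per-base", "per-fragment")) {
  unit <- match.arg(unit)
  stopifnot(inherits(e2d, "siq_eff2d"))
  if (unit == "per-fragment" && is.null(mean_length)) {
    stop("per-fragment units need mean_length (<L>)")
  }
  dt <- data.table::as.data.table(e2d)
  if (nrow(dt) == 0L) {
    out <- data.table::data.table(chrom = character(), xbin = integer(),
                                  value = numeric(), flag = logical())
  } else {
    out <- dt[, list(
      value = if (sum(input) > 0) sum(value * input) / sum(input) else 0,
      flag = sum(input) == 0L && sum(ip) > 0L),
      by = c("chrom", "xbin")]
    data.table::setkeyv(out, c("chrom", "xbin"))
  }
  if (unit == "per-fragment") out$value <- out$value * mean_length
  structure(out, interval_width = attr(e2d, "interval_width"),
            unit = unit, mean_length = mean_length,
            class = c("siq_track", class(data.table::data.table())))
}

#' Convert a per-base efficiency track to per-fragment units
#'
#' Multiplies bin-wise by `<L>`.
#'
#' @param track a per-base `siq_track`.
#' @param mean_length `<L>` in bp.
#' @return a per-fragment `siq_track`.
#' @export
track_per_fragment <- function(track, mean_length) {
  stopifnot(inherits(track, "siq_track"), is.numeric(mean_length),
            mean_length > 0)
  if (!identical(attr(track, "unit"), "per-base")) {
    stop("track is not in per-base units")
  }
  out <- data.table::copy(track)
  out$value <- out$value * mean_length
  data.table::setattr(out, "unit", "per-fragment")
  data.table::setattr(out, "mean_length", mean_length)
  out
}

#' Build the 1D siQ-ChIP efficiency track from fragment sets
#'
#' Convenience wrapper: [bin2d()] both samples, [efficiency2d()], then
#' [project1d()].
#'
#' @param ip,input `siq_fragments`.
#' @param alpha `siq_alpha` or numeric.
#' @param interval_width,length_bin_width binning widths (bp).
#' @param unit `"per-base"` or `"per-fragment"`.
#' @return a `siq_track`.
#' @export
efficiency_track <- function(ip, input, alpha, interval_width,
                             length_bin_width = 10,
                             unit = c("per-base", "per-fragment")) {
  unit <- match.arg(unit)
  e2 <- efficiency2d(bin2d(ip, interval_width, length_bin_width),
                     bin2d(input, interval_width, length_bin_width),
                     alpha)
  project1d(e2, mean_length = mean_fragment_length(ip), unit = unit)
}

#' Choose an interval width at which the track stops changing
#'
#' Interval widths that are too small leave many bins where IP and input do
#' not both have coverage; those bins are evaluated to zero and signal that
#' the width should grow. The width is increased along `widths` until the 1D
#' track no longer depends on it: consecutive tracks are compared after
#' aggregating the finer onto the coarser grid (input-weighted mean), and the
#' smallest width whose mean absolute relative difference to the next width
#' is at most `tol` is chosen.
#'
#' @param ip,input `siq_fragments`.
#' @param alpha `siq_alpha` or numeric.
#' @param widths increasing vector of candidate interval widths (bp), at
#'   least two; default `c(1, 2, 5, 10, 20, 50) * 1000`.
#' @param tol convergence tolerance on the dissimilarity (default 0.05).
#' @param length_bin_width passed to [bin2d()].
#' @return a list: `width` (chosen), `converged` (FALSE means no width met
#'   `tol` and the largest was returned), and `diagnostics`, a data.frame of
#'   per-width zero-bin fraction and consecutive dissimilarity.
#' @export
stabilize_width <- function(ip, input, alpha,
                            widths = c(1, 2, 5, 10, 20, 50) * 1000,
                            tol = 0.05, length_bin_width = 10) {
  stopifnot(length(widths) >= 2L, all(diff(widths) > 0))
  tracks <- vector("list", length(widths))
  frac_zero <- numeric(length(widths))
  for (i in seq_along(widths)) {
    e2 <- efficiency2d(bin2d(ip, widths[i], length_bin_width),
                       bin2d(input, widths[i], length_bin_width), alpha)
    tr <- project1d(e2)
    # also weight by input coverage for aggregation across widths
    cov <- data.table::as.data.table(e2)[, list(input = sum(input)),
                                         by = c("chrom", "xbin")]
    tr <- merge(tr, cov, by = c("chrom", "xbin"))
    tracks[[i]] <- tr
    frac_zero[i] <- mean(tr$value == 0)
  }
  dissim <- rep(NA_real_, length(widths))
  for (i in seq_len(length(widths) - 1L)) {
    fine <- tracks[[i]]; coarse <- tracks[[i + 1L]]
    agg <- fine[, list(value = sum(value * input) / max(sum(input), 1L)),
                by = list(chrom,
                          xbin = as.integer(xbin * widths[i] %/% widths[i + 1L]))]
    cmp <- merge(agg, coarse[, c("chrom", "xbin", "value")],
                 by = c("chrom", "xbin"), suffixes = c(".fine", ".coarse"))
    both <- cmp$value.fine > 0 & cmp$value.coarse > 0
    dissim[i] <- if (any(both)) {
      mean(abs(cmp$value.fine[both] - cmp$value.coarse[both]) /
             ((cmp$value.fine[both] + cmp$value.coarse[both]) / 2))
    } else Inf
  }
  ok <- which(dissim <= tol)
  diagnostics <- data.frame(width = widths, frac_zero = frac_zero,
                            dissimilarity_to_next = dissim)
  if (length(ok)) {
    list(width = widths[min(ok)], converged = TRUE, diagnostics = diagnostics)
  } else {
    list(width = widths[length(widths)], converged = FALSE,
         diagnostics = diagnostics)
  }
}

#' Differential efficiency ratio between two conditions
#'
#' Bin-wise `treatment / control` wherever both efficiencies are positive;
#' bins where either is zero are emitted as missing (`NA`), not 0 and not
#' infinity, so genome browsers do not render false depletion.
#'
#' @param treatment,control `siq_track`s on the same binning and unit.
#' @return a `siq_track` of ratios (unit `"ratio"`), `NA` where undefined.
#' @export
differential <- function(treatment, control) {
  stopifnot(inherits(treatment, "siq_track"), inherits(control, "siq_track"))
  if (attr(treatment, "interval_width") != attr(control, "interval_width")) {
    stop("geometry mismatch: tracks have different interval widths")
  }
  if (!identical(attr(treatment, "unit"), attr(control, "unit"))) {
    stop("unit mismatch between treatment and control tracks")
  }
  a <- data.table::as.data.table(treatment)[, c("chrom", "xbin", "value")]
  b <- data.table::as.data.table(control)[, c("chrom", "xbin", "value")]
  m <- merge(a, b, by = c("chrom", "xbin"), all = TRUE,
             suffixes = c(".t", ".c"))
  m$value <- ifelse(!is.na(m$value.t) & !is.na(m$value.c) &
                      m$value.t > 0 & m$value.c > 0,
                    m$value.t / m$value.c, NA_real_)
  out <- m[, c("chrom", "xbin", "value")]
  structure(out, interval_width = attr(treatment, "interval_width"),
            unit = "ratio", mean_length = NULL,
            class = c("siq_track", class(data.table::data.table())))
}

#' Write a 1D track as bedGraph
#'
#' Standard 4-column bedGraph (chrom, start, end, value) in 0-based
#' half-open coordinates, via `rtracklayer`. Missing (`NA`) bins are
#' omitted.
#'
#' @param track a `siq_track`.
#' @param path output path (`.bedGraph`).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "siq_track"))
  w <- attr(track, "interval_width")
  dt <- data.table::as.data.table(track)
  dt <- dt[!is.na(dt$value), ]
  gr <- GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$xbin * w + 1, width = w),
    score = dt$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph written by [write_bedgraph()] back into a track
#'
#' @param path bedGraph file.
#' @param interval_width the bin width the file was written at (bp).
#' @param unit unit tag to restore.
#' @return a `siq_track`.
#' @export
read_bedgraph <- function(path, interval_width, unit = "per-base") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    xbin = as.integer(GenomicRanges::start(gr) %/% interval_width),
    value = gr$score)
  data.table::setkeyv(out, c("chrom", "xbin"))
  structure(out, interval_width = interval_width, unit = unit,
            mean_length = NULL,
            class = c("siq_track", class(data.table::data.table())))
}

#' @export
print.siq_track <- function(x, ...) {
  cat(sprintf("siQ-ChIP track: %d bins, interval width %g bp, units %s\n",
              nrow(x), attr(x, "interval_width"), attr(x, "unit")))
  if (!is.null(attr(x, "mean_length"))) {
    cat(sprintf("  <L> = %.2f bp\n", attr(x, "mean_length")))
  }
  print(data.table::as.data.table(utils::head(as.data.frame(x), 6)))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
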