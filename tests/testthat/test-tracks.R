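frag_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".bed",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("fragment files are parsed with coordinate arithmetic and line-level errors", {
  f <- frag_file("chr1\t100\t250")
  fr <- read_fragments(f)
  expect_equal(nrow(fr), 1)
  expect_equal(fr$chrom, "chr1")
  expect_equal(fr$start, 100L)
  expect_equal(fr$length, 150L)

  empty <- frag_file(character())
  expect_warning(fr0 <- read_fragments(empty), "empty")
  expect_equal(nrow(fr0), 0)

  inverted <- frag_file(c("chr1\t10\t20", "chr1\t30\t30", "chr1\t50\t40"))
  expect_warning(fr1 <- read_fragments(inverted), "2 line")
  expect_equal(nrow(fr1), 1)
  expect_equal(attr(fr1, "n_rejected"), 2L)

  bad <- frag_file(c("chr1\t10\t20", "chr1\toops\t30"))
  expect_error(read_fragments(bad), "line 2")
})

test_that("single-end data takes a constant user-supplied length", {
  f <- frag_file(c("chr1\t100\t101", "chr1\t500\t501"))
  fr <- read_fragments(f, fixed_length = 200)
  expect_equal(fr$length, c(200L, 200L))
})

test_that("2D binning uses floor arithmetic on start and length", {
  fr <- fragment_set("chr1", 100, 150)
  t2 <- bin2d(fr, interval_width = 1000, length_bin_width = 50)
  expect_equal(as.data.frame(t2),
               data.frame(chrom = "chr1", xbin = 0L, lbin = 3L, count = 1L),
               ignore_attr = TRUE)
})

test_that("binning and rebinning conserve fragment counts", {
  set.seed(11)
  n <- 1e4
  fr <- fragment_set(sample(c("chr1", "chr2"), n, replace = TRUE),
                     sample.int(1e6, n, replace = TRUE) - 1L,
                     sample(50:500, n, replace = TRUE))
  for (w in c(1000, 2000, 7777)) {
    t2 <- bin2d(fr, w, 10)
    expect_equal(sum(t2$count), n)
  }
  # rebinning at 2x interval width merges adjacent x-bin pairs
  fine <- as.data.frame(bin2d(fr, 1000, 10))
  coarse <- as.data.frame(bin2d(fr, 2000, 10))
  fine$xbin <- fine$xbin %/% 2L
  agg <- aggregate(count ~ chrom + xbin + lbin, fine, sum)
  m <- merge(agg, coarse, by = c("chrom", "xbin", "lbin"))
  expect_equal(nrow(m), nrow(coarse))
  expect_equal(m$count.x, m$count.y)
  # marginal over L equals an independent 1D start histogram
  marg <- aggregate(count ~ chrom + xbin, as.data.frame(bin2d(fr, 1000, 10)),
                    sum)
  ref <- as.data.frame(table(chrom = fr$chrom, xbin = fr$start %/% 1000),
                       stringsAsFactors = FALSE)
  ref <- ref[ref$Freq > 0, ]
  ref$xbin <- as.integer(ref$xbin)
  m2 <- merge(marg, ref, by = c("chrom", "xbin"))
  expect_equal(nrow(m2), nrow(marg))
  expect_equal(m2$count, m2$Freq)
})

test_that("2D efficiency is alpha * IP/input with the zero rule and flags", {
  fr <- fragment_set(rep("chr1", 4), c(0, 0, 1000, 2000), rep(150, 4))
  ipt <- bin2d(fr, 1000, 10)
  # identical tracks at alpha 1 give efficiency 1 wherever occupied
  e <- efficiency2d(ipt, ipt, 1)
  expect_true(all(e$value == 1))
  expect_false(any(e$flag))

  ip2 <- bin2d(fragment_set("chr1", 500, 150), 1000, 10)      # ip only
  in2 <- bin2d(fragment_set("chr1", 1500, 150), 1000, 10)     # input only
  e2 <- efficiency2d(ip2, in2, 1)
  expect_true(all(e2$value == 0))
  expect_identical(e2$flag, e2$ip > 0 & e2$input == 0)
  expect_true(any(e2$flag))

  ip4 <- bin2d(fragment_set(rep("chr1", 4), rep(10, 4), rep(100, 4)), 1000, 10)
  in8 <- bin2d(fragment_set(rep("chr1", 8), rep(20, 8), rep(100, 8)), 1000, 10)
  expect_equal(efficiency2d(ip4, in8, 0.5)$value, 0.25)

  expect_error(efficiency2d(bin2d(fr, 1000, 10), bin2d(fr, 2000, 10), 1),
               "geometry")
})

test_that("efficiency is linear in alpha and zero exactly where a sample is empty", {
  set.seed(3)
  mk <- function(n) fragment_set(sample(c("chr1", "chr2"), n, TRUE),
                                 sample.int(5e4, n, TRUE) - 1L,
                                 sample(80:300, n, TRUE))
  ipt <- bin2d(mk(400), 5000, 25)
  int <- bin2d(mk(500), 5000, 25)
  e1 <- efficiency2d(ipt, int, 0.37)
  e2 <- efficiency2d(ipt, int, 0.74)
  expect_equal(e2$value, 2 * e1$value)
  expect_identical(e1$value == 0, e1$ip == 0 | e1$input == 0)
})

test_that("projection collapses L by the input-weighted mean", {
  # two L-bins with values (0.2, 0.6) and input weights (3, 1) -> 0.3
  e2d <- structure(
    data.table::data.table(chrom = "chr1", xbin = 0L, lbin = c(10L, 12L),
                           ip = c(6L, 6L), input = c(3L, 1L),
                           value = c(0.2, 0.6), flag = FALSE),
    interval_width = 1000, length_bin_width = 10, alpha = 0.1,
    class = c("siq_eff2d", class(data.table::data.table())))
  tr <- project1d(e2d)
  expect_equal(tr$value, 0.3)

  # constant value across L-bins is preserved regardless of weights
  e2d$value <- 0.4
  expect_equal(project1d(e2d)$value, 0.4)

  # single occupied L-bin passes through
  one <- structure(
    data.table::data.table(chrom = "chr1", xbin = 0L, lbin = 10L,
                           ip = 6L, input = 3L, value = 0.4, flag = FALSE),
    interval_width = 1000, length_bin_width = 10, alpha = 0.1,
    class = c("siq_eff2d", class(data.table::data.table())))
  expect_equal(project1d(one)$value, 0.4)
})

test_that("per-fragment track is <L> times the per-base track on every bin", {
  set.seed(5)
  mk <- function(n) fragment_set("chr1", sample.int(4e4, n, TRUE) - 1L,
                                 sample(80:300, n, TRUE))
  ip <- mk(600); input <- mk(700)
  per_base <- efficiency_track(ip, input, 0.2, 2000)
  L <- mean_fragment_length(ip)
  per_frag <- track_per_fragment(per_base, L)
  expect_equal(per_frag$value, per_base$value * L)
  expect_identical(attr(per_frag, "unit"), "per-fragment")
  direct <- efficiency_track(ip, input, 0.2, 2000, unit = "per-fragment")
  expect_equal(direct$value, per_frag$value)
})

test_that("duplicating every record leaves the efficiency unchanged", {
  # sequencer-specific constants multiply both samples and must cancel
  set.seed(6)
  mk <- function(n) fragment_set("chr1", sample.int(4e4, n, TRUE) - 1L,
                                 sample(80:300, n, TRUE))
  ip <- mk(500); input <- mk(400)
  dup <- function(fr) fragment_set(rep(fr$chrom, 3), rep(fr$start, 3),
                                   rep(fr$length, 3))
  t1 <- efficiency_track(ip, input, 0.3, 2000)
  t3 <- efficiency_track(dup(ip), dup(input), 0.3, 2000)
  expect_equal(as.data.frame(t3)[, c("chrom", "xbin", "value")],
               as.data.frame(t1)[, c("chrom", "xbin", "value")])
})

test_that("differential ratio is missing, not zero, where either condition is empty", {
  mk_track <- function(xbin, value) {
    structure(data.table::data.table(chrom = "chr1", xbin = as.integer(xbin),
                                     value = value, flag = FALSE),
              interval_width = 1000, unit = "per-base", mean_length = NULL,
              class = c("siq_track", class(data.table::data.table())))
  }
  a <- mk_track(0:3, c(0.2, 0.4, 0, 0.8))
  d_same <- differential(a, a)
  expect_equal(d_same$value, c(1, 1, NA, 1))
  b <- mk_track(0:2, c(0.1, 0.2, 0.5))
  d <- differential(a, b)
  expect_equal(d$value, c(2, 2, NA, NA))   # control 0 and control absent
  expect_error(differential(a, mk_track(0, 1)), NA)
  wrong <- mk_track(0, 1); data.table::setattr(wrong, "interval_width", 500)
  expect_error(differential(a, wrong), "geometry")
})

test_that("bedGraph output is 0-based half-open and round-trips", {
  tr <- structure(data.table::data.table(chrom = "chr1", xbin = 0L,
                                         value = 0.25, flag = FALSE),
                  interval_width = 1000, unit = "per-base", mean_length = NULL,
                  class = c("siq_track", class(data.table::data.table())))
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, path)
  line <- grep("^chr", readLines(path), value = TRUE)
  expect_equal(strsplit(line, "\t")[[1]], c("chr1", "0", "1000", "0.25"))

  set.seed(8)
  big <- structure(
    data.table::data.table(chrom = rep(c("chr1", "chr2"), each = 20),
                           xbin = rep(0:19, 2),
                           value = round(runif(40), 6), flag = FALSE),
    interval_width = 1000, unit = "per-base", mean_length = NULL,
    class = c("siq_track", class(data.table::data.table())))
  p2 <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(big, p2)
  back <- read_bedgraph(p2, 1000)
  expect_equal(back$value, big$value, tolerance = 1e-6)
  expect_equal(back$chrom, big$chrom)
  expect_equal(back$xbin, big$xbin)
  # write -> read -> write is idempotent
  p3 <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(back, p3)
  expect_identical(readLines(p3), readLines(p2))
})

test_that("width stabilization accepts small widths for deep uniform coverage", {
  set.seed(9)
  n <- 2e4
  mk <- function() fragment_set("chr1", sample.int(1e5, n, TRUE) - 1L,
                                sample(100:200, n, TRUE))
  res <- stabilize_width(mk(), mk(), 1, widths = c(1000, 2000, 5000),
                         tol = 0.2)
  expect_true(res$converged)
  expect_equal(res$width, 1000)
  expect_equal(nrow(res$diagnostics), 3)
})

test_that("zero-bin fraction shrinks with width on sparse data", {
  set.seed(10)
  mk <- function(n) fragment_set("chr1", sample.int(1e6, n, TRUE) - 1L,
                                 sample(100:200, n, TRUE))
  res <- stabilize_width(mk(300), mk(300), 1,
                         widths = c(1000, 5000, 20000, 100000), tol = 0.05)
  fz <- res$diagnostics$frac_zero
  expect_true(all(diff(fz) <= 0))
  expect_gt(fz[1], fz[length(fz)])
})

test_that("stabilization converges at or below the scale of real structure", {
  # block structure: efficiency flat on 50-kb blocks
  set.seed(12)
  block <- 50000
  starts_in <- sample.int(1e6, 3e4, TRUE) - 1L
  keep_hi <- (starts_in %/% block) %% 2 == 0
  # IP keeps all fragments in even blocks, a third of those in odd blocks
  pick <- keep_hi | (runif(length(starts_in)) < 1/3)
  starts_ip <- starts_in[pick]
  ip <- fragment_set("chr1", starts_ip,
                     sample(100:200, length(starts_ip), TRUE))
  input <- fragment_set("chr1", starts_in,
                        sample(100:200, length(starts_in), TRUE))
  res <- stabilize_width(ip, input, 1,
                         widths = c(2000, 10000, 50000, 200000), tol = 0.1)
  expect_true(res$converged)
  expect_lte(res$width, block)
})
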