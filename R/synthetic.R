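#' Lay out a toy genome as genomic intervals
#'
#' @param sizes named vector of chromosome sizes in bp (default two 1-Mb
#'   chromosomes).
#' @param interval_width interval (bin) width in bp (default 10 kb).
#' @return a data.frame with one row per interval: `chrom`, `xbin`
#'   (0-based within chromosome), `start` (0-based) and `width`.
#' @export
toy_genome <- function(sizes = c(chrA = 1e6, chrB = 1e6),
                       interval_width = 10000) {
  stopifnot(!is.null(names(sizes)), all(sizes > 0), interval_width > 0)
  out <- do.call(rbind, lapply(names(sizes), function(chr) {
    nb <- ceiling(sizes[[chr]] / interval_width)
    data.frame(chrom = chr, xbin = seq_len(nb) - 1L,
               start = (seq_len(nb) - 1L) * interval_width,
               width = pmin(interval_width,
                            sizes[[chr]] - (seq_len(nb) - 1L) * interval_width))
  }))
  attr(out, "sizes") <- sizes
  attr(out, "interval_width") <- interval_width
  out
}

#' Expected fragments of a species on one interval
#'
#' If an antibody captured `n_bound` fragments of a species and a fraction
#' `o` of that species' fragments start in the interval, on average
#' `n_bound * o` of the captured fragments fall there.
#'
#' @param n_bound bound fragment count for the species.
#' @param o the species' normalized occupancy of the interval, `o_i(x)`.
#' @return expected fragment count on the interval.
#' @export
#' @examples
#' expected_bound_fragments(100, 0.02)  # 2
expected_bound_fragments <- function(n_bound, o) {
  stopifnot(n_bound >= 0, all(o >= 0), all(o <= 1))
  n_bound * o
}

# draw fragment lengths from a truncated, rounded Gaussian
.draw_lengths <- function(n, mean, sd, range) {
  out <- integer(0)
  while (length(out) < n) {
    cand <- as.integer(round(stats::rnorm(n - length(out) + 16L, mean, sd)))
    out <- c(out, cand[cand >= range[1] & cand <= range[2]])
  }
  out[seq_len(n)]
}

# fragments for per-bin counts: uniform starts within each interval
.place_fragments <- function(bin_counts, genome, len_mean, len_sd, len_range) {
  iw <- attr(genome, "interval_width")
  n <- sum(bin_counts)
  idx <- rep.int(seq_len(nrow(genome)), bin_counts)
  offs <- floor(stats::runif(n) * genome$width[idx])
  fragment_set(genome$chrom[idx],
               genome$start[idx] + offs,
               .draw_lengths(n, len_mean, len_sd, len_range))
}

#' Generate a ground-truth synthetic ChIP-seq experiment
#'
#' Simulates the full siQ-ChIP data-generating process on a toy genome:
#' the competitive IP is solved at equilibrium with [solve_binding()], input
#' fragments are drawn per species proportional to total concentrations and
#' placed along each species' genomic distribution `o_i(x)`, IP fragments
#' are drawn proportional to the equilibrium bound concentrations, fragment
#' lengths follow a discrete Gaussian (default mean 150 bp, sd 20, truncated
#' to \[50, 500\]), and a bench manifest is fabricated whose alpha equals the
#' ledger's true value, so the whole track pipeline can be validated against
#' known expectations.
#'
#' Counts stand in for concentrations through a fixed arbitrary
#' `(V - v_in) N_A` scale: only the fractions `S_i^t / sum S^t` and
#' `S_i^b / sum S^b` drive sampling, so the true alpha is
#' `(depth_input / depth_ip) * (sum S^b / sum S^t)`.
#'
#' @param rx a [reaction()] describing the chromatin and antibody load.
#' @param distributions matrix of `o_i(x)`: one row per species (rownames =
#'   species names), one column per interval of `genome`; rows sum to 1.
#' @param genome a [toy_genome()].
#' @param depth_ip,depth_input fragments to sample for each file.
#' @param length_mean,length_sd,length_range fragment-length model (bp).
#' @param seed integer seed; the same seed reproduces the experiment
#'   byte-identically.
#' @return an object of class `siq_synthetic`: `ip` and `input`
#'   (`siq_fragments`), `manifest` (list of `ip`, `input`, `volumes`), and
#'   `ledger` -- seed, solved reaction (with per-species bound counts),
#'   true `alpha`, per-interval expected efficiency and expected IP/input
#'   sampling probabilities, drawn per-species counts, total fragment
#'   lengths, and the length-model parameters.
#' @export
generate_experiment <- function(rx, distributions, genome,
                                depth_ip = 1e4, depth_input = 1e4,
                                length_mean = 150, length_sd = 20,
                                length_range = c(50, 500),
                                seed = 1L) {
  stopifnot(inherits(rx, "siq_reaction"), is.matrix(distributions),
            !is.null(rownames(distributions)),
            ncol(distributions) == nrow(genome))
  sp_names <- rx$species$name
  o <- distributions[match(sp_names, rownames(distributions)), , drop = FALSE]
  if (anyNA(o)) stop("every species needs a distribution row")
  if (any(abs(rowSums(o) - 1) > 1e-8)) stop("each o_i(x) must sum to 1")
  set.seed(seed)
  sol <- solve_binding(rx)
  totals <- sol$species$total
  bound <- sol$species$bound
  if (sum(totals) <= 0) stop("infeasible scenario: no chromatin")
  if (sum(bound) <= 0) stop("infeasible scenario: nothing binds in the IP")

  # species draws, then per-bin placement along o_i
  n_t <- as.vector(stats::rmultinom(1, depth_input, totals / sum(totals)))
  n_b <- as.vector(stats::rmultinom(1, depth_ip, bound / sum(bound)))
  bins_for <- function(counts) {
    tot <- rep(0L, nrow(genome))
    for (i in seq_along(counts)) {
      if (counts[i] > 0) {
        tot <- tot + as.vector(stats::rmultinom(1, counts[i], o[i, ]))
      }
    }
    tot
  }
  input_bins <- bins_for(n_t)
  ip_bins <- bins_for(n_b)
  input_frags <- .place_fragments(input_bins, genome,
                                  length_mean, length_sd, length_range)
  ip_frags <- .place_fragments(ip_bins, genome,
                               length_mean, length_sd, length_range)

  alpha_true <- (depth_input / depth_ip) * (sum(bound) / sum(totals))
  # bench manifest whose alpha reproduces the ledger value: all material
  # ratios 1, the volume factor carries alpha
  v_total <- 100
  v_in <- v_total * alpha_true / (1 + alpha_true)
  manifest <- list(
    ip = sample_manifest(mapped_reads = depth_ip,
                         library_sequenced = 1, library_total = 1,
                         pcr_cycles = 0, bead_capture_yield = 1,
                         ip_mass_total = 1, mass_into_library = 1),
    input = sample_manifest(mapped_reads = depth_input,
                            library_sequenced = 1, library_total = 1,
                            pcr_cycles = 0, bead_capture_yield = 1,
                            ip_mass_total = 1, mass_into_library = 1),
    volumes = reaction_volumes(v_total, v_in))

  eff <- predict_efficiency(sol, o)
  ledger <- list(
    seed = seed,
    alpha = alpha_true,
    species = cbind(sol$species,
                    n_input = n_t, n_ip = n_b),
    free_antibody = sol$free_antibody,
    expected_efficiency = data.frame(chrom = genome$chrom,
                                     xbin = genome$xbin,
                                     efficiency = eff),
    p_ip = as.numeric(bound %*% o) / sum(bound),
    p_input = as.numeric(totals %*% o) / sum(totals),
    depth_ip = depth_ip, depth_input = depth_input,
    total_length_ip = sum(ip_frags$length),
    total_length_input = sum(input_frags$length),
    length_model = list(mean = length_mean, sd = length_sd,
                        range = length_range),
    interval_width = attr(genome, "interval_width"),
    genome_sizes = attr(genome, "sizes"))

  structure(list(ip = ip_frags, input = input_frags,
                 manifest = manifest, ledger = ledger),
            class = "siq_synthetic")
}

#' Write a synthetic experiment to disk
#'
#' Emits `<prefix>_ip.bed`, `<prefix>_input.bed`, `<prefix>_manifest.yaml`
#' and `<prefix>_ledger.json`.
#'
#' @param gen a `siq_synthetic` from [generate_experiment()].
#' @param prefix output path prefix.
#' @return named vector of the four paths, invisibly.
#' @export
write_experiment <- function(gen, prefix) {
  stopifnot(inherits(gen, "siq_synthetic"))
  paths <- c(ip = paste0(prefix, "_ip.bed"),
             input = paste0(prefix, "_input.bed"),
             manifest = paste0(prefix, "_manifest.yaml"),
             ledger = paste0(prefix, "_ledger.json"))
  write_fragments(gen$ip, paths[["ip"]])
  write_fragments(gen$input, paths[["input"]])
  write_manifest(gen$manifest$ip, gen$manifest$input, gen$manifest$volumes,
                 paths[["manifest"]])
  jsonlite::write_json(gen$ledger, paths[["ledger"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}

#' @export
print.siq_synthetic <- function(x, ...) {
  cat(sprintf(
    "synthetic siQ-ChIP experiment: %d IP / %d input fragments, alpha = %.6g (seed %d)\n",
    nrow(x$ip), nrow(x$input), x$ledger$alpha, x$ledger$seed))
  invisible(x)
}
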