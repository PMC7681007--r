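#' Spike-in (HMD) normalization factor
#'
#' The histone-modification-density recipe normalizes a raw IP/input track by
#' the target spike-in read ratio: IP reads of target spike-in divided by
#' input reads of target spike-in.
#'
#' @param ip_target_reads spike-in target reads in the IP sample.
#' @param input_target_reads spike-in target reads in the input sample.
#' @return the normalization factor (ratio). Zero IP reads give 0 with a
#'   warning; zero input reads are an error (undefined normalizer).
#' @export
#' @examples
#' hmd_factor(899, 100)  # 8.99
hmd_factor <- function(ip_target_reads, input_target_reads) {
  stopifnot(is.numeric(ip_target_reads), is.numeric(input_target_reads),
            ip_target_reads >= 0, input_target_reads >= 0)
  if (input_target_reads == 0) {
    stop("undefined HMD normalizer: zero input spike-in reads")
  }
  if (ip_target_reads == 0) {
    warning("zero IP spike-in reads: HMD factor is 0")
  }
  ip_target_reads / input_target_reads
}

#' Apply HMD normalization to a raw IP/input ratio track
#'
#' Divides the raw ratio track bin-wise by the spike-in factor and multiplies
#' by the mean fragment length, producing the "histone modification density"
#' in per-fragment units. HMD values above 100% can and do occur.
#'
#' @param raw_track a `siq_track` of raw IP/input ratios (or any per-base
#'   ratio track).
#' @param factor the [hmd_factor()] value; must be positive.
#' @param mean_length `<L>` in bp.
#' @return a `siq_track` in unit `"hmd-per-fragment"`.
#' @export
hmd_track <- function(raw_track, factor, mean_length) {
  stopifnot(inherits(raw_track, "siq_track"))
  if (!is.numeric(factor) || factor <= 0) {
    stop("HMD factor must be positive")
  }
  out <- data.table::copy(raw_track)
  out$value <- out$value / factor * mean_length
  data.table::setattr(out, "unit", "hmd-per-fragment")
  data.table::setattr(out, "mean_length", mean_length)
  out
}

#' Compare a spike-in normalizer with the siQ-ChIP scale
#'
#' A spike-in normalization is quantitative only when its normalizer equals
#' `alpha^-1` for the experiment -- a condition that can always be checked.
#' For a single condition this reports the discrepancy factor
#' `alpha^-1 / hmd`; for a two-condition comparison it additionally reports
#' the apparent material-difference ratios each scale implies (ratio of
#' normalizers vs ratio of inverse alphas), which is where spike-in
#' insensitivity shows up.
#'
#' @param hmd spike-in factor for condition A (see [hmd_factor()]).
#' @param alpha `siq_alpha` (or numeric alpha) for condition A.
#' @param hmd_b,alpha_b optional second condition.
#' @return an object of class `siq_norm_report` (a list of the factors and
#'   ratios) with a print method.
#' @export
#' @examples
#' compare_normalizers(1.51, 1 / 9.17, hmd_b = 8.99, alpha_b = 1 / 16.02)
compare_normalizers <- function(hmd, alpha, hmd_b = NULL, alpha_b = NULL) {
  ainv <- function(a) if (inherits(a, "siq_alpha")) a$alpha_inverse else 1 / as.numeric(a)
  out <- list(hmd = hmd, alpha_inverse = ainv(alpha),
              discrepancy = ainv(alpha) / hmd)
  if (!is.null(hmd_b)) {
    stopifnot(!is.null(alpha_b))
    out$hmd_b <- hmd_b
    out$alpha_inverse_b <- ainv(alpha_b)
    out$discrepancy_b <- ainv(alpha_b) / hmd_b
    out$normalizer_ratio <- hmd_b / hmd
    out$inverse_alpha_ratio <- ainv(alpha_b) / ainv(alpha)
  }
  structure(out, class = "siq_norm_report")
}

#' @export
print.siq_norm_report <- function(x, ...) {
  s4 <- function(v) format(signif(v, 4))
  cat("spike-in normalizer vs siQ-ChIP scale\n")
  cat(sprintf("  condition A: HMD factor %s, alpha^-1 %s (discrepancy %sx)\n",
              s4(x$hmd), s4(x$alpha_inverse), s4(x$discrepancy)))
  if (!is.null(x$hmd_b)) {
    cat(sprintf("  condition B: HMD factor %s, alpha^-1 %s (discrepancy %sx)\n",
                s4(x$hmd_b), s4(x$alpha_inverse_b), s4(x$discrepancy_b)))
    cat(sprintf("  apparent material difference B/A: %sx by spike-in, %sx by alpha\n",
                s4(x$normalizer_ratio), s4(x$inverse_alpha_ratio)))
  }
  invisible(x)
}
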