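#' Bench-measurement manifest for one sequenced sample
#'
#' Collects every bench measurement for a single IP or input sample that
#' enters the siQ-ChIP scale: the mapped read count, the molar fraction of
#' the library that was sequenced, PCR cycles, the bead-capture yield and the
#' mass fraction of recovered DNA carried into library preparation.
#'
#' All quantities are kept at full precision; ratios are formed only between
#' values carrying the same unit tag. Mixed units within one ratio are an
#' error, never a silent conversion.
#'
#' @param mapped_reads total mapped fragments actually sequenced (R-hat).
#' @param library_sequenced molar amount of library loaded on the sequencer.
#' @param library_total molar amount of the whole library.
#' @param pcr_cycles integer number of amplification cycles, c >= 0.
#' @param bead_capture_yield ratio of captured to expected library
#'   concentration (rho). `NULL` (unmeasured) defaults to 1, the no-loss
#'   limit, with a warning. Values above 1 are accepted: rho also absorbs
#'   global deviations from perfect `2^c` amplification.
#' @param ip_mass_total mass of DNA recovered from the IP (or input aliquot).
#' @param mass_into_library mass of that DNA carried into library prep.
#' @param molar_unit,mass_unit unit tags for the molar and mass pairs.
#' @return an object of class `siq_manifest`.
#' @seealso [compute_alpha()], [scaled_total_reads()], [read_manifest()]
#' @export
#' @examples
#' ip <- sample_manifest(mapped_reads = 37298373,
#'                       library_sequenced = 20, library_total = 856,
#'                       pcr_cycles = 11, bead_capture_yield = 1,
#'                       ip_mass_total = 24.2, mass_into_library = 10)
#' fraction_sequenced(ip)
sample_manifest <- function(mapped_reads,
                            library_sequenced, library_total,
                            pcr_cycles,
                            bead_capture_yield = NULL,
                            ip_mass_total, mass_into_library,
                            molar_unit = "fmol", mass_unit = "ng") {
  if (is.null(bead_capture_yield)) {
    warning("bead_capture_yield (rho) not measured; defaulting to 1 (no-loss limit)")
    bead_capture_yield <- 1
  }
  stopifnot(is.numeric(mapped_reads), length(mapped_reads) == 1L,
            mapped_reads >= 0)
  if (!is.numeric(pcr_cycles) || length(pcr_cycles) != 1L ||
      pcr_cycles < 0 || pcr_cycles != round(pcr_cycles)) {
    stop("pcr_cycles must be a single non-negative integer")
  }
  if (!is.numeric(bead_capture_yield) || bead_capture_yield <= 0) {
    stop("bead_capture_yield (rho) must be a positive number")
  }
  .check_ratio_pair(library_sequenced, library_total,
                    "library_sequenced", "library_total")
  .check_ratio_pair(mass_into_library, ip_mass_total,
                    "mass_into_library", "ip_mass_total")
  structure(
    list(mapped_reads       = as.numeric(mapped_reads),
         library_sequenced  = as.numeric(library_sequenced),
         library_total      = as.numeric(library_total),
         pcr_cycles         = as.integer(pcr_cycles),
         bead_capture_yield = as.numeric(bead_capture_yield),
         ip_mass_total      = as.numeric(ip_mass_total),
         mass_into_library  = as.numeric(mass_into_library),
         molar_unit         = molar_unit,
         mass_unit          = mass_unit),
    class = "siq_manifest")
}

# numerator must be positive and no larger than the denominator
.check_ratio_pair <- function(num, den, num_name, den_name) {
  if (!is.numeric(num) || !is.numeric(den) ||
      length(num) != 1L || length(den) != 1L ||
      !is.finite(num) || !is.finite(den)) {
    stop("invalid manifest: ", num_name, " and ", den_name,
         " must be single finite numbers")
  }
  if (num <= 0 || den <= 0) {
    stop("invalid manifest: ", num_name, " and ", den_name,
         " must be positive")
  }
  if (num > den) {
    stop("invalid manifest: ", num_name, " (", num,
         ") exceeds ", den_name, " (", den, ")")
  }
  invisible(TRUE)
}

#' Reaction volumes for the chromatin suspension
#'
#' The chromatin is suspended in a total volume `V`; an input aliquot of
#' volume `v_in` is removed before the antibody reaction, leaving `V - v_in`
#' as the IP volume. The ratio `v_in / (V - v_in)` is the volume factor folded
#' into alpha.
#'
#' @param total_volume V, the total suspension volume.
#' @param input_aliquot v_in, the aliquot removed for the input sample.
#' @param unit unit tag (both volumes must share it).
#' @return an object of class `siq_volumes`.
#' @export
reaction_volumes <- function(total_volume, input_aliquot, unit = "ul") {
  stopifnot(is.numeric(total_volume), is.numeric(input_aliquot),
            length(total_volume) == 1L, length(input_aliquot) == 1L)
  if (!(input_aliquot > 0 && input_aliquot < total_volume)) {
    stop("invalid volumes: need 0 < input_aliquot < total_volume")
  }
  structure(list(total_volume = as.numeric(total_volume),
                 input_aliquot = as.numeric(input_aliquot),
                 unit = unit),
            class = "siq_volumes")
}

#' @export
print.siq_manifest <- function(x, ...) {
  cat("siQ-ChIP sample manifest\n")
  cat(sprintf("  mapped reads (R-hat):   %s\n",
              format(x$mapped_reads, big.mark = ",")))
  cat(sprintf("  library sequenced/total: %g / %g %s  (F_L = %s)\n",
              x$library_sequenced, x$library_total, x$molar_unit,
              signif(fraction_sequenced(x), 4)))
  cat(sprintf("  PCR cycles (c):         %d\n", x$pcr_cycles))
  cat(sprintf("  bead-capture yield (rho): %g\n", x$bead_capture_yield))
  cat(sprintf("  mass into library/total: %g / %g %s  (F = %s)\n",
              x$mass_into_library, x$ip_mass_total, x$mass_unit,
              signif(fraction_into_library(x), 4)))
  invisible(x)
}

#' Fraction of the library that was sequenced
#'
#' `F_L = sequenced / total`, formed from molar amounts sharing one unit.
#' Can be called on two molar amounts or on a manifest.
#'
#' @param sequenced molar amount sequenced, or a `siq_manifest`.
#' @param total molar amount of the whole library (ignored for manifests).
#' @return the dimensionless ratio F_L.
#' @export
#' @examples
#' fraction_sequenced(20, 856)   # 0.02336
fraction_sequenced <- function(sequenced, total = NULL) {
  if (inherits(sequenced, "siq_manifest")) {
    m <- sequenced
    return(m$library_sequenced / m$library_total)
  }
  .check_ratio_pair(sequenced, total, "sequenced", "total")
  sequenced / total
}

#' Fraction of IP material carried into the library
#'
#' `F = mass_used / mass_total`, formed from masses sharing one unit.
#'
#' @param mass_used mass carried into library prep, or a `siq_manifest`.
#' @param mass_total total mass recovered (ignored for manifests).
#' @return the dimensionless ratio F.
#' @export
#' @examples
#' fraction_into_library(10, 24.2)   # 0.413
fraction_into_library <- function(mass_used, mass_total = NULL) {
  if (inherits(mass_used, "siq_manifest")) {
    m <- mass_used
    return(m$mass_into_library / m$ip_mass_total)
  }
  .check_ratio_pair(mass_used, mass_total, "mass_used", "mass_total")
  mass_used / mass_total
}

#' Scale the observed read count up to the whole-material read count
#'
#' Undoes each known source of material loss and down-sampling between the
#' IP (or input aliquot) and the sequencer:
#' `R = R_hat / (F_L * 2^c * rho * F)`. The result estimates the fragments
#' obtainable if all recovered material were sequenced, and is returned at
#' full precision.
#'
#' @param manifest a [sample_manifest()].
#' @return the scaled total read count R (numeric, not rounded).
#' @export
scaled_total_reads <- function(manifest) {
  stopifnot(inherits(manifest, "siq_manifest"))
  f_l <- fraction_sequenced(manifest)
  f   <- fraction_into_library(manifest)
  rho <- manifest$bead_capture_yield
  if (rho == 0) stop("cannot scale reads: bead_capture_yield (rho) is zero")
  if (f == 0)   stop("cannot scale reads: mass fraction F is zero")
  manifest$mapped_reads / (f_l * 2^manifest$pcr_cycles * rho * f)
}

#' Compute the siQ-ChIP proportionality constant alpha
#'
#' Alpha is the ratio of the input sample's material-tracking factors to the
#' IP sample's, times the reaction-volume factor `v_in / (V - v_in)`:
#'
#' \deqn{\alpha = \frac{\rho_{in}}{\rho}\,
#'   \frac{F_{L,in}}{F_L}\, \frac{F_{in}}{F}\, 2^{c_{in}-c}\,
#'   \frac{v_{in}}{V - v_{in}}}
#'
#' The PCR factor `2^(c_in - c)` equals 1 when IP and input libraries were
#' amplified with the same number of cycles, recovering the familiar
#' three-ratio form; it is reported separately along with every other factor
#' so all material quantities can be reported with published experiments.
#' The volume factor is folded into alpha but also exposed on its own for
#' reconciliation with the bare (volume-free) definition.
#'
#' @param ip manifest for the IP sample.
#' @param input manifest for the input sample.
#' @param volumes a [reaction_volumes()] object.
#' @return an object of class `siq_alpha` with elements `alpha`,
#'   `alpha_inverse`, `alpha_bare` (no volume factor), the individual factors
#'   (`rho_ratio`, `library_fraction_ratio`, `mass_fraction_ratio`,
#'   `cycle_factor`, `volume_factor`), and `ip_scaled_reads` /
#'   `input_scaled_reads` from [scaled_total_reads()].
#' @export
compute_alpha <- function(ip, input, volumes) {
  stopifnot(inherits(ip, "siq_manifest"), inherits(input, "siq_manifest"),
            inherits(volumes, "siq_volumes"))
  if (!identical(ip$molar_unit, input$molar_unit)) {
    stop("unit mismatch: IP library amounts in ", ip$molar_unit,
         " but input in ", input$molar_unit)
  }
  if (!identical(ip$mass_unit, input$mass_unit)) {
    stop("unit mismatch: IP masses in ", ip$mass_unit,
         " but input in ", input$mass_unit)
  }
  rho_ratio  <- input$bead_capture_yield / ip$bead_capture_yield
  fl_ratio   <- fraction_sequenced(input) / fraction_sequenced(ip)
  f_ratio    <- fraction_into_library(input) / fraction_into_library(ip)
  cyc_factor <- 2^(input$pcr_cycles - ip$pcr_cycles)
  vol_factor <- volumes$input_aliquot /
    (volumes$total_volume - volumes$input_aliquot)
  alpha <- rho_ratio * fl_ratio * f_ratio * cyc_factor * vol_factor
  structure(
    list(alpha                  = alpha,
         alpha_inverse          = 1 / alpha,
         alpha_bare             = alpha / vol_factor,
         rho_ratio              = rho_ratio,
         library_fraction_ratio = fl_ratio,
         mass_fraction_ratio    = f_ratio,
         cycle_factor           = cyc_factor,
         volume_factor          = vol_factor,
         ip_scaled_reads        = scaled_total_reads(ip),
         input_scaled_reads     = scaled_total_reads(input),
         ip_manifest            = ip,
         input_manifest         = input,
         volumes                = volumes),
    class = "siq_alpha")
}

#' @export
print.siq_alpha <- function(x, ...) {
  s4 <- function(v) format(signif(v, 4))
  cat("siQ-ChIP scale\n")
  cat(sprintf("  alpha                = %s\n", s4(x$alpha)))
  cat(sprintf("  alpha^-1             = %s\n", s4(x$alpha_inverse)))
  cat(sprintf("  alpha (no volume)    = %s\n", s4(x$alpha_bare)))
  cat("  factors (input over IP):\n")
  cat(sprintf("    rho ratio          = %s\n", s4(x$rho_ratio)))
  cat(sprintf("    F_L ratio          = %s\n", s4(x$library_fraction_ratio)))
  cat(sprintf("    F ratio            = %s\n", s4(x$mass_fraction_ratio)))
  cat(sprintf("    2^(c_in - c)       = %s\n", s4(x$cycle_factor)))
  cat(sprintf("    v_in/(V - v_in)    = %s\n", s4(x$volume_factor)))
  cat(sprintf("  scaled total reads: IP %s, input %s\n",
              s4(x$ip_scaled_reads), s4(x$input_scaled_reads)))
  invisible(x)
}

#' Ratio of siQ-ChIP scales between two conditions
#'
#' The ratio of alpha between two conditions is the material difference
#' between the two samples as they arrive at the sequencer. Because usage in
#' the literature is ambiguous about direction, both the alpha ratio and the
#' inverse-alpha ratio (each as condition `b` relative to condition `a`) are
#' reported; they are reciprocals.
#'
#' @param a,b `siq_alpha` objects, or bare numeric alpha values.
#' @return a list with `alpha_ratio` (= alpha_b / alpha_a) and
#'   `inverse_alpha_ratio` (= alpha_b^-1 / alpha_a^-1).
#' @export
#' @examples
#' alpha_ratio(1 / 9.17, 1 / 16.02)$inverse_alpha_ratio  # ~1.74
alpha_ratio <- function(a, b) {
  av <- if (inherits(a, "siq_alpha")) a$alpha else as.numeric(a)
  bv <- if (inherits(b, "siq_alpha")) b$alpha else as.numeric(b)
  if (!is.finite(av) || !is.finite(bv) || av <= 0 || bv <= 0) {
    stop("alpha values must be positive")
  }
  list(alpha_ratio = bv / av,
       inverse_alpha_ratio = (1 / bv) / (1 / av))
}

#' Read an experiment manifest file
#'
#' The manifest is flat YAML with `ip:`, `input:` and `volumes:` blocks whose
#' keys are the arguments of [sample_manifest()] and [reaction_volumes()].
#'
#' @param path path to a YAML manifest.
#' @return a list with elements `ip`, `input` (both `siq_manifest`) and
#'   `volumes` (`siq_volumes`).
#' @export
read_manifest <- function(path) {
  raw <- yaml::read_yaml(path)
  for (blk in c("ip", "input", "volumes")) {
    if (is.null(raw[[blk]])) stop("manifest is missing the '", blk, "' block")
  }
  mk <- function(b) {
    do.call(sample_manifest, b[names(b) %in% names(formals(sample_manifest))])
  }
  vols <- raw$volumes
  list(ip = mk(raw$ip), input = mk(raw$input),
       volumes = do.call(reaction_volumes,
                         vols[names(vols) %in% names(formals(reaction_volumes))]))
}

#' Write an experiment manifest file
#'
#' Inverse of [read_manifest()]; a write/read round trip reproduces alpha
#' bit-identically.
#'
#' @param ip,input `siq_manifest` objects.
#' @param volumes a `siq_volumes` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(ip, input, volumes, path) {
  out <- list(ip = unclass(ip), input = unclass(input),
              volumes = unclass(volumes))
  yaml::write_yaml(out, path, precision = 17L)
  invisible(path)
}
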