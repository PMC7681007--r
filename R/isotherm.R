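#' Define an epitope species in the IP binding reaction
#'
#' A species is anything the antibody-bead particle can capture: the target
#' PTM, an off-target PTM, an inert pool (binding constant 0), or an
#' exogenous spike-in nucleosome. Binding constants are macroscopic,
#' absorbing the unknown polyvalent complexity of the chromatin-antibody-bead
#' interaction.
#'
#' @param name species label.
#' @param total total concentration S_i^t in the IP volume (uM).
#' @param K macroscopic binding constant K_B,i (1/uM); 0 encodes an inert
#'   species.
#' @param spike logical; spike-in species are solved like any other but are
#'   excluded from chromatin fractional composition and reported separately.
#' @return a one-row data.frame.
#' @export
species <- function(name, total, K, spike = FALSE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(total), total >= 0,
            is.numeric(K), K >= 0)
  data.frame(name = name, total = as.numeric(total), K = as.numeric(K),
             spike = isTRUE(spike), stringsAsFactors = FALSE)
}

#' Define a competitive IP binding reaction
#'
#' @param antibody_total total antibody concentration AB^t (uM).
#' @param species a data.frame of species rows (see [species()]), rbind-ed.
#' @return an object of class `siq_reaction`.
#' @export
#' @examples
#' rx <- reaction(6, rbind(species("target", 10.7, 11),
#'                         species("off1", 0.3, 0.1),
#'                         species("off2", 0.3, 0.5)))
#' solve_binding(rx)
reaction <- function(antibody_total, species) {
  stopifnot(is.numeric(antibody_total), antibody_total >= 0)
  if (is.null(species) || nrow(species) == 0L) {
    species <- data.frame(name = character(), total = numeric(),
                          K = numeric(), spike = logical())
  }
  stopifnot(all(c("name", "total", "K", "spike") %in% names(species)),
            all(species$total >= 0), all(species$K >= 0),
            !anyDuplicated(species$name))
  structure(list(antibody_total = as.numeric(antibody_total),
                 species = species),
            class = "siq_reaction")
}

# conservation defect as a function of candidate free antibody a:
# g(a) = a + sum_i S_i^t * aK_i/(1 + aK_i) - AB^t, strictly increasing in a.
.g_conservation <- function(a, antibody_total, totals, K) {
  y <- a * K
  a + sum(totals * y / (1 + y)) - antibody_total
}

#' Solve the IP mass-conservation laws for free antibody and bound species
#'
#' Total antibody and total epitope of every species are conserved in the
#' binding reaction, with per-species bound concentration
#' `S_i^b = S_i^t * y/(1+y)`, `y = AB^f * K_i`. The free antibody `AB^f` is
#' the unique root in `[0, AB^t]` of the antibody-conservation defect
#' `g(a) = a + sum_i S_i^t aK_i/(1+aK_i) - AB^t`, which is strictly
#' increasing, so a bracketed bisection is guaranteed to converge; we iterate
#' to a relative bracket width of `tolerance`.
#'
#' @param rx a [reaction()].
#' @param tolerance relative bisection tolerance on AB^f (default 1e-12).
#' @param max_iter iteration cap (the bracket halves each step; 200 is far
#'   beyond what 1e-12 needs).
#' @return an object of class `siq_isotherm`: `free_antibody`, a `species`
#'   data.frame gaining `bound` and `free` columns, and `residual`, the
#'   absolute antibody-conservation defect at the solution.
#' @export
solve_binding <- function(rx, tolerance = 1e-12, max_iter = 200L) {
  stopifnot(inherits(rx, "siq_reaction"), tolerance > 0)
  sp <- rx$species
  abt <- rx$antibody_total
  if (abt == 0 || nrow(sp) == 0L || all(sp$total * sp$K == 0)) {
    ab_f <- abt      # nothing binds
  } else {
    lo <- 0; hi <- abt
    scale <- max(abt, 1)
    it <- 0L
    # bisect past `tolerance` down to the floating-point pinch: g can be
    # steep, so conservation needs the root at machine precision
    while (it < max_iter) {
      mid <- (lo + hi) / 2
      if (mid <= lo || mid >= hi) break
      if (.g_conservation(mid, abt, sp$total, sp$K) < 0) lo <- mid else hi <- mid
      it <- it + 1L
    }
    if (hi - lo > tolerance * scale) {
      stop(sprintf(
        "binding solver did not converge: bracket [%.15g, %.15g] after %d iterations",
        lo, hi, it))
    }
    ab_f <- (lo + hi) / 2
  }
  y <- ab_f * sp$K
  sp$bound <- sp$total * y / (1 + y)
  sp$free  <- sp$total - sp$bound
  structure(list(free_antibody = ab_f,
                 antibody_total = abt,
                 species = sp,
                 residual = abs(ab_f + sum(sp$bound) - abt)),
            class = "siq_isotherm")
}

#' @export
print.siq_isotherm <- function(x, ...) {
  cat(sprintf("IP binding equilibrium: AB^t = %g, AB^f = %.6g (residual %.2e)\n",
              x$antibody_total, x$free_antibody, x$residual))
  df <- x$species
  df$bound <- signif(df$bound, 6)
  df$free <- signif(df$free, 6)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Fractional composition of the sequenced (bound) fragments
#'
#' The share of all captured chromatin fragments contributed by each species:
#' `100 * bound_i / sum_j bound_j`, over non-spike species. This is the
#' quantity spike-in capture efficiencies cannot report. The last element is
#' computed by complement so the vector sums to 100 exactly.
#'
#' @param sol a `siq_isotherm` solution.
#' @return named percentage vector over non-spike species.
#' @export
composition <- function(sol) {
  stopifnot(inherits(sol, "siq_isotherm"))
  sp <- sol$species[!sol$species$spike, , drop = FALSE]
  tot <- sum(sp$bound)
  if (nrow(sp) == 0L || tot == 0) {
    stop("composition undefined: no chromatin species has bound material")
  }
  pct <- 100 * sp$bound / tot
  if (length(pct) > 1L) pct[length(pct)] <- 100 - sum(pct[-length(pct)])
  stats::setNames(pct, sp$name)
}

#' Capture efficiency of one species
#'
#' The fraction of a species that is captured in the IP,
#' `100 * bound/total = 100 * AB^f K/(1 + AB^f K)` -- distinct from its
#' fractional composition. This is what a spike-in reports about itself.
#'
#' @param sol a `siq_isotherm` solution.
#' @param name species label.
#' @return percentage in \[0, 100\].
#' @export
capture_efficiency <- function(sol, name) {
  stopifnot(inherits(sol, "siq_isotherm"))
  i <- match(name, sol$species$name)
  if (is.na(i)) stop("species not in reaction: ", name)
  if (sol$species$total[i] <= 0) {
    stop("capture efficiency undefined: species ", name, " has zero total")
  }
  100 * sol$species$bound[i] / sol$species$total[i]
}

#' Antibody selectivity as a ratio of binding constants
#'
#' @param a,b [species()] rows (or any list with a `K` element).
#' @return K_a / K_b.
#' @export
#' @examples
#' selectivity(species("t", 1, 11), species("o", 1, 0.5))  # 22
selectivity <- function(a, b) {
  ka <- a$K; kb <- b$K
  stopifnot(is.numeric(ka), is.numeric(kb))
  if (kb == 0) stop("selectivity undefined against an inert species (K = 0)")
  if (ka == 0) stop("selectivity undefined for an inert species (K = 0)")
  ka / kb
}

#' Scan the isotherm across target-depletion conditions
#'
#' Models an epitope-depletion experiment as motion along the binding
#' isotherm: the target total `S1t` (species 1 of the base reaction) is swept
#' over a grid while total chromatin load is held fixed, under one of two
#' replacement scenarios:
#'
#' * `case1` -- depleted target is replaced by inert nucleosomes. Inert
#'   fragments do not enter the conservation law, so only the target total
#'   changes between points; the implied inert pool
#'   `total_chromatin - sum(binding totals)` is tracked and must stay
#'   non-negative.
#' * `case2` -- depleted target is replaced by the first off-target (species
#'   2), i.e. `S2t = total_constant - S1t`.
#'
#' Each grid point is solved independently with [solve_binding()].
#'
#' @param base a [reaction()] whose first species is the target.
#' @param scenario `"case1"` or `"case2"`.
#' @param grid numeric vector of target totals S1t (strictly monotone).
#' @param total_constant total chromatin (case1) / target + first off-target
#'   (case2) concentration held fixed across the scan; default 11 uM.
#' @param tolerance passed to [solve_binding()].
#' @return an object of class `siq_scan`: a data.frame with one row per grid
#'   point holding `S1t`, `free_antibody`, `total_bound`, and per-species
#'   `bound.*`, `pct.*` (composition, non-spike) and `eff.*` (capture
#'   efficiency) columns, plus the per-point solutions in
#'   `attr(, "solutions")`.
#' @export
depletion_scan <- function(base, scenario = c("case1", "case2"), grid,
                           total_constant = 11, tolerance = 1e-12) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(base, "siq_reaction"), length(grid) >= 1L)
  if (length(grid) > 1L) {
    d <- diff(grid)
    if (!(all(d > 0) || all(d < 0))) stop("grid must be strictly monotone")
  }
  sp0 <- base$species
  nonspike <- !sp0$spike
  if (!any(nonspike)) stop("base reaction needs at least one chromatin species")
  target_idx <- which(nonspike)[1L]
  if (scenario == "case2") {
    chrom_idx <- which(nonspike)
    if (length(chrom_idx) < 2L) {
      stop("case2 needs an off-target species to receive the depleted target")
    }
    off_idx <- chrom_idx[2L]
  }
  sols <- vector("list", length(grid))
  rows <- vector("list", length(grid))
  for (j in seq_along(grid)) {
    s1 <- grid[j]
    sp <- sp0
    sp$total[target_idx] <- s1
    if (scenario == "case2") {
      s2 <- total_constant - s1
      if (s2 < 0) {
        stop(sprintf("infeasible grid point S1t = %g: implied %s total %g < 0",
                     s1, sp$name[off_idx], s2))
      }
      sp$total[off_idx] <- s2
      inert_pool <- NA_real_
    } else {
      binding_load <- sum(sp$total[!sp$spike])
      inert_pool <- total_constant - binding_load
      if (inert_pool < -1e-9) {
        stop(sprintf(
          "infeasible grid point S1t = %g: implied inert pool %g < 0",
          s1, inert_pool))
      }
    }
    sol <- solve_binding(reaction(base$antibody_total, sp),
                         tolerance = tolerance)
    sols[[j]] <- sol
    pct <- composition(sol)
    eff <- vapply(sol$species$name[sol$species$total > 0],
                  function(nm) capture_efficiency(sol, nm), numeric(1))
    row <- data.frame(S1t = s1, free_antibody = sol$free_antibody,
                      total_bound = sum(sol$species$bound[!sol$species$spike]),
                      inert_pool = inert_pool)
    for (nm in sol$species$name) {
      row[[paste0("bound.", nm)]] <- sol$species$bound[sol$species$name == nm]
    }
    for (nm in names(pct)) row[[paste0("pct.", nm)]] <- pct[[nm]]
    for (nm in names(eff)) row[[paste0("eff.", nm)]] <- eff[[nm]]
    rows[[j]] <- row
  }
  out <- do.call(rbind, rows)
  structure(out, scenario = scenario, total_constant = total_constant,
            solutions = sols, class = c("siq_scan", "data.frame"))
}

#' @export
print.siq_scan <- function(x, ...) {
  cat(sprintf("siQ-ChIP depletion scan (%s), %d grid points, total constant %g\n",
              attr(x, "scenario"), nrow(x), attr(x, "total_constant")))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE,
                   digits = 4)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Plot a depletion scan
#'
#' Fractional composition (solid), capture efficiencies (dashed) and total
#' bound concentration against target total; depletion reads right to left.
#'
#' @param x a `siq_scan`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.siq_scan <- function(x, ...) {
  df <- as.data.frame(x)
  pct <- df[, grep("^pct\\.", names(df)), drop = FALSE]
  eff <- df[, grep("^eff\\.", names(df)), drop = FALSE]
  graphics::matplot(df$S1t, cbind(pct, eff), type = "l",
                    lty = c(rep(1, ncol(pct)), rep(2, ncol(eff))),
                    xlab = "target total S1t (uM)", ylab = "percent", ...)
  graphics::legend("right", legend = c(names(pct), names(eff)),
                   lty = c(rep(1, ncol(pct)), rep(2, ncol(eff))),
                   col = seq_len(ncol(pct) + ncol(eff)), cex = 0.7, bty = "n")
  invisible(x)
}

#' Predict the capture-efficiency track from an isotherm solution
#'
#' Evaluates the model efficiency per genomic interval:
#' `e(x) = sum_i S_i^b o_i(x) / sum_i S_i^t o_i(x)`, where `o_i(x)` is the
#' normalized genomic distribution of species i. Intervals where no species
#' has material get value 0 and are flagged.
#'
#' @param sol a `siq_isotherm` solution.
#' @param distributions matrix of `o_i(x)`: one row per species (rownames
#'   matching species names, or in species order), one column per interval;
#'   each row sums to 1.
#' @return numeric efficiency vector over intervals, in \[0, 1\], with
#'   `attr(, "empty")` flagging zero-material intervals.
#' @export
predict_efficiency <- function(sol, distributions) {
  stopifnot(inherits(sol, "siq_isotherm"), is.matrix(distributions))
  sp <- sol$species
  o <- distributions
  if (!is.null(rownames(o))) {
    idx <- match(rownames(o), sp$name)
    if (anyNA(idx)) stop("distribution rows not in reaction: ",
                         paste(rownames(o)[is.na(idx)], collapse = ", "))
    sp <- sp[idx, , drop = FALSE]
  } else if (nrow(o) != nrow(sp)) {
    stop("distributions must have one row per species")
  }
  rs <- rowSums(o)
  keep <- sp$total > 0
  if (any(abs(rs[keep] - 1) > 1e-8)) {
    stop("each species distribution o_i(x) must sum to 1")
  }
  num <- as.numeric(sp$bound %*% o)
  den <- as.numeric(sp$total %*% o)
  e <- ifelse(den > 0, num / pmax(den, .Machine$double.xmin), 0)
  attr(e, "empty") <- den == 0
  e
}
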