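---
title: "The siQ-ChIP model: a physical scale for ChIP-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The siQ-ChIP model: a physical scale for ChIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siqchip)
```

## The problem

ChIP-seq reports the ratio of immunoprecipitated (IP) to input fragments per
genomic interval, but that ratio is only *proportional* to a physical
quantity. Without the proportionality constant, peak heights cannot be
compared between conditions — an epitope-depleted sample can show *taller*
peaks than its control. The common fix is to add exogenous spike-in
chromatin and normalize to its capture, but a spike-in only reports its own
capture efficiency, not the composition of the captured material, and it
saturates exactly in the regimes (excess antibody, depleted target) where
quantification matters most.

siQ-ChIP ("sans-spike-in quantitative ChIP") closes the gap by treating the
IP as what it physically is: a competitive equilibrium binding reaction.
Two results follow. First, the proportionality constant — called alpha —
is computable from measurements already made in every ChIP-seq experiment.
Second, a forward model of the binding reaction predicts how IP composition
responds to perturbations, including the failure modes of spike-in
normalization.

## The scale: alpha

Every material-handling step between the IP product and the sequencer
down-samples or amplifies the library by a known factor. If `R̂` mapped
fragments were sequenced from a fraction `F_L` of the library, after `c` PCR
cycles, with bead-capture yield `ρ` and a fraction `F` of the IP mass
carried into library prep, the whole IP product would have yielded

```
R = R̂ / (F_L · 2^c · ρ · F)
```

fragments ([scaled_total_reads()]). Alpha is the ratio of the input sample's
factors to the IP sample's, times the reaction-volume factor:

```
alpha = (ρ_in/ρ) · (F_L,in/F_L) · (F_in/F) · 2^(c_in − c) · v_in/(V − v_in)
```

where `V` is the total chromatin suspension volume and `v_in` the input
aliquot. The cycle factor `2^(c_in − c)` is our completion of the ratio:
when IP and input libraries are amplified with equal cycle counts it is
exactly 1 and the familiar three-ratio product is recovered; when cycle
counts differ (common in practice — inputs need fewer cycles), omitting it
would silently mis-scale alpha by a power of two. The volume factor is
folded into alpha but also reported separately so users comparing against
the bare three-ratio form can reconcile.

`compute_alpha()` reports every individual factor, not just the product:
these are the measurements that should accompany any published ChIP-seq
experiment, because two "repeats" whose factors differ were not run in the
same reaction regime.

```{r}
man <- read_manifest(system.file("extdata", "example_manifest.yaml",
                                 package = "siqchip"))
compute_alpha(man$ip, man$input, man$volumes)
```

Units are tags, not conversions: a manifest carries `fmol` and `ng` labels
and alpha only ever consumes same-unit ratios, so mixed units within one
ratio are rejected rather than converted. When the bead-capture yield `ρ`
was not measured we default it to 1 — the no-loss limit — with a warning;
we deliberately do not back-solve `ρ` from downstream read counts.

## The forward model: competitive binding

In the IP volume each epitope species `i` (target PTM, off-target PTMs,
spike-in nucleosomes) has total concentration `S_i^t` and a macroscopic
binding constant `K_i` to the antibody–bead particle (macroscopic in the
sense that polyvalent complexity is absorbed into `K`; stoichiometry is
taken 1:1). At equilibrium, mass conservation gives the bound concentration
`S_i^b = S_i^t · y/(1+y)` with `y = AB^f K_i`, and the free antibody `AB^f`
is the unique root in `[0, AB^t]` of

```
g(a) = a + Σ_i S_i^t · aK_i/(1 + aK_i) − AB^t
```

`g` is strictly increasing, so `solve_binding()` uses bracketed bisection on
`[0, AB^t]` — robustness over speed at these problem sizes. Because `g` can
be steep (slope up to `1 + Σ S_i^t K_i`), the bisection continues past the
nominal tolerance down to the floating-point pinch of the bracket; the
conservation residual `|AB^f + Σ S_i^b − AB^t|` then sits at machine level
(the suite checks < 1e−10, observed ~1e−15) rather than tolerance × slope.
Degenerate reactions (no antibody, no species, all species inert) short-cut
to the exact answer.

Two distinct percentages matter downstream, and conflating them is the root
of the spike-in critique:

* **capture efficiency** (`capture_efficiency()`): the fraction of one
  species that is bound, `100·y/(1+y)`. A spike-in reports this, about
  itself.
* **fractional composition** (`composition()`): the share of all bound
  fragments contributed by one species. This is what sequencing actually
  samples, and no spike-in can report it. The last element is computed by
  complement so the vector sums to 100.

### Depletion scans

`depletion_scan()` sweeps the target total `S1t` downward under fixed total
chromatin load, the design constraint of a well-posed comparison. Two
replacement scenarios are modeled: depleted target replaced by inert
nucleosomes (case 1; inert material never enters `g`) or by the first
off-target (case 2, `S2t = total − S1t`). Defaults we had to choose and
document as package choices: the case-2 total constant is 11 µM; in case 1
the off-target totals stay at 0.3 µM each (the second off-target's value,
used symmetrically for the first, whose case-1 value is not independently
fixed); spike-in species default to 0.03 µM totals with `K` matching the
target and weaker off-target, small enough that the antibody saturates them
readily. All are overridable in scenario files.

The scans reproduce the model's qualitative predictions as strict
monotonicities, which the test suite asserts grid-point by grid-point: as
the target is depleted, free antibody rises, *every* species' capture
efficiency rises (including spike-ins — which is why spike-in normalizers
are insensitive exactly when composition is changing fastest), the target's
composition falls, and every off-target's composition rises.

```{r, fig.width = 6, fig.height = 4}
sc <- depletion_scan(
  reaction(6, rbind(species("target", 10.4, 11),
                    species("off1", 0.3, 0.1),
                    species("off2", 0.3, 0.5))),
  "case2", grid = seq(0.5, 10.4, length.out = 40))
plot(sc)
```

## From fragments to efficiency tracks

With alpha in hand, the efficiency at genomic interval `x` for fragments of
length `L` is `ê(x, L) = alpha · IP(x, L)/input(x, L)`. Conventions, all
deliberate:

* Coordinates are 0-based half-open (BED dialect); a fragment belongs to the
  interval its *start* falls in, and to length bin `floor(L / 10 bp)` by
  default. Single-end data get a user-supplied constant length.
* **Zero rule**: a bin where either sample has no fragments evaluates to 0.
  Bins with IP but no input coverage are flagged — a high flagged fraction
  is the symptom of a too-small interval width.
* **Projection to 1D**: `ê(x)` is the input-count-weighted mean of
  `ê(x, L)` over length bins. The weighted mean preserves the per-base
  interpretation, reduces to the plain scalar ratio when all fragments share
  one length, and makes the projection insensitive to sparsely populated
  length bins. Per-fragment units multiply by the mean fragment length
  `⟨L⟩`, taken by default from the IP sample (the sample whose capture is
  being reported; configurable).
* **Width stabilization** (`stabilize_width()`): the interval width is grown
  along a ladder (default 1, 2, 5, 10, 20, 50 kb) until consecutive tracks
  agree. Dissimilarity is the mean absolute relative difference after
  aggregating the finer track onto the coarser grid with input weights;
  because input-weighted aggregation reproduces the coarse ratio exactly in
  the absence of zero-rule losses, this measure isolates precisely the
  width-dependence the zero rule creates. 10 kb is a sensible working width
  for broad marks like H3K27me3.
* **Differential tracks** (`differential()`): treatment/control ratios are
  emitted as *missing*, not 0 and not infinity, wherever either condition is
  empty, so browsers do not render false depletion.
* Duplicating every record in both samples leaves `ê(x)` unchanged —
  sequencer-specific proportionality constants cancel, which is also why IP
  and input must come off the same sequencer.

Output is standard 4-column bedGraph via `rtracklayer`.

## Spike-in (HMD) arithmetic, for comparison

`hmd_factor()` and `hmd_track()` implement the spike-in recipe — divide the
raw ratio track by the target spike-in's IP/input read ratio and multiply by
`⟨L⟩` (the same `⟨L⟩` as the siQ track by default, overridable). The point
of carrying this arithmetic in the package is `compare_normalizers()`: a
spike-in normalizer is quantitative only if it equals `alpha⁻¹`, a condition
that can always be checked, and in a two-condition comparison the ratio of
spike-in normalizers and the ratio of inverse alphas give directly
comparable "apparent material difference" numbers. Because the direction of
such ratios is ambiguous in informal usage, `alpha_ratio()` reports both the
alpha ratio and the inverse-alpha ratio rather than guessing.

## Overlap statistic

`overlap_stats()` reduces two merged interval sets to indicator sets over
genome bins (default bin = track interval width), making the hypergeometric
urn model exact: observed overlapping bins against expectation
`|A||B|/N` with upper-tail `P(X ≥ obs)` from `phyper`. The universe defaults
to all bins of the supplied chromosome sizes; restricting the universe
(e.g. to covered bins) is the caller's choice via the sizes argument. The
suite validates `p` against exhaustive enumeration of all draws on
universes of ≤ 12 bins and checks fold ≈ 1 under independent random sets.

## The synthetic generator

`generate_experiment()` is the package's ground truth. It emulates exactly
the data-generating process the model assumes: per-species genomic
distributions `o_i(x)` on a toy genome (default 2 × 1 Mb at 10 kb
intervals — the working resolution for broad marks, at desk scale), an
equilibrium IP solved by `solve_binding()`, input fragments drawn
proportional to totals and IP fragments proportional to bound
concentrations (each placed along its species' `o_i`), and fragment lengths
from a rounded Gaussian (mean 150 bp, sd 20, truncated to [50, 500] —
typical sonicated mononucleosomal libraries). Counts map to concentrations
through an arbitrary fixed `(V − v_in)·N_A` scale, so only fractions drive
sampling and the true alpha is `(depth_in/depth_ip)·(ΣS^b/ΣS^t)`; the
generator fabricates a bench manifest realizing that alpha through the
volume factor, and records everything — seed, bound counts, expected
per-interval efficiencies, total fragment lengths — in a ledger.

What it does *not* emulate, hence what passing recovery tests do not show
about real data: GC and mappability bias, duplicate reads, chromatin
accessibility structure in fragmentation, antibody positional bias (the
model itself assumes none), wash kinetics (equilibrium only), and read-level
sequence errors (fragments are intervals, not reads). Recovery tests run
the full pipeline (read → bin → efficiency → project) against the ledger at
depths 10⁴ and 10⁵ over 200 intervals, where the mean absolute error halves
and better as depth grows ten-fold, consistent with √depth sampling noise.

## Known limitations

* Alpha is only as good as the bench measurements; `ρ` in particular is
  often unmeasured and defaulted, which biases the absolute scale (not
  differential comparisons run with the same default).
* The binding model is forward-only: no fitting of `K` values from data.
* Equilibrium is assumed, and the very-low-material regime (combining IPs
  for sequencing) is out of scope.
* The 2D→1D projection is one defensible choice; at high resolution,
  per-fragment reporting should integrate over the length distribution
  rather than multiply by `⟨L⟩`.
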