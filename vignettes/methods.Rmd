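---
title: "Detecting recessive lethal haplotypes: models, assumptions and design choices"
author: "lethalscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recessive lethal haplotypes: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lethalscan)
```

# The inference chain

A recessive lethal allele at haplotype frequency $p$ kills (a fraction
of) homozygous conceptuses or calves. In a genotyped population this
produces three independent, connectable signals, and `lethalscan`
implements one stage for each:

1. **Deficiency of homozygotes.** Among $N$ genotyped animals a neutral
   haplotype yields $p^2 N$ homozygotes in expectation; a lethal yields
   none. Two probability models quantify "none observed":
   * *random mating*: with carrier frequency $C = 2p$, the expected
     count is $(C^2/4)\,N = p^2 N$ and
     $P_0 = (1 - C^2/4)^N = (1-p^2)^N$, evaluated in log space. This
     equals the zero class of a $\mathrm{Binomial}(N, p^2)$ — an
     identity the test suite asserts exactly over a $10\times10$
     $(p,N)$ grid.
   * *carrier mating*: count the genotyped offspring of carrier ×
     carrier matings (sire × dam when both are genotyped; sire ×
     maternal grand sire when the dam is not — the dam's genotype,
     when available, takes precedence). Each such mating produces a
     homozygote with probability $1/4$, so the expectation is
     $\text{count}/4$ and $P_0 = 0.75^{\text{count}}$. The MGS route
     inherits the assumption that carrier frequency is equal in
     maternal grand sires and grand dams.
2. **Insemination failure.** A conception-acting lethal makes cows
   return to service. Classifying each insemination by the carrier
   status of the service sire and the cow's own sire (the conceptus's
   maternal grand sire) gives four mating types whose extra failure
   beyond the background rate $f$ is $0$, $0$, $0.25\,p(1-f)$ and
   $0.25\,\frac{0.5}{1-0.5p}(1-f)$: in type 4 the ungenotyped dam is a
   carrier with probability $0.5/(1-0.5p)$ given her carrier sire. $f$
   is estimated as the weighted mean failure of types 1–2, which are
   free of the candidate lethal. The formal test is a linear mixed
   model on the 0/1 non-return indicator (NRR56) with parity, year and
   mating type fixed, plus the cow's additive genetic effect against
   the pedigree relationship matrix; effects are reported as deviations
   from type 4 with Wald z statistics.
3. **Stillbirth.** A birth-acting lethal raises stillbirth in matings
   where the conceptus can be homozygous. The live-calf indicator is
   regressed (logistic, IRLS, log-likelihood tolerance $10^{-8}$, 50
   iterations) on
   $P_{\text{hom fetus}} = 0.25\cdot\text{sire}\cdot\text{dam}$ or
   $0.125\cdot\text{sire}\cdot\text{MGS}$, with parity (0–4), calf sex
   and year–month fixed. Because the response is the *live* outcome, a
   lethal shows as $\beta < 0$; the stillbirth odds ratio
   $1/e^{\beta}$ is reported alongside to keep the sign unambiguous.

The association arm runs on *corrected phenotypes*
$y^* = \text{EBV} (+ \text{PE}) + \bar e$, built from pedigree mixed
models, then tested marker by marker under a genomic relationship
matrix (below).

# The mixed-model engine

All pedigree models go through one engine: Henderson's mixed-model
equations with a sparse $A^{-1}$ assembled directly from the sorted
pedigree (Meuwissen–Luo inbreeding; Mendelian sampling variance
$d_i = 1 - 0.25(1+F_s) - 0.25(1+F_d)$ with $F = -1$ for unknown
parents). Unknown-parent groups are supported as Westell–Quaas genetic
groups: unknown parents map to trailing group columns and the groups
are fitted as random inside the genetic term; on synthetic data the
default grouping is one group per birth cohort.

Variance components come from average-information REML. Scores and the
AI matrix are computed through the MME inverse:
$\mathrm{tr}(P Z K Z') = q/\sigma^2 - \mathrm{tr}(K^{-1}C^{uu})/\sigma^4$
for a simple term, with the analogous 2×2-weighted trace for the
correlated direct–maternal block $G_0 \otimes A$; the identities are
verified in the test suite against a dense-$V$ restricted likelihood
maximised independently. When an AI step leaves the parameter space it
is damped (step halving); variances driven below the floor
($10^{-6}\times\mathrm{var}(y)$) are pinned there and flagged; if no
damped step is admissible the round falls back to an EM update, which
cannot leave the space. Convergence is declared at a relative parameter
change below $10^{-6}$. One genuine boundary case deserves note: with
little information the direct–maternal correlation can have its REML
maximum at $\pm 1$; EM then crawls toward the boundary forever. The
engine accepts such runs once the relative change falls below
$10^{-3}$ and flags every component as a boundary estimate rather than
failing.

The bivariate first-vs-later-parity stillbirth structure is implemented
as two univariate maternal–direct analyses by parity group: the
corrected phenotypes use only within-group components, and full
cross-group AI-REML would be disproportionate at desk scale. Corrected
stillbirth phenotypes attach the residual of the calving where the
animal was the dam (her first calving for the group-1 traits; the mean
of her later calvings, plus her permanent-environment solution, for the
group-2 maternal trait). An animal lacking the needed record is
excluded from that trait and counted in the log. Binary traits are
analysed on the observed 0/1 scale with linear models; no threshold
model is offered.

Heritabilities: maternal
$h^2_m = \sigma^2_m / (\sigma^2_m + \sigma^2_u + \sigma^2_e +
2\sigma_{mu})$, direct the same denominator with $\sigma^2_u$ on top,
repeatability models $h^2 = \sigma^2_u/(\sigma^2_u + \sigma^2_{PE} +
\sigma^2_e)$.

# GWAS

Marker QC runs in a fixed order — marker missingness $> 5\%$, animal
call rate $< 95\%$, heterozygosity $> 3$ SD above the mean,
Hardy–Weinberg exact $P < 10^{-6}$, MAF $< 0.01$ — with a per-step
removal report. The GRM is allele-count standardized with equal marker
weights, $G_{jk} = \frac1m \sum_i (x_{ji}-2p_i)(x_{ki}-2p_i) /
(2p_i(1-p_i))$. Association is two-stage: variance components are
estimated once on the null model by exact 1-D REML on the
eigendecomposition of $G$, then each marker is tested by GLS at that
fixed covariance with a per-marker residual scale on the whitened data
— so $\sigma^2_u = 0$ reduces exactly to OLS, and on a 30-animal toy
the two-stage p-values track an exact per-marker REML oracle within
10%. Significance: Bonferroni $\alpha/m$; "suggestive" is the 10
smallest p-values per trait with deterministic positional tie-breaks.
Suggestive markers are co-located with scan haplotypes when they fall
within the haplotype interval padded by 1 Mb on each side (1-based
closed intervals throughout), and linkage is declared at $r^2 > 0.5$,
computed on phased haplotype indicators where available (a
genotype-dosage fallback is labelled). The genomic inflation factor is
the median association $\chi^2_1$ over its null median 0.4549.

# The synthetic world

The generator states the world the analyses assume and is *not* tuned
to test outcomes:

* **Pedigree**: an AI half-sib structure — a few sires per generation
  drawn from the previous generation's males, dams sampled from its
  females, ~5 generations, birth dates advancing two years per
  generation. Real family-size distributions for the source population
  are unpublished; the presets use plausible AI structure.
* **Genotypes**: gene-drop through the pedigree from a finite founder
  haplotype pool with a gently decaying frequency spectrum; at most
  one crossover per chromosome per meiosis at rate 0.2 — consistent
  with the scaled-down map of 150 markers at 60 kb (~9 Mb ≈ 9 cM per
  "chromosome"). Full genetic-map fidelity is deliberately out of
  scope; the deficiency statistics only need realistic window
  haplotype structure.
* **Lethals**: each rides a designated founder haplotype at a target
  frequency (defaults in the 2–9% range where segregating cattle
  lethals are found), acting at conception or at birth with a
  penetrance. Pedigree individuals are survivors, so a homozygous
  conceptus is redrawn with probability equal to the penetrance — no
  genotyped adult is homozygous for a fully penetrant lethal, by
  construction. Because a handful of AI sires per generation is a
  severe bottleneck, drift would regularly lose the allele; the
  gene-drop is therefore redrawn (up to 25 times) until the realized
  frequency is within a factor of two of target. This conditions on
  the stated world — a lethal *currently segregating* near its target
  frequency — and is applied before any statistic is computed.
* **Phenotypes**: per-insemination conception with background failure
  $f = 0.32$ (a realistic non-return failure for AI dairy records;
  the source analysis computes $f$ from data but never prints it),
  cow-level additive genetic and permanent-environment effects dropped
  down the pedigree, a small seasonal term, re-insemination after
  18–24 days, calving at 278–284 days. Stillbirth uses a linear
  liability: baseline 26% for heifer calvings and 9.2% for later
  parities, plus maternal and direct breeding values, permanent
  environment, a +0.03 male-calf effect and season, clamped to
  [0.005, 0.98]. Variance components default to the magnitudes
  reported for these traits on the observed scale (stillbirth additive
  ≈ 0.015–0.016 vs residual ≈ 0.162; fertility additive ≈ 0.0039 vs
  residual ≈ 0.22). Twins (2%) and recorded abortions (0.5%) exist so
  the record filters have work to do.

What a green test does establish: the statistics recover planted
lethals with the advertised power, the filters implement the stated
rules, REML recovers known variance components, and the null
calibrations (logistic type-I error, GWAS p-value uniformity) hold.
What it does not: concordance with any licensed real data, realistic
linkage disequilibrium beyond window scale, genotyping error beyond
random missingness, or selection/inbreeding dynamics.

# Numerical and interface choices

* Zero-homozygote probabilities are computed as
  $\exp(N\log(1-p^2))$ to survive $N \sim 10^5$, $p^2 \sim 10^{-3}$.
* Expected homozygote counts are kept at full precision and rounded
  half-up only for display in the integer evidence column.
* The carrier frequency in the random-mating expectation is $C = 2p$
  without a Hardy–Weinberg $(1-p)$ correction — the only reading under
  which the published expected counts reproduce from the printed
  frequencies (e.g. $0.06178^2 \times 20{,}557 \approx 78$).
* Age in months is $\lfloor \text{days}/30.4375 \rfloor$; "more than
  19 and less than 37 months" becomes 20–36 whole months.
* CR success (IFL 0–4 days) checks the 260–302-day calving window from
  the *first* insemination; CR failure with IFL ≥ 5 checks it from the
  *last* insemination, where conception actually happened — the only
  reading consistent with the worked failure example (two
  inseminations 30 days apart, calving 280 days after the second).
* Service periods are delimited by calvings; inseminations after the
  last calving form a final open period. Lactation-2/3 records are
  dropped when any earlier lactation's period is absent.
* Year–month cells below 5 records merge into the nearest preceding
  month before the logistic fit, keeping the design full rank on
  synthetic data.
* Mating-type contrasts use type 4 as the reference level so the
  solutions are directly the deviations from the carrier×carrier
  class; only sire × MGS classification is used (records with
  genotyped dams are not reclassified — the mating-type definition
  requires the MGS route).
* Haplotype ids are `hap<window>-<rank>` (genome-wide window index,
  within-window frequency rank). The scheme is documented, without
  claiming identity to any external phasing software's numbering.
* The 75- and 25-marker scans are reported separately; no merged list
  is constructed.
* Whether the published expectation used all genotyped animals or only
  those non-missing per window is not stated; recomputation matches
  the former, so the per-window $N$ is reported alongside for
  transparency.
* File dialects: phased VCF (GT with `|`; `/` is a phase error naming
  the line) and a two-row-per-individual haplotype-matrix TSV with a
  `<path>.map` sidecar, since that dialect has no room for map
  metadata. Results TSVs have documented stable column orders and
  round-trip losslessly at 10 significant digits.

# Known limitations

* Phasing is consumed, not performed; phase errors in real input would
  propagate into window haplotype calls.
* The two-stage GWAS refits no variance components per marker; under
  strong single-marker effects the test is slightly conservative.
* The REML engine computes dense MME inverses for traces; it is sized
  for desk-scale problems (a few thousand equations), not national
  evaluations.
* Incomplete penetrance is simulated but not estimated; effect models
  test one haplotype at a time.
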