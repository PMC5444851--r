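---
title: "Models and methods: crossover landscapes and interference in meiorec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: crossover landscapes and interference in meiorec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiorec)
```

`meiorec` analyses meiotic crossovers (COs) scored in backcross progenies:
each progeny inherits one recombinant chromatid per chromosome from the
hybrid parent, and every allele transition between adjacent markers reveals
one CO. This vignette is the package's account of the models behind each
stage, the parameters that matter, and the numerical decisions taken where
the methods literature leaves choices open.

## The two-pathway model of crossover formation

COs arise through two pathways. Class I COs (ZMM/MLH1-dependent) interfere:
a CO inhibits further COs nearby, making inter-CO distances more regular
than random. Class II COs (MUS81-dependent) are insensitive to interference
and contribute a minority of events in most plants. The package models a
bivalent's COs as the superposition of

* a **stationary gamma renewal process** for Class I: inter-event distances
  are i.i.d. Gamma with shape $\nu$ and mean $100/(2(1-p))$ cM, so that
  after chromatid thinning the gamete map-length identity holds (one CO per
  100 cM of gamete map, i.e. two per 100 cM on the bivalent). $\nu = 1$
  gives a Poisson process (no interference); as $\nu$ grows the coefficient
  of variation of inter-CO distances, $1/\sqrt{\nu}$, shrinks and spacing
  becomes regular;
* an independent **Poisson "sprinkling" process** for Class II with density
  $2p$ per 100 cM, so $p$ is the expected proportion of all COs formed
  through the non-interfering pathway.

Boundary and transmission conventions, chosen where the model family is
silent:

* **Stationary start.** The first Class I event sits at the equilibrium
  forward-recurrence distance from the chromosome start: a $U(0,1)$
  fraction of a length-biased interval, and the length-biased version of a
  Gamma($\nu$) law is Gamma($\nu+1$) with the same scale. This removes edge
  artifacts without burn-in.
* **No obligate CO.** Zero-CO bivalents are allowed; the gamma model as
  used here has no obligate-CO constraint, and the package does not add
  one.
* **No chromatid interference.** Each bivalent CO involves two of the four
  chromatids, so a given chromatid carries it with probability 1/2,
  independently across COs (`thin_to_gamete`). Consequently per-meiosis CO
  counts are exactly twice per-gamete counts, which is how
  `summarize_counts` reports both scales.

## The synthetic data generator

`scenario_preset` fixes two contrasting parameter sets that emulate the
diploid and allotriploid study conditions the package targets:

| preset | genome map | $\nu$ | $p$ | Marey shape |
|---|---|---|---|---|
| `"diploid"` | 700 cM (14 COs/meiosis) | 5 | 0.05 | pericentromere-suppressed |
| `"allotriploid"` | 1970 cM (2.8-fold longer) | 1.3 | 0.10 | flat |

The physical frame is a synthetic ten-chromosome genome at the scale of the
*Brassica rapa* A genome (~255 Mbp; chromosome sizes are synthetic
approximations), with ~204 markers at ~1.25 Mbp mean spacing, terminal
markers anchored at the chromosome ends and interior positions jittered.
The diploid preset's $p$ sits in the few-percent range typical of diploid
plants, and its genetic lengths give about one to two COs per chromosome
per meiosis; the allotriploid preset's weak interference and flat Marey map
reproduce the qualitative signatures of hybrids carrying an unpaired extra
genome: more COs, crossovers through the pericentromeres, and a
near-Poisson spacing.

The Marey function maps physical to genetic coordinates. The suppressed
shape uses a local rate proportional to $\varepsilon + ((x-c)/S)^2$
($c$ the centromere position, $S$ the chromosome size,
$\varepsilon = 0.01$): essentially zero recombination at the centromere and
the highest rates distally. The flat shape is linear.

What the generator deliberately does **not** emulate: genotyping error
(calls are error-free; QC paths are exercised with constructed fixtures),
segregation distortion, marker dropout, hotspot-scale rate variation below
the marker spacing, chromatid interference, and obligate-CO enforcement. A
green test suite therefore demonstrates correctness of the statistical
machinery under the stated model, not robustness to every artefact of real
genotyping data.

Reproducibility: `simulate_population` seeds a master stream from the
scenario seed and draws one sub-seed per attempted gamete, so populations
are byte-identical across runs, including when viability selection discards
attempts.

Detectability: two COs falling in the same marker interval cancel and are
invisible to calling, so called counts under-estimate truth by an even,
non-negative per-interval deficit (a property the tests assert). The effect
is negligible for the diploid preset (~3.6 cM mean interval) and a few
percent for the allotriploid one (~10 cM mean interval), which is why the
allotriploid preset's *called* map is somewhat shorter than its nominal
1970 cM — real maps are detection-limited in exactly the same way.

## Crossover calling, maps and landscapes

Marker order is fixed by physical position; the per-interval recombination
fraction $r$ (fraction of progeny with discordant flanking calls) is
converted to centimorgans with the Kosambi function
$d = 25\,\ln\!\big(\tfrac{1+2r}{1-2r}\big)$, and CO positions are interval
midpoints in both frames. Degenerate inputs: an interval with $r \ge 0.5$
(possible in tiny samples) is capped at $r = 0.49$ with a warning rather
than failing, and flagged in the interval table; markers with no
informative calls yield `NA` segregation tests rather than silent removal.
Failing segregation markers are reported, never auto-removed.

Landscape comparisons:

* **Heterogeneity tests** are 2-by-2 chi-squared tests without continuity
  correction. At interval scope the table is (COs, gametes without a CO in
  that interval) by population. At chromosome and genome scope — where the
  literature does not spell out the table — the package uses total COs
  against total scored gamete-intervals minus COs. Bonferroni divisors are
  the per-chromosome interval count (chromosome scope) or the genome-wide
  interval count (interval and genome scope).
* **The equal-count shape test** pools both populations' CO physical
  positions per chromosome, cuts them into 10 bins of equal pooled counts,
  and compares per-population bin counts by chi-squared; normalising by
  each population's total makes it a *shape* comparison, invariant to
  scaling either population. Because called CO positions are interval
  midpoints, ties are massive; ties are broken uniformly at random in the
  pooled ranking (a deterministic stable break provably biases the null —
  tied values of the first population would always land in earlier bins —
  while the random break keeps the null p-value distribution calibrated,
  as the test suite checks on random halves of one population). Fewer
  pooled COs than bins reduces the bin count with a warning. Per-bin
  binomial confidence intervals are Clopper-Pearson. The "ALL" analysis
  sums the ten per-chromosome chi-squared statistics and degrees of
  freedom.
* **Regressions** are ordinary least squares; for the
  centromere-distance mode, relative distance is measured from the nearest
  centromere edge and normalised per chromosome arm, in percent. Only the
  leading coefficient's p-value is reported.

## Model-free interference: ICDs, shuffle null, KL index

Inter-crossover distances (ICDs) are computed per progeny chromosome with
at least two COs and never across chromosome boundaries; pooled analyses
concatenate per-chromosome ICDs. Interference shows up as a deficit of
small ICDs and reduced ICD variance.

The **no-interference null** re-draws, per plant and chromosome, the
plant's CO count of positions from the chromosome's pooled CO position
list (with replacement; a draw with two identical positions is discarded
and repeated, up to 1000 attempts before an explicit failure). This
preserves per-plant CO counts and the marginal position distribution while
destroying within-plant spacing — exactly the interference signal. The
default of 1000 shuffle replicates makes the null distribution smooth
relative to experimental sample sizes of a few hundred ICDs.

The **KL interference index** is the plug-in divergence
$\mathrm{KL}(P\|Q) = \sum_i p_i \ln(p_i/q_i)$ between experimental and null
ICD distributions on shared fixed-width bins (default 5 cM from 0 to the
common maximum; the width is an argument). Empty experimental bins
contribute zero; a bin with null mass zero but experimental mass positive
is merged into its right neighbour until the null mass is positive, which
keeps the index finite without inventing pseudocounts. The logarithm is
natural: indices are in nats. With 5 cM bins and a few hundred ICDs the
index of a truly non-interfering population is close to but not exactly
zero (plug-in estimators are positively biased at finite sample size); the
calibration tests bound it below 0.02 under the no-interference preset.

The **permutation test** on the difference of two KL indices re-partitions
the pooled ICD list into groups of the original sizes (a true
re-partition, without replacement), scores each group against the weighted
average of the two populations' null distributions (weights = the
proportions of the group's ICDs actually drawn from each population), and
repeats; both one- and two-sided p-values include the observed score in
the null set, so they are never exactly zero and never below
$1/(\text{reps}+1)$. Both populations' nulls are generated from the same
RNG state, so comparing a population with itself scores exactly zero. The
default is $10^6$ re-partitions for final inference; the package's tests
and acceptance script use $10^3$–$10^4$, which is ample for the effect
sizes involved.

## Post-meiotic selection: the truncated-Poisson bound

If gametes are viable only with at least $X$ COs genome-wide, and the
pre-selection count is Poisson($\lambda$) with $\lambda = L_G/100$, the
post-selection mean is the truncated mean $E[k \mid k \ge X]$.
`required_selection` finds the smallest integer $X$ whose truncated mean
reaches the target $L_G'/100$ and reports the viable fraction
$P(k \ge X)$. Note the boundary case: the truncated mean at $X = 0$ equals
$\lambda$ exactly, so any strictly larger target forces $X \ge 1$. Tail
sums run in log space up to $\lambda + 40\sqrt{\lambda} + 100$, summed in
increasing order of magnitude — exact far beyond double precision, and
validated against direct pmf summation at $10^{-12}$ tolerance. Since
interference narrows the count distribution, the Poisson assumption is
conservative: the true required selection would be even more severe, so
the reported fraction is an upper bound. The package reports the bound
side by side with whatever survival proxies are observed (pollen
viability, relative seed set) and leaves the verdict to the analyst beyond
the order-of-magnitude contrast.

## Fitting the two-pathway model

`fit_gamma_sprinkling` estimates $(\nu, p)$ per chromosome by maximising a
**simulated composite likelihood**: for each candidate parameter pair the
generator simulates a large gamete sample at the chromosome's observed map
length (held fixed — a profile over length, not a joint fit), and two data
summaries are scored against their simulated analogues by multinomial
log-likelihood: the per-gamete CO-count distribution and the binned ICD
distribution (5 cM bins). A 0.5 pseudocount per simulated category keeps
the objective finite. Optimisation is Nelder-Mead over
$(\log\nu, \operatorname{logit} p)$, seeded from a
$\{0.8, 2, 5, 12\} \times \{0.01, 0.1, 0.25\}$ grid, with bounds
$\nu \in [0.2, 50]$, $p \in [0, 0.5]$ enforced by penalty; the same
simulation seed is reused at every objective evaluation (common random
numbers), which removes simulation jitter from the objective surface.
Fewer than 50 informative gametes triggers a warning, and non-convergence
is flagged, never silent. Defaults: 20,000 simulated gametes per
evaluation, two Nelder-Mead starts; the tests and acceptance script use
8,000–10,000 and one start, settings under which the recovery checks
(e.g. data at $\nu = 10, p = 0.1$) were calibrated.

Two identifiability notes. At $\nu \approx 1$, $p$ is unidentifiable —
Class II events are indistinguishable from non-interfering Class I events
— so fitted $p$ on weak-interference data is essentially unconstrained
while $\nu$ remains well determined. And on short chromosomes with few
multi-CO gametes the ICD summary is sparse, so per-chromosome $\hat\nu$ is
noticeably noisier (and upward-biased) relative to a single long
chromosome with the same total CO count; the mean-interference test below
averages over chromosomes partly for this reason.

**Confidence intervals** (`ci_by_resimulation`) are a parametric
bootstrap: simulate datasets of the original size at the fitted
parameters, refit, and take the 2.5/97.5 percentiles, widened if needed to
bracket the point estimate; more than 20% refit failures flags the bounds
as unreliable.

**Mean interference comparison** (`mean_interference_test`): with
per-chromosome strengths paired across two crosses, the score is the
difference of the two 10-chromosome means; under the null the members of
each pair are exchangeable, so all $2^{10} = 1024$ within-pair swaps give
the exact null distribution (the identity swap included, hence
$p \ge 1/1024$). For pooled analyses with more pairs the test samples
random swap patterns instead ($10^5$ by convention for 30 pairs).

## Problem sizes and runtime envelope

All sizes are package choices balancing Monte-Carlo precision against
runtime: preset populations of 100–400 progeny (matching the 109–429 range
typical of backcross designs), 10,000-gamete samples for distributional
calibration checks, 1000-replicate shuffle nulls, $10^3$–$10^4$
permutations in tests with the $10^6$ default reserved for final
inference, and 16–20 bootstrap refits in the interval-coverage tests. The
acceptance script (`scripts/acceptance.R`) recomputes the headline
quantities in under a minute on one core.

## Known limitations

* The composite likelihood is not the exact thinned-gamma likelihood;
  fitted values are consistent in simulation-recovery tests but the
  objective is a documented package choice, not a literature standard.
* Mechanical (stress-relaxation) interference models are out of scope; the
  interference strength fed to the comparison test is always the gamma
  $\nu$.
* The XLSX converter expects one sheet per population with marker metadata
  columns followed by progeny columns, and requires the allele-code
  dialect to be declared — it refuses to guess.
* Whole-progeny exclusion is the default missing-data policy; per-
  chromosome retention is available but changes sample sizes per
  chromosome and is not used by the presets.
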