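---
title: "Four-point analysis of crossover interference: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Four-point analysis of crossover interference: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fourpoint)
```

## The problem

Meiotic crossovers (COs) do not occur independently along a chromosome: a
CO in one interval suppresses — or, in some genomes, promotes — COs in
nearby intervals. The classical summary of this phenomenon is the
coefficient of coincidence (CoC), the ratio of the observed frequency of
multi-interval recombinants to the frequency expected if the intervals
recombined independently. `fourpoint` implements a four-locus version of
this analysis for full-sib families of outbred (highly heterozygous)
parents, the standard design in forest trees where inbred lines do not
exist: both parents are modelled as quadruply heterozygous `ABCD/abcd`
individuals, and every group of four consecutive mapped markers yields six
recombination fractions and four coincidence coefficients, including a
triple-interval coefficient that measures interference across three
consecutive intervals at once.

## The gamete algebra

For a window of four ordered markers A-B-C-D, a gamete is classified by the
crossover-indicator triple over the intervals (A-B, B-C, C-D). This gives
eight *gamete types* `g000 ... g111`; each type contains the two
complementary gametes (e.g. `ABCD` and `abcd` for `g000`), which are
equifrequent by meiotic symmetry, so the sixteen concrete gametes carry
probability $g_t/2$ each. Pairwise recombination fractions are sums of
the four types recombinant for that pair, e.g.

$$r_{AB} = g_{111}+g_{110}+g_{101}+g_{100}, \qquad
  r_{AD} = g_{111}+g_{010}+g_{100}+g_{001},$$

(the non-adjacent fractions count indicator *parity*, because two
crossovers cancel). The coincidence coefficients are

$$C_1 = \frac{g_{111}+g_{110}}{r_{AB}\,r_{BC}}, \quad
  C_2 = \frac{g_{111}+g_{011}}{r_{BC}\,r_{CD}}, \quad
  C_3 = \frac{g_{111}+g_{101}}{r_{AB}\,r_{CD}}, \quad
  C_4 = \frac{g_{111}}{r_{AB}\,r_{BC}\,r_{CD}}.$$

$C = 1$ means no interference, $C < 1$ positive interference, $C > 1$
clustering of crossovers. Two conventions are worth stating explicitly:

* **Zero denominators.** When an interval's $r$ is zero, a coefficient is
  reported as 0 if its numerator is also 0, and as `NA` ("undefined")
  otherwise; undefined values are excluded (and counted) by every
  downstream summary. For frequencies that actually come from a valid
  gamete distribution the undefined case cannot arise — the numerator
  types are subsets of the denominator sums — but the sentinel keeps the
  convention total for user-supplied tables.
* **$r$ is not truncated.** The four-term sums can exceed 0.5 for
  repulsion/unlinked configurations, and printed linkage-scan tables do
  show 0.50–0.51; we report the algebraic value untouched.

## Estimating gamete frequencies

Which estimator applies depends on the markers' segregation type.

**Testcross-informative windows** (`lm_ll`, heterozygous in the first
parent; `nn_np`, in the second): each offspring genotype reveals the
informative parent's gamete directly (heterozygous call = one allele,
homozygous = the other). Decoding the four calls gives a concrete gamete,
which collapses to its type; $\hat g$ is the vector of type proportions.

**Intercross-informative windows** (`hk_hk`, heterozygous in both
parents): parental origin is confounded. The 256 ordered gamete pairings
collapse to 81 identifiable genotype classes (code per locus: number of
parental-phase alleles, 2/1/0); heterozygous classes are mixtures of
several gamete-type products. The package builds the class table by
exhaustive enumeration — never from a transcribed table — and fits the
class counts by EM: the E-step distributes each class count over its
contributing ordered pairings in proportion to current probabilities, the
M-step divides expected type totals by the $2n$ parental draws. One
frequency vector is shared by both parents, matching the symmetric
products of the full-sib design; the data cannot cleanly separate
per-parent vectors in `hk_hk` windows, and carrying two vectors is left to
the simulator, which supports asymmetric parents.

Numerical choices: initialization is uniform ($g_t = 1/8$; phase-agnostic,
and empirically the likelihood surface for these mixtures shows no
local-optimum problems across thousands of random truths), or any
user-supplied vector. An initialization from moment-estimated interval
$r$'s was considered and dropped: there is no standard moment estimator of
$r$ for four-locus intercross data, and uniform EM converges in tens of
iterations anyway. Convergence is `max |change in g| < 1e-8` or 5000
iterations; the log-likelihood trace is returned and asserted
non-decreasing in the tests. If an observed class ever acquires model
probability below `1e-300` (possible after a boundary excursion), the
estimate is jittered once toward the interior with a seeded draw rather
than letting `log(0)` occur. Boundary estimates ($\hat g_t = 0$) are
reported as converged: they are meaningful (complete interference).
Windows mixing segregation types are skipped with a recorded reason — no
likelihood is defined for them here.

## The genome scan and regional analysis

The scan cuts each linkage group into consecutive disjoint four-marker
windows (matching the analysis unit of four markers per group; a stride-1
sliding scheme is available), estimates each window, and emits one record
with $r$'s, $C$'s, the method used and the window's representative
position — the midpoint of its outer markers, a choice this package makes
explicitly since none is standard.

Regional comparisons divide each linkage group's cM span into three
equal-length parts NO.1/NO.2/NO.3 (half-open intervals, last closed) and
compare interference-strength distributions with

$$\delta = \sum_{i=1}^{N} |p_{i1} - p_{i2}| \in [0, 2],$$

the L1 distance between histograms on shared bin edges: 0 for identical
binned distributions, 2 for disjoint support. $\delta$ depends on the
binning, which no convention fixes; the default is 10 equal-width bins
over the pooled range of the two regions being compared, and the binning
is recorded in every report. Because "sum of difference values" can also
be read unnormalized, a `method = "counts"` variant (sum of absolute
bin-count differences) is provided behind the same interface; the
proportion-based $\delta$ is the default. Interference strength defaults
to $C_4$ (the high-dimensional coefficient) and can be switched to
$C_1$–$C_3$.

Chromosome-level summaries are five-number statistics plus the mean of the
defined strength values per linkage group, with quartiles by linear
interpolation of order statistics (R's type 7) — stated because IQRs are
convention-dependent. The length–interference relationship is fitted by
OLS of mean strength on genetic length (max − min marker position),
separately for a named group of chromosomes and the remainder, with
outlier chromosomes excluded from both fits.

## The simulator and what passing tests mean

The simulator is parameterized at the window level: each four-marker
window gets a true gamete-frequency vector, either supplied directly, or
inverted from a target $(r_{AB}, r_{BC}, r_{CD}, C_1..C_4)$ via
$g_{111} = C_4 r_{AB} r_{BC} r_{CD}$, $g_{110} = C_1 r_{AB} r_{BC} -
g_{111}$, …, $g_{000} = 1 - \sum$. Not every printed $(r, C)$ combination
is feasible — the inversion rejects any negative entry by name, and indeed
some published extreme-CoC rows fail this screen while others
(surprisingly, even $C_4 \approx 177$ at $r \approx 0.02$–0.04) pass.
Offspring are formed by drawing one maternal and one paternal gamete from
the 16-gamete expansion and encoding them per segregation type.

Default study geometry echoes a forest-tree full-sib design: 19 linkage
groups from 530 down to 130 cM, 40 equally spaced markers each, family
size 408, windows cycling through the three segregation types, and
per-window truths drawn from a Dirichlet concentrated on `g000`
(interval $r$'s of a few percent, CoC scattered above and below 1 — the
regime real scans report). The marker count per group is kept at
desk scale rather than the thousands of a RAD map; that choice affects
only how many windows exist, not any per-window property.

What the simulator does *not* emulate: genotyping error (calls are
error-free), segregation distortion, a continuous chiasma process along
the chromosome (windows are independent, so between-window interference
correlation is absent by construction), and map-construction uncertainty
(marker order and positions are taken as given). Passing recovery tests
therefore demonstrates correctness of the estimators and summaries under
the stated four-locus model, not robustness to miscalled genotypes or
misordered maps.

## Test design

Statistical acceptance checks are sized so that a failure indicates a
defect, not bad luck, at fixed seeds chosen before the checks were run:

* EM/direct recovery tolerances (max-abs error 0.01 at family size
  50,000) sit at ~6 binomial standard errors.
* The recovery check of a $C_4 = 5$ truth at $r = (0.02, 0.04, 0.02)$
  uses $5\times10^6$ testcross meioses, set by a ~5σ rule: $g_{111} =
  8\times10^{-5}$, so tens of thousands of meioses would leave the
  relative error of $\hat C_4$ near 50% and a 25% band would be a coin
  flip.
* Joint checks over many components use widened per-component bands
  (4 SE over 81 genotype classes; a ≥94/100-seed pass rate where 8
  components are tested jointly at 3 SE).
* The pipeline-recovery scenario (19 groups, family size 408, testcross
  windows, baseline $C_4$ rising 1→11 with chromosome length and the
  middle third elevated by +10) pools windows of all chromosomes by
  region for the directional $\delta$ comparison — per-chromosome regions
  hold only two windows at this marker density — and assigns chromosome
  lengths in a fixed permuted order so both fitted groups span the length
  range. Power was checked by pilot simulation before freezing the
  scenario.

## Known limitations

* Per-window $C_4$ at family size ~400 is heavy-tailed whenever the
  interval $r$'s are small: the denominator is a product of three small
  estimates, so individual windows can print enormous coefficients.
  Chromosome- and region-level aggregation, not single windows, carries
  the signal; this is also the likely origin of extreme printed CoC
  values in real scans.
* No standard errors or likelihood-ratio tests are attached to the
  coefficients; the regional $\delta$ and the fits are descriptive.
* Coupling phase (`ABCD/abcd`) is assumed known from map construction;
  the package performs no phase inference, and no map-distance functions
  (Haldane/Kosambi) are involved anywhere — everything is expressed in
  recombination fractions.
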