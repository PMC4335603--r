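---
title: "Models and methods behind transpoly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind transpoly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transpoly)
```

# The model

`transpoly` analyses the footprints of a biallelic polymorphism kept
segregating by balancing selection for so long that it predates the split of
two species, so that both species carry the same two alleles identical by
descent. The demography is deliberately minimal: an ancestral panmictic
species of constant diploid size $N_a$ splits $T$ generations ago into two
descendant species of size $N_e$ each, with no gene flow afterwards. At the
selected site, allele $A_1$ sits at a constant equilibrium frequency $p$
(and $A_2$ at $q = 1-p$) in every population from the moment the derived
allele $A_1$ arose, $T_S$ generations before the coalescence of the class
ancestors; there is no later mutation at the selected site, so no allele
turnover. Time is measured backwards in generations and a population of $N$
diploids coalesces pairs of lineages at rate $1/(2N)$.

Backward in time the two allelic classes behave like demes of a structured
coalescent: lineages carrying the same allele coalesce within their class,
and a lineage changes class only through a crossover between the selected
site and the focal neutral site, which drops the neutral site onto a random
background — class $A_1$ with probability $p$. A neutral site at genetic
distance $d$ Morgans therefore "migrates" out of class $A_1$ at rate $d\,q$
per generation and out of $A_2$ at rate $d\,p$.

For a sample containing both alleles from both species, the genealogy of
the region around the selected site factors into three stages: (I) the
sampled lineages within each species and class coalesce down to one lineage
per class per species; (II) those four lineages coalesce into the two class
ancestors, which requires crossing the species split and takes $T + t$
generations, where $t = \max(t_1, t_2)$ and $t_1 \sim
\mathrm{Exp}(1/(2N_ap))$, $t_2 \sim \mathrm{Exp}(1/(2N_aq))$ are the
within-class coalescence times in the ancestral species; (III) the two
class ancestors coalesce, which cannot happen before the derived allele's
origin.

# The length of the ancestral segment

The *ancestral segment* is the region whose genealogy still clusters by
allele rather than by species. On each side of the selected site it is
eroded by the nearest class-switching crossover accrued during stage II.
Our exposure convention treats all four stage-II lineages as exposed for
the whole duration $T + t$: each lineage switches at rate (opposite class
frequency) per Morgan per generation, and the four opposite-class
frequencies sum to $2(p + q) = 2$, so conditionally on $t$

$$X \mid t \;\sim\; \mathrm{Exp}\!\left(2(T+t)\right) \quad
  \text{(per Morgan)},$$

independent of $p$. This convention double-counts the interval between the
first and second class coalescence (after the first class has found its
ancestor, fewer than four lineages remain); the resulting mean is a few
percent short of the exact event process, a bias we quantify below and
accept for the closed form it buys. Marginalising over $t$ uses only the
Laplace transform $M(s) = E[e^{-st}]$ of the density of $\max(t_1,t_2)$,
giving closed forms for the survival function $S(x) = e^{-2Tx}M(2x)$, the
density, and the mean
$\int_0^\infty S$, the latter in terms of the exponential integral $E_1$
(evaluated through `pracma`, with a continued-fraction tail so that very
old splits do not overflow). Quantiles are solved from $S$ by root finding
to relative tolerance $10^{-8}$. Lengths are kept continuous; conversion
between Morgans and base pairs uses the per-bp recombination rate $r$.

```{r length}
d1 <- one_sided_length(Na = 5e4, T = 2.5e5, p = 0.5, r = 1.2e-8)
c(mean_bp = mean(d1), q95_bp = quantile(d1, 0.95))
```

Erosion on the two sides is treated as independent, so the total length is
the self-convolution of the one-sided law, computed on a regular grid
(default spacing 0.05 bp-equivalents) with the mean pinned exactly at twice
the one-sided mean; the grid mean agrees to $10^{-3}$ relative, which is
the accuracy the convolution is asked to certify. In truth the two sides
share the same $t_1, t_2$, so they are only conditionally independent; the
convolution inherits that approximation deliberately, keeping the two-sided
law a pure functional of the one-sided law.

The distribution is insensitive to $p$ (the dominant erosion happens while
there are two species, at rates that do not involve $p$) and shrinks
exponentially with $T$: with $N_a = 10^6$ and $T = 2\times 10^7$
(a *Drosophila*-like regime) the one-sided mean is about 2 bp. Usable
footprints therefore require $N_e \ll T \ll 1/r$.

# Coalescent times and shared neutral SNPs

Neutral polymorphisms shared identical by descent arise from mutations on
the two stage-III branches, so their expected number at distance $d$ is
$2\mu\,E[T_B(d)]$ per site, where $T_B$ is the coalescence time of the two
class ancestors at the neutral site.

For an infinitely old polymorphism, first-step analysis of the two-deme
island model (deme sizes $pN_a$, $qN_a$; switching hazards $dq$, $dp$; no
coalescence across classes) gives the linear system solved by
`island_model_times()`: $T_B \to \infty$ as $d \to 0$ and all three
expectations approach $2N_a$ as $d$ grows.

For a polymorphism of finite age $T_S$ we follow a discrete-generation
absorbing Markov chain. During the selection phase the two lineages are in
one of the states $(1,1)$, $(0,2)$, $(2,0)$, $(*)$ (counts of lineages on
the derived and ancestral backgrounds, with $(*)$ = coalesced); the
per-generation matrix combines switching ($dq$, $dp$; $2dp$, $2dq$ for the
doubled states) and within-class coalescence ($1/(2N_aq)$, $1/(2N_ap)$).
At the phase boundary the bridge matrix sends $(2,0)$ to $(*)$: both
lineages still carrying the derived allele must coalesce at its origin,
because forward in time the allele jumped to frequency $p$ when it arose.
The neutral phase is a single geometric step with rate $1/(2N_a)$.
`expected_tb_numeric()` accumulates the survival probabilities of the
transient chain over the $T_S$ generations with binary power-sums
($O(\log T_S)$ $3\times3$ multiplications), then closes the neutral tail
analytically with $2N_a$; a plain generation-by-generation iteration is
kept as an independent route and the two agree to $10^{-8}$ relative. A
closed-form approximation (`expected_tb_approx()`) drops recombination
once the chain leaves $(1,1)$ — the selection-phase matrix becomes upper
triangular and everything reduces to geometric sums. Because excursions
back to $(1,1)$ (where coalescence is impossible) are dropped, the
approximation can only underestimate; within the segment scale
($d < 1/(2T_S)$) it stays within 5% of the numeric value.

`expected_shared_snps()` combines the pieces: the expected total count is

$$1 + \sum_{\text{sides}} \sum_{i \ge 1} \Pr(X > i\,\text{bp}) \cdot
  2\mu\,E[T_B(r\,i)],$$

with the inclusion probability from the one-sided survival function
(`mode = "marginal"`), or an indicator for a fixed segment length
(`mode = "fixed"`). An age measured from the present is converted to $T_S$
by subtracting the expected span of stages I and II, $T + E[\max(t_1,t_2)]$
(stage I occupies the most recent part of the species phase, so it adds no
extra span for any sample size; an optional `include_stage1` adds $4N_e$
for users who prefer the more conservative conversion). Full ancestry
simulations at $N_a = 5\times10^4$, $T = 2.5\times10^5$, $T_S = 6\times
10^5$, $\mu = r = 1.2\times10^{-8}$ give a segment-restricted shared-SNP
count within one standard error of this formula.

One sensitivity deserves emphasis: the per-site factor $2\mu E[T_B]$
counts mutations on *both* stage-III branches and the sum runs over *both*
sides of the selected site. Counting a single branch, or a single side,
halves the expected count. We use the two-branch, two-sided form because
it is what the pairwise coalescent dictates and what our own simulator
reproduces; analyses that quote roughly half these values are consistent
with a one-sided count.

# LD among shared SNPs

For a minimal sample of four chromosomes (one per class per species) every
shared neutral SNP in the ancestral segment is in perfect LD with the
selected site in both species — there are only two haplotypes. In larger
samples the distal part of the segment (recombination in stage I but not
stage II) admits more haplotypes, so LD weakens with sample size and with
distance, though it stays strong within the expected segment.
`pairwise_ld()` implements the standard $D$, $D'$, $r^2$ on phased
haplotype counts; `ld_significance()` uses the 1-df $\chi^2 = n r^2$
without continuity correction (phased chromosomes are the sampling unit);
`coupling_phase()` compares the sign of $D$ across species under a common
allele labelling. The stage-I retention probability $R_n$ — the chance
that a sampled lineage keeps its allelic identity until its class's
within-species ancestor — is estimated by simulating the class coalescent
with switching; the closed-form slot uses the Laplace transform of the
class $T_{\mathrm{MRCA}}$, $\prod_k \lambda_k/(\lambda_k + dq)$, which
ignores the feedback of switched lineages on the coalescent and therefore
never overestimates the simulated retention (the tests enforce exactly
that one-sided contract).

# The conditional simulator

`simulate_sample()` runs a multi-site structured coalescent conditioned on
the trans-species polymorphism (at least one chromosome per class per
species). Ancestral material is tracked as intervals over the window;
crossovers fall uniformly on the span between the selected position and the
material hull, the selected-site piece keeps its class, and the detached
piece lands on a background drawn from $(p, q)$. Species merge at $T$; at
the derived allele's origin (default $T + T_S + E[\max(t_1,t_2)]$, i.e.
$T_S$ generations before the *expected* end of stage II) all remaining
derived-class lineages coalesce, and a single class of size $N_a$ remains.
Event waiting times are exponential — the continuous-time limit of the
per-generation chain, which at these rates differs negligibly and is what
standard coalescent machinery uses. Every coalescence records marginal-tree
edges per interval, so the sample decomposes into non-recombining segments
with one genealogy each; infinite-sites mutations are dropped per segment
with Poisson counts on branch lengths. Topologies are classified per
segment: *ancestral* (both classes monophyletic), *one-recombined*
(exactly one species monophyletic), *species-short*/*species-long* (both
species monophyletic, split at a reporting threshold of $4N_a$ generations
past the split, mirroring whether the two species lineages carried the
same allele), and a residual *other* for transiently tangled states.
Simulated windows reproduce the expected mosaic: an ancestral core flanked
by one-recombined segments before any species-clustered state appears.

The realized segment extent (`ancestral_segment_extent()`) is measured
from the logged class-switch events up to the end of stage II. A cheap
stage-wise sampler (`simulate_segment_extents()`) draws from the same
event process without the ancestry bookkeeping; `rseglen()` draws from the
analytic exposure convention instead and is the Monte-Carlo oracle for the
closed-form law. The full ancestry process yields extents about 5%
shorter than both (fragmented material erodes through more independent
channels); the tests pin this gap below 12% of the mean, and the analytic
law is used in the knowledge of that bias.

The overdominance mode perturbs the constant-frequency assumption:
`simulate_overdominance_trajectory()` runs a Wright-Fisher path with
homozygote fitnesses $1 - s/(2p_{eq})$ and $1 - s/(2q_{eq})$ (equilibrium
$p_{eq}$, harmonic-mean coefficient $s$), conditioned on segregation by
rejection, and `simulate_segment_extents()` accepts the path as
time-varying class sizes, using one shared path for both descendant
species. With $2N_e s \ge 100$ the frequency is pinned near equilibrium
and the extent distribution is statistically indistinguishable from the
constant-$p$ model, which is the robustness claim the package tests: fast,
bounded fluctuations around a stable mean do not disturb the footprints.

# The recurrent-mutation null

Shared SNPs can also be identical merely by state. `simulate_neutral_pair()`
generates two-species haplotypes with no selected site under a finite-sites
flip-flop model (a recurrent hit toggles the same two alleles, so "same
segregating alleles" needs no nucleotide bookkeeping), with a configurable
fraction of hypermutable CpG-like sites (defaults: 2% of sites at 10 times
the baseline rate — round numbers of the right order for mammalian CpG
elevation). Linkage is complete within blocks (default 400 bp, the window
within which shared pairs are scored) and free between blocks; this is
exact for within-block pair detection and only blurs cross-block pairs,
and it is what keeps thousand-replicate null runs affordable. The test
suite runs the null at $10^3$ replicates of 10 kb (a scaled-down version
of a genome-wide experiment); shared pairs appear in well under 5% of
replicates and multi-pair replicates are rarer still, though the complete
within-block linkage makes CpG shared SNPs cluster somewhat more than a
full recombining model would.

Waiting for shared pairs is hopeless at realistic rates, so
`shared_pair_r2()` estimates their LD by conditioning: for each two-locus
genealogy (a two-locus ancestral recombination graph with the pair
separation drawn up to the window), it enumerates the leading-order
mutation configurations that leave a site polymorphic in both species —
one mutation on a branch whose flip segregates in both species (the
incomplete-lineage-sorting class, negligible when $T \gg N_e$), or two
mutations whose combined flip does — and samples site patterns with their
probability weights, weighting genealogies by their squared per-site
sharedness probability (the weight with which they contribute observed
pairs). The estimator was validated two ways: against brute-force
rejection sampling at scaled-down parameters, and against an independent
coalescent simulator with finite-sites mutations at the human-chimpanzee
scale. The resulting $r^2$ distribution at 50 chromosomes per species is
strongly skewed: weighted mean about 0.20, median about 0.07, with only
6-8% of pairs significantly coupled with the same phase in both species.
Location summaries of this distribution differ by a factor of about three
depending on whether the mean or the typical (median) value is quoted; the
package reports the mean and exposes the full distribution.

# The scanner

`find_shared_snps()` intersects two phased single-species VCFs on position
and requires literal REF/ALT identity (no strand-complement rescue between
closely related genomes; mismatched allele pairs are counted so systematic
strand problems surface). `cluster_and_report()` single-links shared SNPs
at the window (default 400 bp) and reports, per cluster, the span (the
distance between the two outermost shared SNPs in significant LD in both
species), SNP counts with CpG annotation from a reference FASTA, the
within-cluster coupling-phase consensus, cross-cluster phases, and whether
any detectable fixed inter-species difference falls inside the span —
with the caveat that two single-species VCFs only reveal fixed differences
at positions where at least one file has a record. Raw per-pair
chi-squared p-values are reported at the chosen level; genome-wide error
control is left to the user, since the appropriate correction depends on
the scan design. Coordinates are 0-based half-open internally and
converted from VCF's 1-based positions at the boundary; identical inputs
produce identical reports.

# Problem sizes, tolerances, defaults

The package's own test suite uses: $10^5$ Monte-Carlo draws for the
length-law oracle ($10^4$ for the distribution-level KS check at the
simulation parameters of the conditional simulator figure settings),
$10^4$ chain replicates per distance for the coalescent-time check,
250-replicate ancestry runs for extent comparisons, $10^3 \times 10$ kb
for the null rarity check, and 3000 collected pairs for the null LD
estimate. These sizes were chosen so each check resolves the effect it
asserts with a comfortable margin. Numerical tolerances that matter:
quantile root-finding at $10^{-8}$ relative; convolution grid at 0.05
bp-equivalents (mean certified to $10^{-3}$); chain dual-route agreement
at $10^{-8}$; statistical assertions at 2-3 standard errors under fixed
seeds.

# Known limitations

Gene conversion is not modelled; it would shorten apparent segments,
remove shared SNPs and weaken LD, so scans in conversion-prone regions
lose power. Allele turnover and reverse mutation at the selected site are
excluded, as are multiallelic systems with strong epistasis, balanced
polymorphisms lost in one species, and gene flow between the descendant
species; recombination-rate variation over time and hotspots are averaged
away. The null simulator's block-linkage and two-rate-class mutation model
are deliberate simplifications: they preserve within-window pair counts
and LD but exaggerate the clustering of CpG shared SNPs slightly. Passing
tests certify internal consistency of the models above on synthetic data,
not the behaviour of any particular empirical dataset.
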