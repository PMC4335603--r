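# transpoly

Footprints of ancient balanced trans-species polymorphisms in two-species
variation data.

When balancing selection maintains the same two alleles through a
speciation event, both descendant species carry the polymorphism identical
by descent and the gene genealogy around the selected site clusters by
allele instead of by species. `transpoly` provides the quantitative theory
and the simulation machinery for that scenario, for researchers designing
or interpreting genome scans for ancient balancing selection in species
pairs such as human-chimpanzee:

- the length distribution of the **ancestral segment** around the selected
  site: one-sided law with survival $S(x) = e^{-2Tx} M(2x)$ (where $M$ is
  the Laplace transform of the stage-II coalescence time
  $\max(t_1, t_2)$, $t_i$ exponential with means $2N_a p$ and $2N_a q$),
  plus its two-sided self-convolution, means and quantiles in Morgans or bp;
- the expected **coalescent time between the allelic classes** at a linked
  neutral site, from the two-island closed form (infinitely old
  polymorphism) and from a discrete-generation absorbing Markov chain over
  states (1,1), (0,2), (2,0), (\*) (finite age), with a closed-form
  upper-triangular approximation;
- the expected number of **shared neutral SNPs**
  ($1 + \sum_i \Pr(\text{site } i \text{ in segment}) \cdot 2\mu E[T_B(d_i)]$);
- **LD summaries** of shared SNPs (D, D', r², the n·r² chi-squared test,
  cross-species coupling phase, stage-I retention probability R_n);
- a **structured-coalescent simulator** conditioned on the trans-species
  polymorphism (marginal trees, topology classes, haplotypes, segment
  extents, optional fluctuating-frequency overdominance);
- a **neutral recurrent-mutation null** with CpG-like hypermutable sites,
  including a conditioned estimator of the r² distribution among SNP pairs
  shared identical by state;
- a **scanner** that applies the criteria to two phased per-species VCFs
  (shared-SNP discovery, clustering, spans, coupling phases, CpG flags).

## Worked example

Human-chimpanzee-style parameters: ancestral size 50,000, split 250,000
generations ago, equilibrium frequency 0.5, recombination 1.2e-8 per bp
per generation.

```r
library(transpoly)

d1 <- one_sided_length(Na = 5e4, T = 2.5e5, p = 0.5, r = 1.2e-8)
mean(d1)            # 131.4314  -- expected one-sided segment length, bp
quantile(d1, 0.95)  # 398.4345  -- 95% of one-sided lengths are below this
mean(two_sided_length(Na = 5e4, T = 2.5e5, p = 0.5, r = 1.2e-8))
                    # 262.8628  -- expected total segment length, bp
```

So the informative region around a selected site in this species pair is a
few hundred base pairs. How many shared neutral SNPs should it contain for
a 20-Myr-old polymorphism (1e6 generations at 20 y/generation, genome
average mutation rate)?

```r
expected_shared_snps(Na = 5e4, T = 2.5e5, p = 0.5, r = 1.2e-8,
                     mu = 1.2e-8, age = 1e6)
# 4.417312  -- expected shared SNPs including the selected one
# attr "Ts": 675000 (polymorphism age from the end of stage II)
```

And how easily can neutral recurrent mutation fake the signal? Rarely, and
with much weaker allelic associations:

```r
est <- shared_pair_r2(n_pairs = 3000, n = 50, seed = 1)
est$mean_r2          # about 0.21 -- mean r2 of recurrent shared pairs
est$median_r2        # about 0.08 -- the typical pair is far weaker
est$frac_sig_same    # about 0.06 -- significantly coupled in both species
```

In contrast, shared SNPs generated by a balanced trans-species
polymorphism sit in near-perfect LD with the selected site (r² = 1 for
minimal samples; still mostly > 0.5 at 12-24 chromosomes inside the
segment), which is the basis of the scan criteria.

A command-line wrapper is installed with the package:

```sh
Rscript inst/scripts/transpoly length --Na 50000 --T 250000
#statistic  morgans      bp
mean        1.57718e-06  131.431
q50         1.07686e-06  89.7384
q95         4.78121e-06  398.434
```

Subcommands: `length`, `coaltime`, `shared-snps`, `ld`, `simulate`,
`null`, `scan`, `fixtures` (see `transpoly` with no arguments for usage).

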