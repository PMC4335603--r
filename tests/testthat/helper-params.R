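# shared fixtures: parameter sets used across test files

hc_params <- function(...) {
  # human-chimpanzee style parameters; any argument can be overridden
  args <- utils::modifyList(list(Ne = 1e4, Na = 5e4, T = 2.5e5, Ts = 6e5,
                                 p = 0.5, r = 1.2e-8, mu = 1.2e-8),
                            list(...))
  do.call(model_params, args)
}

fig1_params <- function(...) {
  args <- utils::modifyList(list(Ne = 1e4, Na = 5e4, T = 1.6e5, Ts = 6e5,
                                 p = 0.5, r = 1.25e-8, mu = 1.2e-8, L = 10001),
                            list(...))
  do.call(model_params, args)
}

# build a hand-made marginal "tree" in the site_tree() format:
# edges as (parent, child) pairs with node times and labelled tips
fake_tree <- function(parents, times, species, cls) {
  ntip <- length(species)
  nodes <- sort(unique(c(seq_along(parents), parents[!is.na(parents)])))
  list(parent = parents, time = times,
       tips = data.frame(id = seq_len(ntip), species = species, cls = cls),
       nodes = nodes)
}

# write a phased VCF pair from a simulated sample (positions rounded up to
# unique integers), for scanner round-trips
sim_to_vcf_pair <- function(sim, dir) {
  pos0 <- floor(sim$positions)
  keep <- !duplicated(pos0)
  pos0 <- pos0[keep]
  hap <- sim$haplotypes[, keep, drop = FALSE]
  ref <- rep("A", length(pos0)); alt <- rep("G", length(pos0))
  sp1 <- sim$tips$species == 1; sp2 <- sim$tips$species == 2
  seg1 <- colSums(hap[sp1, , drop = FALSE])
  seg2 <- colSums(hap[sp2, , drop = FALSE])
  k1 <- seg1 > 0; k2 <- seg2 > 0       # records present per species
  f1 <- file.path(dir, "s1.vcf"); f2 <- file.path(dir, "s2.vcf")
  transpoly:::.write_vcf(f1, "sim", pos0[k1] + 1L, ref[k1], alt[k1],
                         hap[sp1, k1, drop = FALSE], "h")
  transpoly:::.write_vcf(f2, "sim", pos0[k2] + 1L, ref[k2], alt[k2],
                         hap[sp2, k2, drop = FALSE], "c")
  shared_truth <- pos0[seg1 > 0 & seg1 < sum(sp1) & seg2 > 0 & seg2 < sum(sp2)]
  list(vcf1 = f1, vcf2 = f2, shared_pos0 = shared_truth)
}
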