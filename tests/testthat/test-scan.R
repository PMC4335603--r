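# the two-species shared-SNP scanner

test_that("toy VCF pair: shared SNPs, exclusions, CpG and fixed differences", {
  dir <- tempfile(); fx <- generate_fixtures("toy-vcf-pair", dir = dir, seed = 2)
  sh <- find_shared_snps(file.path(dir, "species1.vcf"),
                         file.path(dir, "species2.vcf"))
  expect_equal(sh$pos, fx$truth$shared_pos0)
  expect_equal(attr(sh, "n_mismatched"), length(fx$truth$mismatched_pos0))
  rep <- cluster_and_report(sh, ref_fasta = file.path(dir, "reference.fa"))
  expect_equal(rep$snps$cpg, c(TRUE, FALSE, FALSE))
  expect_equal(rep$clusters$n_snps, 3)
  expect_equal(rep$clusters$n_noncpg, 2)
  # the fixed difference sits outside the cluster span
  expect_false(rep$clusters$fixed_diff_in_span)
  expect_true(fx$truth$fixed_diff_pos0 %in%
                transpoly:::.fixed_difference_positions(sh))
})

test_that("disjoint variant sets give an empty result", {
  dir <- tempfile(); dir.create(dir)
  transpoly:::.write_vcf(file.path(dir, "a.vcf"), "c", c(10L, 20L),
                         c("A", "C"), c("G", "T"),
                         matrix(c(1L, 0L, 1L, 0L), 2, 2), "x")
  transpoly:::.write_vcf(file.path(dir, "b.vcf"), "c", c(110L, 120L),
                         c("A", "C"), c("G", "T"),
                         matrix(c(1L, 0L, 1L, 0L), 2, 2), "y")
  sh <- find_shared_snps(file.path(dir, "a.vcf"), file.path(dir, "b.vcf"))
  expect_equal(nrow(sh), 0)
  rep <- cluster_and_report(sh)
  expect_equal(nrow(rep$clusters), 0)
})

test_that("planted cluster pattern is recovered exactly", {
  dir <- tempfile(); fx <- generate_fixtures("planted-cluster", dir = dir,
                                             seed = 3)
  sh <- find_shared_snps(file.path(dir, "cluster_sp1.vcf"),
                         file.path(dir, "cluster_sp2.vcf"))
  rep <- cluster_and_report(sh)
  expect_equal(nrow(rep$clusters), 2)
  expect_equal(rep$clusters$span, c(fx$truth$span1, fx$truth$span2))
  expect_equal(rep$clusters$phase_within, c("same", "same"))
  expect_equal(rep$between$phase, fx$truth$between_phase)
  # a single shared SNP forms a cluster of span zero
  one <- sh[1, ]
  class(one) <- class(sh)
  for (a in c("hap1", "hap2", "sp1", "sp2", "af_all1", "af_all2",
              "n_mismatched"))
    attr(one, a) <- attr(sh, a)
  r1 <- cluster_and_report(one)
  expect_equal(r1$clusters$span, 0)
})

test_that("scan recovers the simulator's shared SNPs exactly", {
  pp <- hc_params(L = 2001, selected_pos = 1000)
  dir <- tempfile(); dir.create(dir)
  sim <- simulate_sample(pp, n_per_class = matrix(3, 2, 2), seed = 17)
  vp <- sim_to_vcf_pair(sim, dir)
  sh <- find_shared_snps(vp$vcf1, vp$vcf2)
  expect_equal(sh$pos, sort(vp$shared_pos0))
  # the selected site is among them
  expect_true(floor(sim$selected_pos) %in% sh$pos)
  # reported span cannot exceed the simulated extent plus the window
  rep <- cluster_and_report(sh, window_bp = 400)
  ext <- ancestral_segment_extent(sim)
  sel_cl <- rep$snps$cluster[rep$snps$pos == floor(sim$selected_pos)]
  sp <- rep$clusters$span[rep$clusters$cluster == sel_cl]
  expect_lte(sp, sum(ext) + 400)
})

test_that("reports are deterministic for identical inputs", {
  d1 <- tempfile(); d2 <- tempfile()
  generate_fixtures("toy-vcf-pair", dir = d1, seed = 9)
  generate_fixtures("toy-vcf-pair", dir = d2, seed = 9)
  f1 <- file.path(d1, "species1.vcf"); f2 <- file.path(d2, "species1.vcf")
  expect_identical(readLines(f1), readLines(f2))
  r1 <- cluster_and_report(find_shared_snps(file.path(d1, "species1.vcf"),
                                            file.path(d1, "species2.vcf")))
  r2 <- cluster_and_report(find_shared_snps(file.path(d2, "species1.vcf"),
                                            file.path(d2, "species2.vcf")))
  expect_identical(r1$clusters, r2$clusters)
})

test_that("CpG flagging handles strands and missing context", {
  expect_true(cpg_flag("ACG"))
  expect_true(cpg_flag("CGT"))
  expect_false(cpg_flag("ATA"))
  expect_true(is.na(cpg_flag(NA)))
  expect_true(is.na(cpg_flag("A")))
})

test_that("malformed input is rejected", {
  dir <- tempfile(); dir.create(dir)
  f <- file.path(dir, "u.vcf")
  lines <- c("##fileformat=VCFv4.2", "##contig=<ID=c>",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"G\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "s1"), collapse = "\t"),
             "c\t10\t.\tA\tG\t.\tPASS\t.\tGT\t0/1")
  writeLines(lines, f)
  expect_error(read_species_vcf(f), "phased")
})
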