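# the neutral recurrent-mutation null model

test_that("no mutation means no variants", {
  x <- simulate_neutral_pair(2000, n = 10, mu = 0, seed = 1)
  expect_equal(length(x$positions), 0)
  expect_equal(ncol(x$hap1), 0)
})

test_that("within-species diversity matches 4 Ne mu per site", {
  # scaled-down demography so the estimate stabilises quickly
  Ne <- 1e3; mu <- 1e-6
  set.seed(2)
  pis <- replicate(40, {
    x <- simulate_neutral_pair(4000, n = 10, Ne = Ne, Na = 2e3, T = 1e4,
                               mu = mu, cpg_fraction = 0)
    if (!length(x$positions)) return(0)
    f <- colMeans(x$hap1)
    sum(2 * f * (1 - f) * 10 / 9) / 4000
  })
  se <- sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - 4 * Ne * mu), 3 * se)
})

test_that("shared SNPs are dominated by hypermutable sites", {
  set.seed(3)
  ncpg <- 0; nother <- 0
  for (i in 1:60) {
    x <- simulate_neutral_pair(2000, n = 20, Ne = 1e3, Na = 2e3, T = 1e4,
                               mu = 1e-6, cpg_fraction = 0.1, cpg_mult = 15)
    if (!length(x$positions)) next
    s1 <- colMeans(x$hap1); s2 <- colMeans(x$hap2)
    sh <- s1 > 0 & s1 < 1 & s2 > 0 & s2 < 1
    ncpg <- ncpg + sum(sh & x$is_cpg)
    nother <- nother + sum(sh & !x$is_cpg)
  }
  expect_gt(ncpg + nother, 20)
  # enrichment relative to the 10% site fraction
  expect_gt(ncpg / (ncpg + nother), 0.5)
})

test_that("tally handles empty and planted inputs", {
  empty <- structure(list(positions = integer(0),
                          hap1 = matrix(integer(0), 10, 0),
                          hap2 = matrix(integer(0), 10, 0),
                          is_cpg = logical(0), region_bp = 1000, n = 10),
                     class = "tsp_neutral")
  ns <- tally_shared_pairs(list(empty))
  expect_equal(ns$frac_with_pair, 0)
  expect_equal(ns$n_pairs, 0)
  expect_true(is.na(ns$mean_r2))
  colA <- rep(c(1L, 0L), each = 10)
  planted <- structure(list(positions = c(100L, 200L),
                            hap1 = cbind(colA, colA),
                            hap2 = cbind(colA, colA),
                            is_cpg = c(FALSE, FALSE), region_bp = 1000,
                            n = 20),
                       class = "tsp_neutral")
  np <- tally_shared_pairs(list(planted, empty))
  expect_equal(np$frac_with_pair, 0.5)
  expect_equal(np$n_pairs, 1)
  expect_equal(np$frac_sig_same, 1)
  expect_equal(np$mean_r2, 1)
})

test_that("shared pairs are vanishingly rare at human-chimpanzee parameters", {
  set.seed(4)
  reps <- lapply(1:300, function(i) simulate_neutral_pair(10000))
  ns <- tally_shared_pairs(reps)
  expect_lt(ns$frac_with_pair, 0.05)
  # replicates with more than one pair are rarer still (the complete linkage
  # within blocks makes CpG shared SNPs cluster more than a full ARG would)
  expect_lte(mean(ns$pair_counts > 1), 0.005)
})

test_that("bottlenecks do not increase the shared-pair fraction", {
  bn <- list(sp1 = data.frame(start = 0, end = 5000, size = 100),
             sp2 = data.frame(start = 0, end = 5000, size = 100))
  fc <- 0; fb <- 0
  for (i in 1:250) {
    xc <- simulate_neutral_pair(2000, n = 20, Ne = 1e3, Na = 2e3, T = 1e4,
                                mu = 2e-6, seed = 5000 + i)
    xb <- simulate_neutral_pair(2000, n = 20, Ne = 1e3, Na = 2e3, T = 1e4,
                                mu = 2e-6, bottlenecks = bn, seed = 5000 + i)
    count_pairs <- function(x) {
      s1 <- colMeans(x$hap1); s2 <- colMeans(x$hap2)
      sh <- which(s1 > 0 & s1 < 1 & s2 > 0 & s2 < 1)
      length(sh) >= 2 &&
        any(diff(sort(x$positions[sh])) <= 400)
    }
    fc <- fc + count_pairs(xc); fb <- fb + count_pairs(xb)
  }
  expect_gt(fc, 5)                      # the comparison has signal
  expect_lte(fb, fc)
})

test_that("conditioned r2 estimator agrees with a brute-force oracle", {
  # scaled-down system where rejection sampling is affordable
  n1 <- 6; Ne <- 500; Na <- 2500; T <- 12500; mu <- 3e-6
  set.seed(42)
  r2b <- numeric(0); nw <- 0
  while (length(r2b) < 80 && nw < 30000) {
    nw <- nw + 1
    x <- simulate_neutral_pair(400, n = n1, Ne = Ne, Na = Na, T = T, mu = mu,
                               cpg_fraction = 0, block_bp = 400)
    if (length(x$positions) < 2) next
    s1 <- colMeans(x$hap1); s2 <- colMeans(x$hap2)
    sh <- which(s1 > 0 & s1 < 1 & s2 > 0 & s2 < 1)
    if (length(sh) < 2) next
    cmb <- combn(sh, 2)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1, j]; b <- cmb[2, j]
      rr <- vapply(list(x$hap1, x$hap2), function(h) {
        xx <- h[, a]; yy <- h[, b]
        (mean(xx & yy) - mean(xx) * mean(yy))^2 /
          (mean(xx) * (1 - mean(xx)) * mean(yy) * (1 - mean(yy)))
      }, 0)
      r2b <- c(r2b, mean(rr))
    }
  }
  expect_gt(length(r2b), 40)
  est <- shared_pair_r2(n_pairs = 1500, n = n1, Ne = Ne, Na = Na, T = T,
                        mu = mu, r = 0, window_bp = 400,
                        seed = 7)
  se <- sd(r2b) / sqrt(length(r2b))
  expect_lt(abs(est$mean_r2 - mean(r2b)), 3 * se + 0.03)
})

test_that("balancing selection produces much stronger shared-SNP LD than the null", {
  null <- shared_pair_r2(n_pairs = 600, n = 12, seed = 8)
  pp <- hc_params(L = 801, selected_pos = 400)
  set.seed(9)
  bal <- numeric(0)
  for (s in 1:20) {
    sim <- simulate_sample(pp, n_per_class = matrix(3, 2, 2))
    sp1 <- sim$tips$species == 1; sp2 <- sim$tips$species == 2
    sel <- sim$selected_index
    for (j in seq_along(sim$positions)) {
      if (j == sel) next
      v <- sim$haplotypes[, j]
      if (mean(v[sp1]) %in% c(0, 1) || mean(v[sp2]) %in% c(0, 1)) next
      bal <- c(bal, mean(vapply(list(sp1, sp2), function(sp) {
        x <- sim$haplotypes[sp, sel]; y <- v[sp]
        (mean(x & y) - mean(x) * mean(y))^2 /
          (mean(x) * (1 - mean(x)) * mean(y) * (1 - mean(y)))
      }, 0)))
    }
  }
  expect_gt(length(bal), 5)
  expect_gt(mean(bal), null$mean_r2)
  expect_gt(mean(bal > 0.5), 0.5)
})
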