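# island-model closed forms, the finite-age chain, and shared-SNP counts

test_that("island model has the isolated and panmictic limits", {
  t0 <- island_model_times(0, 5e4, 0.3)
  expect_equal(t0$T1, 2 * 5e4 * 0.3)
  expect_equal(t0$T2, 2 * 5e4 * 0.7)
  expect_identical(t0$TB, Inf)
  tinf <- island_model_times(1, 5e4, 0.3)
  expect_equal(tinf$T1, 1e5, tolerance = 0.01)
  expect_equal(tinf$T2, 1e5, tolerance = 0.01)
  expect_equal(tinf$TB, 1e5, tolerance = 0.01)
  for (d in c(1e-7, 1e-6, 1e-5)) {
    tt <- island_model_times(d, 5e4, 0.3)
    expect_gte(tt$TB, max(tt$T1, tt$T2))
  }
})

test_that("transition matrices are stochastic with the printed structure", {
  cm <- chain_matrices(1e-6, 5e4, 0.3)
  expect_equal(rowSums(cm$PS), rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rowSums(cm$PN), rep(1, 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rowSums(cm$QSN), rep(1, 4), ignore_attr = TRUE)
  expect_true(all(cm$PS >= 0 & cm$PS <= 1))
  # (*) absorbing in both phases
  expect_equal(cm$PS[4, ], c(0, 0, 0, 1), ignore_attr = TRUE)
  expect_equal(cm$PN[2, ], c(0, 1), ignore_attr = TRUE)
  # forced coalescence of the derived pair at the phase change
  expect_equal(cm$QSN["(2,0)", ], c(0, 1), ignore_attr = TRUE)
  # d = 0 leaves (1,1) invariant
  cm0 <- chain_matrices(0, 5e4, 0.3)
  expect_equal(cm0$PS[1, ], c(1, 0, 0, 0), ignore_attr = TRUE)
  expect_error(chain_matrices(0.9, 1, 0.5), "smaller genetic distance")
})

test_that("chain absorption time: structure, dual routes, and limits", {
  expect_equal(expected_tb_numeric(0, 5e4, 0.5, 6e5), 6e5 + 1e5)
  expect_equal(expected_tb_approx(0, 5e4, 0.5, 6e5), 6e5 + 1e5)
  # binary-doubling and plain iteration agree to 1e-8 relative
  for (d in c(5e-7, 5e-6)) {
    a <- expected_tb_numeric(d, 5e4, 0.5, 2e5)
    b <- expected_tb_numeric(d, 5e4, 0.5, 2e5, method = "iterate")
    expect_equal(a, b, tolerance = 1e-8)
  }
  # nondecreasing in Ts
  v <- vapply(c(1e5, 3e5, 6e5, 1.2e6), function(Ts)
    expected_tb_numeric(2e-6, 5e4, 0.5, Ts), 0)
  expect_true(all(diff(v) > 0))
  # old-age limit converges to the infinite-age island model
  tb_inf <- island_model_times(2e-6, 5e4, 0.5)$TB
  tb_old <- expected_tb_numeric(2e-6, 5e4, 0.5, 3e7)
  expect_lt(abs(tb_old - tb_inf) / tb_inf, 0.01)
})

test_that("chain expectation matches its Monte-Carlo simulation", {
  set.seed(7)
  for (d in c(1e-6, 5e-6)) {
    x <- sim_tb_chain(8000, d, 5e4, 0.5, 6e5)
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - expected_tb_numeric(d, 5e4, 0.5, 6e5)), 3 * se)
  }
})

test_that("triangular approximation underestimates, mildly near the segment", {
  Ts <- 6e5
  dg <- c(1e-7, 5e-7, 1e-6, 2e-6, 5e-6, 1e-5, 2e-5)
  num <- vapply(dg, expected_tb_numeric, 0, Na = 5e4, p = 0.5, Ts = Ts)
  app <- vapply(dg, expected_tb_approx, 0, Na = 5e4, p = 0.5, Ts = Ts)
  expect_true(all(app <= num + 1e-6))
  near <- dg < 1 / (2 * Ts)
  expect_true(all((num[near] - app[near]) / num[near] < 0.05))
})

test_that("expected shared-SNP count: degenerate cases and age behaviour", {
  expect_equal(as.numeric(expected_shared_snps(Na = 5e4, T = 2.5e5, p = 0.5,
                                               r = 1.2e-8, mu = 0, Ts = 6e5)), 1)
  expect_equal(as.numeric(expected_shared_snps(Na = 5e4, T = 2.5e5, p = 0.5,
                                               r = 1.2e-8, mu = 1.2e-8,
                                               Ts = 6e5, mode = "fixed",
                                               L_fixed = 0)), 1)
  ages <- c(5e5, 1e6, 2e6)
  v <- vapply(ages, function(a)
    as.numeric(expected_shared_snps(Na = 5e4, T = 2.5e5, p = 0.5, r = 1.2e-8,
                                    mu = 1.2e-8, age = a)), 0)
  expect_true(all(diff(v) > 0))
  expect_error(expected_shared_snps(Na = 5e4, T = 2.5e5, p = 0.5, r = 1.2e-8,
                                    mu = 1.2e-8, age = 2e5), "smaller")
  # fixed-L mode at the expected length is of the same order as marginal
  em <- as.numeric(expected_shared_snps(Na = 5e4, T = 2.5e5, p = 0.5,
                                        r = 1.2e-8, mu = 1.2e-8, Ts = 6e5))
  ef <- as.numeric(expected_shared_snps(Na = 5e4, T = 2.5e5, p = 0.5,
                                        r = 1.2e-8, mu = 1.2e-8, Ts = 6e5,
                                        mode = "fixed", L_fixed = 263))
  expect_gt(ef, 1); expect_gt(em, 1)
  expect_lt(abs(ef - em) / em, 0.35)
})

test_that("simulated shared-SNP counts in the segment match the expectation", {
  pp <- hc_params(L = 4001, selected_pos = 2000)
  ess <- as.numeric(expected_shared_snps(pp, Ts = pp$Ts))
  set.seed(21)
  cnt <- replicate(80, {
    s <- simulate_sample(pp)
    ext <- ancestral_segment_extent(s)
    sp1 <- s$tips$species == 1; sp2 <- s$tips$species == 2
    shared <- apply(s$haplotypes, 2, function(v) {
      a <- mean(v[sp1]); b <- mean(v[sp2]); a > 0 && a < 1 && b > 0 && b < 1
    })
    inseg <- s$positions >= s$selected_pos - ext[1] &
      s$positions <= s$selected_pos + ext[2]
    sum(shared & inseg)
  })
  se <- sd(cnt) / sqrt(length(cnt))
  expect_lt(abs(mean(cnt) - ess), 2 * se + 0.15 * ess)
})
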