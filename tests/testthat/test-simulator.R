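# the conditional structured-coalescent simulator

test_that("simulation is deterministic given the seed", {
  pp <- fig1_params(L = 2001, selected_pos = 1000)
  a <- simulate_sample(pp, seed = 5)
  b <- simulate_sample(pp, seed = 5)
  expect_identical(a$positions, b$positions)
  expect_identical(a$haplotypes, b$haplotypes)
  expect_identical(ancestral_segment_extent(a), ancestral_segment_extent(b))
})

test_that("without mutation only the selected column remains", {
  pp <- fig1_params(L = 2001, selected_pos = 1000, mu = 0)
  s <- simulate_sample(pp, seed = 3)
  expect_equal(ncol(s$haplotypes), 1)
  expect_equal(s$positions, 1000)
  expect_equal(s$haplotypes[, 1], as.integer(s$tips$cls == 1L))
})

test_that("conditioning requires one chromosome per class per species", {
  pp <- fig1_params(L = 1001)
  expect_error(simulate_sample(pp, n_per_class = matrix(c(1, 1, 1, 0), 2, 2)),
               "per allelic class")
})

test_that("the selected site always shows the allele-clustered topology", {
  pp <- fig1_params(L = 2001, selected_pos = 1000)
  for (s in 1:8) {
    sim <- simulate_sample(pp, seed = 100 + s, mutations = FALSE)
    tr <- site_tree(sim, sim$selected_pos)
    expect_equal(classify_topology(tr, T = pp$T, Na = pp$Na), "ancestral")
  }
})

test_that("hand-built topologies classify as expected", {
  T <- 1.6e5; Na <- 5e4
  # ((s1c1, s2c1), (s1c2, s2c2)): clusters by allele
  anc <- fake_tree(c(5L, 5L, 6L, 6L, 7L, 7L, NA),
                   c(0, 0, 0, 0, 3e5, 3.1e5, 9e5),
                   species = c(1, 2, 1, 2), cls = c(1, 1, 2, 2))
  expect_equal(classify_topology(anc, T, Na), "ancestral")
  # clusters by species, allele-discordant deep pair -> long
  spl <- fake_tree(c(5L, 6L, 5L, 6L, 7L, 7L, NA),
                   c(0, 0, 0, 0, 2e4, 2.1e4, T + 5 * Na),
                   species = c(1, 2, 1, 2), cls = c(1, 1, 2, 2))
  expect_equal(classify_topology(spl, T, Na), "species-long")
  sps <- fake_tree(c(5L, 6L, 5L, 6L, 7L, 7L, NA),
                   c(0, 0, 0, 0, 2e4, 2.1e4, T + 0.1 * Na),
                   species = c(1, 2, 1, 2), cls = c(1, 1, 2, 2))
  expect_equal(classify_topology(sps, T, Na), "species-short")
  # exactly one species monophyletic
  onerec <- fake_tree(c(5L, 6L, 5L, 7L, 6L, 7L, NA),
                      c(0, 0, 0, 0, 1e4, 3e5, 9e5),
                      species = c(1, 2, 1, 2), cls = c(1, 1, 2, 2))
  expect_equal(classify_topology(onerec, T, Na), "one-recombined")
})

test_that("the ancestral segment is flanked by one-recombined segments", {
  pp <- fig1_params(L = 6001, selected_pos = 3000)
  n_adjacent <- c(`one-recombined` = 0, other = 0)
  for (s in 1:12) {
    sim <- simulate_sample(pp, seed = 200 + s, mutations = FALSE)
    seg <- classify_segments(sim)
    anc <- which(seg$state == "ancestral")
    expect_true(length(anc) >= 1)
    run <- min(anc):max(anc)
    for (nb in c(min(run) - 1, max(run) + 1)) {
      if (nb < 1 || nb > nrow(seg)) next
      st <- seg$state[nb]
      # one recombination event cannot produce a species-clustered tree
      expect_false(st %in% c("species-long", "species-short"))
      if (st %in% names(n_adjacent))
        n_adjacent[st] <- n_adjacent[st] + 1
    }
  }
  expect_gt(n_adjacent["one-recombined"], n_adjacent["other"])
})

test_that("segment extent is capped by the window when recombination is off", {
  pp <- fig1_params(L = 1001, selected_pos = 300, r = 1e-14, mu = 0)
  s <- simulate_sample(pp, seed = 4, mutations = FALSE)
  expect_equal(unname(ancestral_segment_extent(s)), c(300, 701))
})

test_that("ARG extents agree with the stage-wise event-process sampler", {
  pp <- fig1_params(L = 10001, selected_pos = 5000, mu = 0)
  set.seed(9)
  ext <- replicate(250, ancestral_segment_extent(
    simulate_sample(pp, mutations = FALSE)))
  xs <- simulate_segment_extents(4e4, pp)
  # full-ARG segments are slightly shorter: material fragmentation adds
  # erosion channels the stage-wise approximation does not track
  expect_lt(abs(mean(ext) - mean(xs)) / mean(xs), 0.12)
  expect_lt(mean(ext), mean(xs) * 1.05)
})

test_that("shared SNPs in 4-chromosome samples are in perfect LD", {
  pp <- hc_params(L = 2001, selected_pos = 1000)
  found <- 0
  for (s in 1:25) {
    sim <- simulate_sample(pp, seed = 300 + s)
    ext <- ancestral_segment_extent(sim)
    sp1 <- sim$tips$species == 1; sp2 <- sim$tips$species == 2
    sel <- sim$selected_index
    for (j in seq_along(sim$positions)) {
      if (j == sel) next
      v <- sim$haplotypes[, j]
      if (!(mean(v[sp1]) %in% c(0, 1)) && !(mean(v[sp2]) %in% c(0, 1)) &&
          sim$positions[j] >= sim$selected_pos - ext[1] &&
          sim$positions[j] <= sim$selected_pos + ext[2]) {
        found <- found + 1
        for (sp in list(sp1, sp2)) {
          x <- sim$haplotypes[sp, sel]; y <- v[sp]
          r2 <- (mean(x & y) - mean(x) * mean(y))^2 /
            (mean(x) * (1 - mean(x)) * mean(y) * (1 - mean(y)))
          expect_equal(r2, 1)
        }
      }
    }
  }
  expect_gt(found, 5)
})

test_that("in larger samples LD with the selected site is strong and decays", {
  pp <- hc_params(L = 1201, selected_pos = 600)
  set.seed(41)
  dist <- numeric(0); r2 <- numeric(0)
  for (s in 1:60) {
    sim <- simulate_sample(pp, n_per_class = matrix(6, 2, 2))
    sp1 <- sim$tips$species == 1; sp2 <- sim$tips$species == 2
    sel <- sim$selected_index
    for (j in seq_along(sim$positions)) {
      if (j == sel) next
      v <- sim$haplotypes[, j]
      if (mean(v[sp1]) %in% c(0, 1) || mean(v[sp2]) %in% c(0, 1)) next
      rr <- vapply(list(sp1, sp2), function(sp) {
        x <- sim$haplotypes[sp, sel]; y <- v[sp]
        (mean(x & y) - mean(x) * mean(y))^2 /
          (mean(x) * (1 - mean(x)) * mean(y) * (1 - mean(y)))
      }, 0)
      dist <- c(dist, abs(sim$positions[j] - sim$selected_pos))
      r2 <- c(r2, mean(rr))
    }
  }
  expect_gt(length(r2), 20)
  expect_gt(mean(r2[dist < 150]), 0.5)
  expect_gte(mean(r2[dist < 150]), mean(r2[dist >= 150]))
})

test_that("sample size has a negligible effect on the segment extent", {
  pp <- fig1_params(L = 10001, selected_pos = 5000, mu = 0)
  set.seed(77)
  e4 <- replicate(120, mean(ancestral_segment_extent(
    simulate_sample(pp, mutations = FALSE))))
  e20 <- replicate(120, mean(ancestral_segment_extent(
    simulate_sample(pp, n_per_class = matrix(5, 2, 2), mutations = FALSE))))
  se <- sqrt(var(e4) / 120 + var(e20) / 120)
  expect_lt(abs(mean(e20) - mean(e4)), 2 * se + 0.05 * mean(e4))
})

test_that("overdominance trajectories are pinned by selection and feed the
           extent sampler without changing it when selection is strong", {
  set.seed(13)
  strong <- simulate_overdominance_trajectory(0.05, 1e4, 4000)
  neutralish <- simulate_overdominance_trajectory(0, 1e4, 4000)
  expect_lt(sd(strong), sd(neutralish))
  expect_lt(abs(mean(strong) - 0.5), 0.05)
  expect_true(all(strong > 0 & strong < 1))
  # 2 Ne s >= 100: summaries indistinguishable from the constant-p model
  pp <- fig1_params()
  traj <- simulate_overdominance_trajectory(0.01, 5e4, 4e5, seed = 14)
  x_con <- simulate_segment_extents(8000, pp, seed = 15)
  x_fluc <- simulate_segment_extents(8000, pp, trajectory = traj, seed = 16)
  ks <- suppressWarnings(ks.test(x_con, x_fluc))
  expect_gt(ks$p.value, 0.01)
})
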