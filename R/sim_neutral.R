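# Neutral two-species simulators: the finite-sites recurrent-mutation null
# model (with CpG-like hypermutable sites) and a conditioned estimator of the
# LD between SNP pairs shared by recurrent mutation.
#
# Shared SNPs under neutrality are extremely rare, so the LD estimator does
# not wait for them: it simulates two-species genealogies at the two linked
# sites (a two-locus ancestral recombination graph), enumerates the mutation
# configurations that make a site polymorphic in both species (to leading
# order in mu: one mutation on a branch segregating in both species, or two
# mutations whose combined flip pattern segregates in both), and samples
# site patterns from those configurations with their probability weights.
# Genealogies are weighted by their per-site sharedness probability, exactly
# the weight with which they contribute collected pairs.

# ---- single-locus two-species tree -----------------------------------------

# piecewise-constant population size per species: epochs is a data.frame
# (start, end, size); outside any epoch the size is N0
.coal_phase <- function(state, t0, tend, N0, epochs = NULL, env) {
  act <- state; t <- t0
  size_at <- function(tt) {
    if (!is.null(epochs)) {
      hit <- which(epochs$start <= tt & tt < epochs$end)
      if (length(hit)) return(epochs$size[hit[1]])
    }
    N0
  }
  next_change <- function(tt) {
    if (is.null(epochs)) return(Inf)
    cand <- c(epochs$start, epochs$end)
    cand <- cand[cand > tt]
    if (length(cand)) min(cand) else Inf
  }
  while (length(act) > 1) {
    k <- length(act)
    N <- size_at(t)
    dt <- rexp(1, k * (k - 1) / 2 / (2 * N))
    chg <- min(next_change(t), tend)
    if (t + dt >= chg) { t <- chg; if (t >= tend) return(list(act = act, t = tend)); next }
    t <- t + dt
    pr <- sample.int(k, 2)
    nd <- env$nxt; env$nxt <- env$nxt + 1L
    env$tlow[nd] <- t
    env$thigh[act[pr[1]]] <- t; env$thigh[act[pr[2]]] <- t
    env$desc[, nd] <- env$desc[, act[pr[1]]] | env$desc[, act[pr[2]]]
    act <- c(act[-pr], nd)
  }
  list(act = act, t = t)
}

.sim_pair_tree <- function(n1, n2, Ne, Na, T, bottlenecks = NULL) {
  ntip <- n1 + n2
  env <- new.env()
  env$tlow <- rep(NA_real_, 2 * ntip)
  env$thigh <- rep(NA_real_, 2 * ntip)
  env$desc <- matrix(FALSE, ntip, 2 * ntip)
  env$tlow[1:ntip] <- 0
  env$desc[cbind(1:ntip, 1:ntip)] <- TRUE
  env$nxt <- ntip + 1L
  a1 <- .coal_phase(1:n1, 0, T, Ne, bottlenecks$sp1, env)
  a2 <- .coal_phase((n1 + 1):ntip, 0, T, Ne, bottlenecks$sp2, env)
  an <- .coal_phase(c(a1$act, a2$act), T, Inf, Na, NULL, env)
  env$thigh[an$act] <- env$tlow[an$act]
  u <- seq_len(env$nxt - 1L)
  list(len = (env$thigh - env$tlow)[u],
       desc = env$desc[, u, drop = FALSE])
}

#' Simulate neutral two-species haplotypes with recurrent mutation
#'
#' A standard neutral two-species coalescent with a finite-sites flip-flop
#' mutation model (a recurrent hit toggles a site between the same two
#' alleles), so that shared SNPs identical by state can arise. A fraction of
#' sites is hypermutable (CpG-like) with a rate multiplier. Linkage is
#' complete within blocks of `block_bp` and free between blocks.
#'
#' @param region_bp total region length in bp.
#' @param n chromosomes sampled per species.
#' @param Ne,Na,T demography (diploid sizes and split time in generations).
#' @param mu baseline mutation rate per bp per generation.
#' @param cpg_fraction fraction of hypermutable sites (default 0.02).
#' @param cpg_mult rate multiplier at hypermutable sites (default 10).
#' @param block_bp linkage block size (default 400).
#' @param bottlenecks optional list with elements `sp1`, `sp2`, each a
#'   data.frame with columns `start`, `end`, `size` (epochs in [0, T)).
#' @param seed optional seed.
#' @return An object of class `tsp_neutral`: positions (0-based), `hap1`
#'   and `hap2` (0/1 matrices, chromosomes x sites), `is_cpg`, `region_bp`.
#' @export
simulate_neutral_pair <- function(region_bp, n = 50, Ne = 1e4, Na = 5e4,
                                  T = 2.5e5, mu = 1.2e-8,
                                  cpg_fraction = 0.02, cpg_mult = 10,
                                  block_bp = 400, bottlenecks = NULL,
                                  seed = NULL) {
  stopifnot(region_bp >= 1, n >= 1, mu >= 0,
            cpg_fraction >= 0, cpg_fraction <= 1, cpg_mult >= 0)
  if (!is.null(seed)) set.seed(seed)
  nblock <- ceiling(region_bp / block_bp)
  pos <- integer(0); is_cpg <- logical(0)
  cols1 <- list(); cols2 <- list()
  for (b in seq_len(nblock)) {
    b0 <- (b - 1) * block_bp
    bw <- min(block_bp, region_bp - b0)
    tr <- .sim_pair_tree(n, n, Ne, Na, T, bottlenecks)
    Ltot <- sum(tr$len)
    cpg <- runif(bw) < cpg_fraction
    rate <- mu * ifelse(cpg, cpg_mult, 1)
    M <- rpois(1, Ltot * sum(rate))
    if (M == 0) next
    sites <- sample.int(bw, M, replace = TRUE, prob = rate)
    brs <- sample.int(length(tr$len), M, replace = TRUE, prob = tr$len)
    for (s in unique(sites)) {
      v <- rep(FALSE, 2 * n)
      for (br in brs[sites == s]) v <- xor(v, tr$desc[, br])
      if (!any(v) || all(v)) next
      pos <- c(pos, b0 + s - 1L)
      is_cpg <- c(is_cpg, cpg[s])
      cols1[[length(cols1) + 1L]] <- as.integer(v[1:n])
      cols2[[length(cols2) + 1L]] <- as.integer(v[(n + 1):(2 * n)])
    }
  }
  o <- order(pos)
  structure(list(positions = pos[o],
                 hap1 = if (length(o)) do.call(cbind, cols1)[, o, drop = FALSE]
                 else matrix(integer(0), n, 0),
                 hap2 = if (length(o)) do.call(cbind, cols2)[, o, drop = FALSE]
                 else matrix(integer(0), n, 0),
                 is_cpg = is_cpg[o], region_bp = region_bp, n = n),
            class = "tsp_neutral")
}

#' Tally shared SNP pairs and their LD over null replicates
#'
#' Finds, in each replicate, the SNPs polymorphic in both species (shared
#' identical by state under the flip-flop model), forms all pairs within
#' `window_bp`, and summarises their LD: the fraction of replicates
#' containing at least one pair, the fraction of pairs in significant LD
#' with the same alleles coupled in both species, and the r-squared
#' distribution.
#'
#' @param replicates a list of `tsp_neutral` objects.
#' @param window_bp maximum pair separation (position difference, default
#'   400).
#' @param alpha significance level of the chi-squared LD test.
#' @return A list of class `null_summary`.
#' @export
tally_shared_pairs <- function(replicates, window_bp = 400, alpha = 0.05) {
  stopifnot(length(replicates) >= 1)
  nrep <- length(replicates)
  any_pair <- logical(nrep)
  pair_counts <- integer(nrep)
  r2 <- numeric(0); sig_same <- logical(0)
  for (i in seq_len(nrep)) {
    x <- replicates[[i]]
    n1 <- nrow(x$hap1); n2 <- nrow(x$hap2)
    s1 <- colSums(x$hap1); s2 <- colSums(x$hap2)
    sh <- which(s1 > 0 & s1 < n1 & s2 > 0 & s2 < n2)
    if (length(sh) >= 2) {
      cmb <- combn(sh, 2)
      keep <- abs(x$positions[cmb[1, ]] - x$positions[cmb[2, ]]) <= window_bp
      cmb <- cmb[, keep, drop = FALSE]
      pair_counts[i] <- ncol(cmb)
      any_pair[i] <- ncol(cmb) > 0
      for (j in seq_len(ncol(cmb))) {
        a <- cmb[1, j]; b <- cmb[2, j]
        res <- lapply(list(x$hap1, x$hap2), function(h) {
          tb <- haplotype_table(
            sum(h[, a] == 1 & h[, b] == 1), sum(h[, a] == 1 & h[, b] == 0),
            sum(h[, a] == 0 & h[, b] == 1), sum(h[, a] == 0 & h[, b] == 0))
          c(r2 = pairwise_ld(tb)$r2,
            sig = ld_significance(tb, alpha)$significant,
            D = pairwise_ld(tb)$D)
        })
        r2 <- c(r2, mean(c(res[[1]]["r2"], res[[2]]["r2"])))
        sig_same <- c(sig_same,
                      res[[1]]["sig"] == 1 && res[[2]]["sig"] == 1 &&
                        sign(res[[1]]["D"]) == sign(res[[2]]["D"]))
      }
    }
  }
  structure(list(n_replicates = nrep,
                 frac_with_pair = mean(any_pair),
                 pair_counts = pair_counts,
                 n_pairs = sum(pair_counts),
                 frac_sig_same = if (sum(pair_counts)) mean(sig_same) else NA_real_,
                 mean_r2 = if (sum(pair_counts)) mean(r2) else NA_real_,
                 r2 = r2),
            class = "null_summary")
}

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf("Neutral recurrent-mutation null over %d replicates\n",
              x$n_replicates))
  cat(sprintf("  replicates with a shared SNP pair: %.3g%%\n",
              100 * x$frac_with_pair))
  if (x$n_pairs > 0)
    cat(sprintf("  %d pairs; significant + same coupling: %.3g%%; mean r2 = %.3g\n",
                x$n_pairs, 100 * x$frac_sig_same, x$mean_r2))
  invisible(x)
}

# ---- conditioned estimator of shared-pair LD --------------------------------

# two-locus two-species ARG; returns per-locus branch tables
.sim_two_locus <- function(n1, n2, Ne, Na, T, rho) {
  ntip <- n1 + n2
  NMAX <- 4 * ntip
  tlowA <- rep(NA_real_, NMAX); thighA <- rep(NA_real_, NMAX)
  descA <- matrix(FALSE, ntip, NMAX)
  tlowB <- tlowA; thighB <- thighA; descB <- descA
  tlowA[1:ntip] <- 0; tlowB[1:ntip] <- 0
  descA[cbind(1:ntip, 1:ntip)] <- TRUE; descB[cbind(1:ntip, 1:ntip)] <- TRUE
  nxtA <- ntip + 1L; nxtB <- ntip + 1L
  deme <- c(rep(1L, n1), rep(2L, n2)); a <- 1:ntip; b <- 1:ntip
  doneA <- FALSE; doneB <- FALSE; t <- 0
  repeat {
    live <- (a > 0) | (b > 0)
    deme <- deme[live]; a <- a[live]; b <- b[live]
    if ((doneA && doneB) || length(deme) == 0) break
    demes <- if (t < T) 1:2 else 3L
    Ns <- if (t < T) c(Ne, Ne) else Na
    crates <- vapply(seq_along(demes), function(i) {
      k <- sum(deme == demes[i]); k * (k - 1) / 2 / (2 * Ns[i])
    }, 0)
    rrate <- rho * sum(a > 0 & b > 0)
    tot <- sum(crates) + rrate
    if (tot == 0) { if (t < T) { t <- T; deme[] <- 3L; next } else break }
    dt <- rexp(1, tot)
    if (t < T && t + dt >= T) { t <- T; deme[] <- 3L; next }
    t <- t + dt
    u <- runif(1) * tot
    if (u < rrate) {
      cand <- which(a > 0 & b > 0)
      i <- cand[sample.int(length(cand), 1)]
      deme <- c(deme, deme[i]); a <- c(a, 0L); b <- c(b, b[i]); b[i] <- 0L
    } else {
      u <- u - rrate
      di <- demes[which(cumsum(crates) > u)[1]]
      cand <- which(deme == di)
      pr <- cand[sample.int(length(cand), 2)]
      i <- pr[1]; j <- pr[2]
      if (a[i] > 0 && a[j] > 0) {
        nd <- nxtA; nxtA <- nxtA + 1L
        tlowA[nd] <- t; thighA[a[i]] <- t; thighA[a[j]] <- t
        descA[, nd] <- descA[, a[i]] | descA[, a[j]]
        if (all(descA[, nd])) { doneA <- TRUE; thighA[nd] <- t; a[i] <- 0L }
        else a[i] <- nd
      } else a[i] <- max(a[i], a[j])
      if (b[i] > 0 && b[j] > 0) {
        nd <- nxtB; nxtB <- nxtB + 1L
        tlowB[nd] <- t; thighB[b[i]] <- t; thighB[b[j]] <- t
        descB[, nd] <- descB[, b[i]] | descB[, b[j]]
        if (all(descB[, nd])) { doneB <- TRUE; thighB[nd] <- t; b[i] <- 0L }
        else b[i] <- nd
      } else b[i] <- max(b[i], b[j])
      deme <- deme[-j]; a <- a[-j]; b <- b[-j]
    }
  }
  uA <- seq_len(nxtA - 1L); uB <- seq_len(nxtB - 1L)
  list(A = list(len = (thighA - tlowA)[uA], desc = descA[, uA, drop = FALSE]),
       B = list(len = (thighB - tlowB)[uB], desc = descB[, uB, drop = FALSE]))
}

# shared-site mutation configurations of one marginal tree: weights of single
# branches (ILS class) and branch pairs whose flip pattern segregates in both
# species
.shared_configs <- function(tr, n1, n2, mu) {
  len <- tr$len; D <- tr$desc; nb <- length(len)
  k1 <- colSums(D[1:n1, , drop = FALSE])
  k2 <- colSums(D[(n1 + 1):(n1 + n2), , drop = FALSE])
  O1 <- crossprod(D[1:n1, , drop = FALSE])
  O2 <- crossprod(D[(n1 + 1):(n1 + n2), , drop = FALSE])
  K1 <- outer(k1, k1, "+") - 2 * O1
  K2 <- outer(k2, k2, "+") - 2 * O2
  ok <- K1 > 0 & K1 < n1 & K2 > 0 & K2 < n2
  ok[lower.tri(ok, diag = TRUE)] <- FALSE
  oks <- k1 > 0 & k1 < n1 & k2 > 0 & k2 < n2
  w_s <- ifelse(oks, mu * len, 0)
  idx_p <- which(ok)
  w_p <- ((mu * len) %o% (mu * len))[idx_p]
  list(w = c(w_s, w_p), nb = nb, idx_p = idx_p, D = D,
       W = sum(w_s) + sum(w_p))
}

.draw_config <- function(cw) {
  i <- sample.int(length(cw$w), 1, prob = cw$w)
  if (i <= cw$nb) return(cw$D[, i])
  ij <- cw$idx_p[i - cw$nb]
  ii <- (ij - 1) %% cw$nb + 1
  jj <- (ij - 1) %/% cw$nb + 1
  xor(cw$D[, ii], cw$D[, jj])
}

#' LD between SNP pairs shared by recurrent mutation (conditioned estimator)
#'
#' Estimates the distribution of r-squared between pairs of shared SNPs
#' under the neutral two-species model by conditioning on sharedness rather
#' than waiting for it: for each simulated two-locus genealogy (pair
#' separation drawn uniformly up to `window_bp`), site patterns are sampled
#' from the leading-order mutation configurations that segregate in both
#' species, and genealogies are weighted by their squared per-site
#' sharedness probability — the weight with which they contribute observed
#' pairs.
#'
#' @param n_pairs target number of collected pairs.
#' @param n chromosomes per species.
#' @param Ne,Na,T demography.
#' @param mu,r mutation and recombination rates per bp per generation.
#' @param window_bp maximum pair separation.
#' @param pairs_per_genealogy pairs sampled per genealogy.
#' @param alpha significance level for the chi-squared LD test.
#' @param seed optional seed.
#' @return A list with `mean_r2` (weighted mean over pairs, averaging the
#'   two species), `median_r2`, `frac_sig_same`, the per-pair values and
#'   weights, and `n_pairs`.
#' @export
shared_pair_r2 <- function(n_pairs = 2000, n = 50, Ne = 1e4, Na = 5e4,
                           T = 2.5e5, mu = 1.2e-8, r = 1.2e-8,
                           window_bp = 400, pairs_per_genealogy = 5,
                           alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp1 <- 1:n; sp2 <- (n + 1):(2 * n)
  r2v <- numeric(0); wv <- numeric(0); sig <- logical(0)
  while (length(r2v) < n_pairs) {
    dbp <- sample.int(window_bp, 1)
    tr <- .sim_two_locus(n, n, Ne, Na, T, r * dbp)
    cA <- .shared_configs(tr$A, n, n, mu)
    cB <- .shared_configs(tr$B, n, n, mu)
    if (cA$W <= 0 || cB$W <= 0) next
    for (k in seq_len(pairs_per_genealogy)) {
      pa <- .draw_config(cA); pb <- .draw_config(cB)
      st <- vapply(list(sp1, sp2), function(sp) {
        x <- pa[sp]; y <- pb[sp]
        Dv <- mean(x & y) - mean(x) * mean(y)
        c(Dv^2 / (mean(x) * (1 - mean(x)) * mean(y) * (1 - mean(y))), Dv)
      }, c(0, 0))
      r2v <- c(r2v, mean(st[1, ]))
      wv <- c(wv, cA$W * cB$W)
      sig <- c(sig, all(n * st[1, ] > qchisq(1 - alpha, 1)) &&
                 prod(sign(st[2, ])) > 0)
    }
  }
  o <- order(r2v); cw <- cumsum(wv[o]) / sum(wv)
  list(mean_r2 = weighted.mean(r2v, wv),
       median_r2 = r2v[o][which(cw >= 0.5)[1]],
       frac_sig_same = weighted.mean(sig, wv),
       r2 = r2v, weights = wv, n_pairs = length(r2v))
}
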