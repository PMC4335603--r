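# Structured-coalescent simulator conditioned on a biallelic trans-species
# balanced polymorphism.
#
# Backward in time, the allelic classes at the selected site behave like
# demes: within-class coalescence at rate k(k-1)/2 / (2*N*f) for a class at
# frequency f in a population of diploid size N, and "migration" by crossover.
# A crossover splits a lineage's ancestral material at a uniform breakpoint;
# the piece on the selected-site side keeps its allelic class, the other
# piece lands on a random background (class A1 with probability p). Lineages
# from the two species join a common ancestral population at the split time
# T; at the time the derived allele arose (t_arise) all remaining A1 lineages
# coalesce, because forward in time the allele jumped to frequency p when it
# appeared; thereafter a single panmictic class of size Na remains.
#
# Ancestral material is tracked as half-open intervals [left, right) over the
# window [0, L); every coalescence records, for each region where both
# children carry material, edges of the marginal trees. Event times are
# continuous (exponential waiting times between events).

# ---- interval helpers -------------------------------------------------------
# interval maps are matrices with columns l, r, node, k (k = sample tips below)

.iv_compact <- function(iv) {
  if (nrow(iv) <= 1) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  keep <- rep(TRUE, nrow(iv))
  j <- 1
  for (i in 2:nrow(iv)) {
    if (iv[i, 1] == iv[j, 2] && iv[i, 3] == iv[j, 3] && iv[i, 4] == iv[j, 4]) {
      iv[j, 2] <- iv[i, 2]; keep[i] <- FALSE
    } else j <- i
  }
  iv[keep, , drop = FALSE]
}

.iv_split <- function(iv, u) {
  lo <- iv[iv[, 1] < u, , drop = FALSE]
  hi <- iv[iv[, 2] > u, , drop = FALSE]
  if (nrow(lo)) lo[, 2] <- pmin(lo[, 2], u)
  if (nrow(hi)) hi[, 1] <- pmax(hi[, 1], u)
  list(lo = lo, hi = hi)
}

.iv_covers <- function(iv, x) {
  nrow(iv) > 0 && any(iv[, 1] <= x & iv[, 2] > x)
}

# ---- the engine -------------------------------------------------------------

#' Structured-coalescent simulation of a sample around a balanced
#' trans-species polymorphism
#'
#' Simulates the multi-site genealogy of a sample conditioned on the
#' trans-species polymorphism (at least one chromosome per allelic class per
#' species), drops neutral mutations under the infinite-sites model, and
#' classifies the genealogical state of each non-recombining segment.
#'
#' @param params a [model_params()] object (uses Ne, Na, T, Ts, p, r, mu, L,
#'   selected_pos).
#' @param n_per_class integer matrix or vector of sampled chromosome counts;
#'   either a 2x2 matrix (rows = species, columns = allelic classes A1, A2)
#'   or a single total per species split evenly between classes.
#' @param seed integer seed (the simulation is deterministic given the seed).
#' @param t_arise backward time at which the derived allele arose; default
#'   `T + Ts + E[max(t1, t2)]`, anchoring the allele's age at Ts generations
#'   before the expected end of stage II.
#' @param mutations drop neutral mutations (logical).
#' @param max_events safety cap on the number of events.
#' @return An object of class `tsp_sim`: tips, marginal-tree edges, node
#'   times, per-segment topology classes, haplotypes, mutation positions,
#'   the class-switch event log and the stage-II bookkeeping used by
#'   [ancestral_segment_extent()].
#' @export
simulate_sample <- function(params, n_per_class = NULL, seed = NULL,
                            t_arise = NULL, mutations = TRUE,
                            max_events = 1e6) {
  stopifnot(inherits(params, "tsp_params"))
  if (!is.null(seed)) set.seed(seed)
  p <- params$p; q <- params$q
  Ne <- params$Ne; Na <- params$Na; T <- params$T
  rbp <- params$r; L <- params$L; selpos <- params$selected_pos
  if (is.null(t_arise)) {
    rt <- .seg_rates(Na, p)
    t_arise <- T + params$Ts + (1 / rt$a + 1 / rt$b - 1 / (rt$a + rt$b))
  }
  if (t_arise < T) stop("`t_arise` must not precede the species split")
  if (is.null(n_per_class)) {
    half <- max(1, floor(params$n / 2))
    n_per_class <- matrix(c(half, half, params$n - half, params$n - half),
                          2, 2)
  }
  if (!is.matrix(n_per_class))
    n_per_class <- matrix(rep(n_per_class, length.out = 4), 2, 2)
  if (any(n_per_class < 1))
    stop("need at least one chromosome per allelic class per species ",
         "(conditioning on observing the polymorphism)")
  ntot <- sum(n_per_class)

  tips <- data.frame(
    id = seq_len(ntot),
    species = rep(rep(1:2, each = 2), times = as.vector(t(n_per_class))),
    cls = rep(rep(c(1L, 2L), 2), times = as.vector(t(n_per_class))))

  # lineage state
  lin_iv <- vector("list", ntot)
  for (i in seq_len(ntot))
    lin_iv[[i]] <- matrix(c(0, L, i, 1), 1, 4,
                          dimnames = list(NULL, c("l", "r", "node", "k")))
  deme <- tips$species
  cls <- tips$cls
  alive <- rep(TRUE, ntot)

  ntime <- numeric(ntot)               # node times; grows
  ed_par <- integer(0); ed_child <- integer(0)
  ed_l <- numeric(0); ed_r <- numeric(0)
  nxt_node <- ntot + 1L

  sel_count <- c(sum(tips$cls == 1L), sum(tips$cls == 2L))
  class_mrca <- c(NA_real_, NA_real_)
  sw_time <- numeric(0); sw_side <- integer(0); sw_dist <- numeric(0)

  add_node <- function(t) {
    ntime[nxt_node] <<- t
    id <- nxt_node
    nxt_node <<- nxt_node + 1L
    id
  }

  merge_lineages <- function(i, j, t) {
    nn <- add_node(t)
    A <- lin_iv[[i]]; B <- lin_iv[[j]]
    both_sel <- .iv_covers(A, selpos) && .iv_covers(B, selpos)
    bps <- sort(unique(c(A[, 1], A[, 2], B[, 1], B[, 2])))
    rows <- list(); ne <- 0L
    for (s in seq_len(length(bps) - 1)) {
      x1 <- bps[s]; x2 <- bps[s + 1]; mid <- (x1 + x2) / 2
      ia <- which(A[, 1] <= mid & A[, 2] > mid)
      ib <- which(B[, 1] <= mid & B[, 2] > mid)
      if (length(ia) && length(ib)) {
        ed_par <<- c(ed_par, nn, nn)
        ed_child <<- c(ed_child, A[ia, 3], B[ib, 3])
        ed_l <<- c(ed_l, x1, x1); ed_r <<- c(ed_r, x2, x2)
        kk <- A[ia, 4] + B[ib, 4]
        if (kk < ntot) rows[[length(rows) + 1L]] <- c(x1, x2, nn, kk)
      } else if (length(ia)) {
        rows[[length(rows) + 1L]] <- c(x1, x2, A[ia, 3], A[ia, 4])
      } else if (length(ib)) {
        rows[[length(rows) + 1L]] <- c(x1, x2, B[ib, 3], B[ib, 4])
      }
    }
    if (both_sel) {
      cc <- cls[i]
      sel_count[cc] <<- sel_count[cc] - 1L
      if (sel_count[cc] == 1L && is.na(class_mrca[cc])) class_mrca[cc] <<- t
    }
    iv <- if (length(rows)) .iv_compact(do.call(rbind, rows))
    else matrix(numeric(0), 0, 4)
    lin_iv[[i]] <<- iv
    alive[j] <<- FALSE
    if (nrow(iv) == 0) alive[i] <<- FALSE
  }

  t <- 0
  epoch_bounds <- c(T, t_arise, Inf)
  nev <- 0L
  repeat {
    idx <- which(alive)
    if (!length(idx)) break
    nev <- nev + 1L
    if (nev > max_events) stop("event cap exceeded; window too large?")
    # groups and rates
    if (t < T) { gdeme <- deme[idx]; two_cls <- TRUE; Npop <- Ne }
    else { gdeme <- rep(0L, length(idx)); two_cls <- t < t_arise; Npop <- Na }
    gcls <- if (two_cls) cls[idx] else rep(2L, length(idx))
    gsize <- ifelse(gcls == 1L, p * Npop, if (two_cls) q * Npop else Npop)
    key <- paste(gdeme, gcls)
    crate_by <- tapply(seq_along(idx), key, function(ii) {
      k <- length(ii)
      k * (k - 1) / 2 / (2 * gsize[ii[1]])
    })
    widths <- vapply(idx, function(i) {
      iv <- lin_iv[[i]]
      max(iv[, 2], selpos) - min(iv[, 1], selpos)
    }, 0)
    rrate <- rbp * widths
    tot <- sum(crate_by) + sum(rrate)
    if (tot <= 0) stop("internal error: zero total rate")
    dt <- rexp(1, tot)
    bnd <- epoch_bounds[epoch_bounds > t][1]
    if (t + dt >= bnd) {
      t <- bnd
      if (bnd == t_arise) {
        c1 <- which(alive & cls == 1L)
        if (length(c1) >= 2) {
          for (j in c1[-1]) if (alive[c1[1]] && alive[j])
            merge_lineages(c1[1], j, t)
        }
        if (is.na(class_mrca[1])) class_mrca[1] <- t
        cls[alive] <- 2L
        if (is.na(class_mrca[2]) && sel_count[2] <= 1L) class_mrca[2] <- t
      }
      if (bnd == Inf) break
      next
    }
    t <- t + dt
    u <- runif(1) * tot
    if (u < sum(rrate)) {
      # crossover
      i <- idx[which(cumsum(rrate) > u)[1]]
      iv <- lin_iv[[i]]
      lo <- min(iv[, 1], selpos); hi <- max(iv[, 2], selpos)
      bp <- runif(1, lo, hi)
      parts <- .iv_split(iv, bp)
      det <- if (bp > selpos) parts$hi else parts$lo       # detached piece
      kept <- if (bp > selpos) parts$lo else parts$hi
      if (nrow(det) == 0) next
      newcls <- if (t >= t_arise) 2L
      else if (runif(1) < p) 1L else 2L
      oldcls <- cls[i]
      if (nrow(kept) == 0) {
        # all material detaches; the (untracked) selected-side piece is dropped
        lin_iv[[i]] <- det
        cls[i] <- newcls
      } else {
        lin_iv[[i]] <- kept
        lin_iv[[length(lin_iv) + 1L]] <- det
        deme <- c(deme, deme[i]); cls <- c(cls, newcls)
        alive <- c(alive, TRUE)
      }
      if (newcls != oldcls) {
        if (bp > selpos) {
          sw_time <- c(sw_time, t); sw_side <- c(sw_side, 2L)
          sw_dist <- c(sw_dist, min(det[, 1]) - selpos)
        } else {
          sw_time <- c(sw_time, t); sw_side <- c(sw_side, 1L)
          sw_dist <- c(sw_dist, selpos - max(det[, 2]))
        }
      }
    } else {
      u <- u - sum(rrate)
      gk <- names(crate_by)[which(cumsum(crate_by) > u)[1]]
      members <- idx[key == gk]
      pr <- sample(members, 2)
      merge_lineages(pr[1], pr[2], t)
    }
  }

  stage2_end <- max(class_mrca, na.rm = TRUE)
  edges <- data.frame(parent = ed_par, child = ed_child,
                      left = ed_l, right = ed_r)
  sim <- structure(list(params = params, seed = seed, tips = tips,
                        edges = edges, node_time = ntime[seq_len(nxt_node - 1L)],
                        L = L, selected_pos = selpos, t_arise = t_arise,
                        class_mrca = class_mrca, stage2_end = stage2_end,
                        switch_events = data.frame(time = sw_time,
                                                   side = sw_side,
                                                   dist = sw_dist)),
                   class = "tsp_sim")
  sim$segments <- .sim_segments(sim)
  if (mutations && params$mu > 0) {
    mut <- .drop_mutations(sim, params$mu)
    sim$haplotypes <- mut$hap
    sim$positions <- mut$pos
  } else {
    sim$haplotypes <- matrix(integer(0), ntot, 0)
    sim$positions <- numeric(0)
  }
  # selected-site column
  selcol <- as.integer(tips$cls == 1L)
  ins <- findInterval(selpos, sim$positions)
  sim$positions <- append(sim$positions, selpos, after = ins)
  sim$haplotypes <- cbind(sim$haplotypes[, seq_len(ins), drop = FALSE],
                          selcol,
                          sim$haplotypes[, seq(ins + 1, length.out = ncol(sim$haplotypes) - ins),
                                         drop = FALSE])
  colnames(sim$haplotypes) <- NULL
  sim$selected_index <- ins + 1L
  sim
}

#' @export
print.tsp_sim <- function(x, ...) {
  cat(sprintf("Structured-coalescent sample: %d chromosomes, window %g bp\n",
              nrow(x$tips), x$L))
  cat(sprintf("  %d marginal-tree segments, %d variant sites (selected site at %g)\n",
              nrow(x$segments), length(x$positions), x$selected_pos))
  cat(sprintf("  one-sided ancestral-segment extent: left %.1f bp, right %.1f bp\n",
              ancestral_segment_extent(x)[1], ancestral_segment_extent(x)[2]))
  invisible(x)
}

# breakpoints of the marginal-tree mosaic and a representative point each
.sim_segments <- function(sim) {
  bp <- sort(unique(c(0, sim$L, sim$edges$left, sim$edges$right)))
  data.frame(left = bp[-length(bp)], right = bp[-1])
}

#' Marginal genealogy at a site
#'
#' @param sim a `tsp_sim`.
#' @param x position in the window.
#' @return A list with `parent` (named by node id, NA at the root), `time`,
#'   and the tip table; pass to [classify_topology()] or [site_tree_phylo()].
#' @export
site_tree <- function(sim, x) {
  stopifnot(inherits(sim, "tsp_sim"), x >= 0, x < sim$L)
  e <- sim$edges[sim$edges$left <= x & sim$edges$right > x, ]
  nodes <- sort(unique(c(e$parent, e$child, sim$tips$id)))
  parent <- rep(NA_integer_, max(nodes))
  parent[e$child] <- e$parent
  list(parent = parent, time = sim$node_time, tips = sim$tips,
       nodes = nodes)
}

#' Convert a marginal genealogy to an ape phylo object
#'
#' Tip labels are `s<species>c<class>_<id>`.
#'
#' @param tree result of [site_tree()].
#' @return An object of class `phylo`.
#' @export
site_tree_phylo <- function(tree) {
  tips <- tree$tips
  ntip <- nrow(tips)
  inner <- setdiff(tree$nodes, tips$id)
  relab <- integer(max(tree$nodes))
  relab[tips$id] <- seq_len(ntip)
  root <- tree$nodes[is.na(tree$parent[tree$nodes])]
  root <- root[!root %in% tips$id]
  inner_sorted <- c(root, setdiff(inner, root))
  relab[inner_sorted] <- ntip + seq_along(inner_sorted)
  has_par <- tree$nodes[!is.na(tree$parent[tree$nodes])]
  edge <- cbind(relab[tree$parent[has_par]], relab[has_par])
  elen <- tree$time[tree$parent[has_par]] - tree$time[has_par]
  phy <- list(edge = edge, edge.length = elen,
              tip.label = sprintf("s%dc%d_%d", tips$species, tips$cls, tips$id),
              Nnode = length(inner_sorted))
  class(phy) <- "phylo"
  ape::collapse.singles(phy)
}

# descendant tip sets of every node present at a site
.tip_sets <- function(tree) {
  ntip <- nrow(tree$tips)
  ord <- as.integer(tree$nodes[order(tree$time[tree$nodes])])
  sets <- vector("list", max(tree$nodes))
  for (n in ord) {
    if (n <= ntip) sets[[n]] <- n
    else {
      ch <- which(tree$parent == n)
      sets[[n]] <- sort(unique(as.integer(unlist(sets[ch]))))
    }
  }
  sets
}

#' Classify the genealogical state of a marginal tree
#'
#' `"ancestral"` when both allelic classes are monophyletic (the tree
#' clusters by allele); `"one-recombined"` when exactly one species is
#' monophyletic (recombination erased the class structure in that species
#' only); `"species-short"`/`"species-long"` when both species are
#' monophyletic, split by whether the two species lineages coalesce within
#' `threshold` generations past the split (a reporting convention mirroring
#' whether the two ancestral lineages carried the same allele); `"other"`
#' for residual configurations.
#'
#' @param tree result of [site_tree()].
#' @param T species split time (generations); taken from the simulation when
#'   classifying via [classify_segments()].
#' @param Na ancestral population size, used for the default threshold.
#' @param threshold time past the split separating short from long
#'   species-clustered states (default 4*Na).
#' @return A character scalar.
#' @export
classify_topology <- function(tree, T, Na, threshold = 4 * Na) {
  tips <- tree$tips
  if (is.null(tips$species) || is.null(tips$cls)) stop("tips must be labelled")
  sets <- .tip_sets(tree)
  ntip <- nrow(tips)
  inner <- setdiff(tree$nodes, tips$id)
  setlist <- lapply(inner, function(n) sets[[n]])
  is_clade <- function(ids) {
    ids <- sort(as.integer(ids))
    length(ids) == 1 ||
      any(vapply(setlist, function(s) identical(s, ids), TRUE))
  }
  cls_mono <- c(is_clade(tips$id[tips$cls == 1L]),
                is_clade(tips$id[tips$cls == 2L]))
  sp_mono <- c(is_clade(tips$id[tips$species == 1L]),
               is_clade(tips$id[tips$species == 2L]))
  if (all(cls_mono)) return("ancestral")
  if (all(sp_mono)) {
    root_t <- max(tree$time[tree$nodes])
    return(if (root_t > T + threshold) "species-long" else "species-short")
  }
  if (xor(sp_mono[1], sp_mono[2])) return("one-recombined")
  "other"
}

#' Topology class of every non-recombining segment
#'
#' @param sim a `tsp_sim`.
#' @param threshold see [classify_topology()].
#' @return The segment table with a `state` column appended.
#' @export
classify_segments <- function(sim, threshold = 4 * sim$params$Na) {
  seg <- sim$segments
  seg$state <- vapply(seq_len(nrow(seg)), function(i) {
    mid <- (seg$left[i] + seg$right[i]) / 2
    classify_topology(site_tree(sim, mid), T = sim$params$T,
                      Na = sim$params$Na, threshold = threshold)
  }, "")
  seg
}

#' Realized extent of the ancestral segment
#'
#' The distance, on each side of the selected site, to the nearest
#' class-switching crossover that occurred before the end of stage II (both
#' allelic classes coalesced to their MRCAs at the selected site). Events
#' later than stage II do not erode the segment.
#'
#' @param sim a `tsp_sim`.
#' @return Named numeric vector `c(left =, right =)` in bp (capped at the
#'   window edges).
#' @export
ancestral_segment_extent <- function(sim) {
  stopifnot(inherits(sim, "tsp_sim"))
  ev <- sim$switch_events
  ev <- ev[ev$time <= sim$stage2_end, ]
  lft <- min(c(ev$dist[ev$side == 1L], sim$selected_pos))
  rgt <- min(c(ev$dist[ev$side == 2L], sim$L - sim$selected_pos))
  c(left = lft, right = rgt)
}

# infinite-sites mutation dropping on the segment mosaic
.drop_mutations <- function(sim, mu) {
  ntip <- nrow(sim$tips)
  seg <- sim$segments
  pos <- numeric(0); cols <- list()
  for (i in seq_len(nrow(seg))) {
    mid <- (seg$left[i] + seg$right[i]) / 2
    e <- sim$edges[sim$edges$left <= mid & sim$edges$right > mid, ]
    if (!nrow(e)) next
    elen <- sim$node_time[e$parent] - sim$node_time[e$child]
    tot <- sum(elen)
    nm <- rpois(1, mu * tot * (seg$right[i] - seg$left[i]))
    if (nm == 0) next
    tree <- site_tree(sim, mid)
    sets <- .tip_sets(tree)
    br <- sample.int(nrow(e), nm, replace = TRUE, prob = elen)
    xs <- runif(nm, seg$left[i], seg$right[i])
    for (m in seq_len(nm)) {
      carriers <- sets[[e$child[br[m]]]]
      col <- integer(ntip); col[carriers] <- 1L
      if (all(col == 1L) || all(col == 0L)) next
      pos <- c(pos, xs[m]); cols[[length(cols) + 1L]] <- col
    }
  }
  if (!length(pos))
    return(list(pos = numeric(0), hap = matrix(integer(0), ntip, 0)))
  o <- order(pos)
  list(pos = pos[o], hap = do.call(cbind, cols)[, o, drop = FALSE])
}

#' Stage-wise simulation of ancestral-segment extents
#'
#' Draws one-sided (or two-sided) segment extents directly from the stage
#' structure of the event process: the class coalescence times t1 and t2 are
#' drawn (from their exponentials, or from per-generation hazards when a
#' frequency trajectory is supplied), and the nearest class-switching
#' crossover on each side is exponential with the summed per-Morgan exposure
#' of the surviving lineages up to the end of stage II (two lineages per
#' class until that class's MRCA, then one). This reproduces the full
#' ancestry simulation's extent law at a fraction of the cost; it differs
#' from the analytic convention of [rseglen()], which keeps all four
#' lineages exposed until max(t1, t2) and therefore yields slightly shorter
#' segments.
#'
#' @param nrep number of replicates.
#' @param params a [model_params()].
#' @param trajectory optional per-generation frequency path of A1 from a
#'   [simulate_overdominance_trajectory()] call, indexed backwards from the
#'   present; beyond its end the equilibrium frequency is used.
#' @param side `"one"` or `"two"`.
#' @param seed optional seed.
#' @return Numeric vector of extents in bp.
#' @export
simulate_segment_extents <- function(nrep, params, trajectory = NULL,
                                     side = c("one", "two"), seed = NULL) {
  side <- match.arg(side)
  if (!is.null(seed)) set.seed(seed)
  p <- params$p; q <- params$q; Na <- params$Na; T <- params$T
  if (is.null(trajectory)) {
    a <- 1 / (2 * Na * p); b <- 1 / (2 * Na * q)
    t1 <- rexp(nrep, a); t2 <- rexp(nrep, b)
    tmax <- pmax(t1, t2)
    expo <- q * (2 * (T + t1) + (tmax - t1)) + p * (2 * (T + t2) + (tmax - t2))
  } else {
    span <- length(trajectory)
    horizon <- max(span, ceiling(T + 40 * Na))
    pt <- c(trajectory, rep(p, horizon - span))
    qt <- 1 - pt
    h1 <- cumsum(c(rep(0, min(T, horizon)),
                   1 / (2 * Na * pt[seq(T + 1, horizon)])))
    h2 <- cumsum(c(rep(0, min(T, horizon)),
                   1 / (2 * Na * qt[seq(T + 1, horizon)])))
    cq <- cumsum(qt); cp <- cumsum(pt)
    drawt <- function(H) {
      u <- rexp(nrep)
      i <- findInterval(u, H) + 1
      pmin(i, length(H)) - T
    }
    t1 <- drawt(h1); t2 <- drawt(h2)
    tmax <- pmax(t1, t2)
    expo_at <- function(cum, tt) cum[pmin(pmax(round(tt), 1), length(cum))]
    expo <- 2 * expo_at(cq, T + t1) + expo_at(cq, T + tmax) -
      expo_at(cq, T + t1) +
      2 * expo_at(cp, T + t2) + expo_at(cp, T + tmax) - expo_at(cp, T + t2)
  }
  x <- rexp(nrep, expo)
  if (side == "two") {
    y <- rexp(nrep, expo)     # the two sides share t1, t2
    x <- x + y
  }
  x / params$r
}

#' Wright-Fisher overdominance frequency trajectory
#'
#' Simulates the allele-frequency path of a balanced polymorphism under
#' symmetric-equilibrium overdominance: homozygote fitnesses 1 - s/(2p_eq)
#' and 1 - s/(2q_eq) against a heterozygote fitness of 1, so that the
#' deterministic equilibrium is p_eq and the harmonic mean of the two
#' homozygote selection coefficients is s. The path is conditioned on
#' segregation throughout (rejection sampling).
#'
#' @param s harmonic-mean homozygote selection coefficient (>= 0).
#' @param N diploid population size.
#' @param span number of generations.
#' @param p_eq equilibrium frequency (default 0.5).
#' @param seed optional seed.
#' @param max_tries rejection budget.
#' @return Numeric vector of length `span` with the frequency of A1 per
#'   generation; the number of rejected paths is attached as attribute
#'   `rejected`.
#' @export
simulate_overdominance_trajectory <- function(s, N, span, p_eq = 0.5,
                                              seed = NULL, max_tries = 1000) {
  stopifnot(s >= 0, N > 0, span >= 1, p_eq > 0, p_eq < 1)
  if (!is.null(seed)) set.seed(seed)
  s1 <- if (s > 0) s / (2 * p_eq) else 0
  s2 <- if (s > 0) s / (2 * (1 - p_eq)) else 0
  if (s1 >= 1 || s2 >= 1) stop("selection too strong for the WF update")
  for (try in seq_len(max_tries)) {
    pvec <- numeric(span)
    x <- p_eq
    okpath <- TRUE
    for (g in seq_len(span)) {
      w11 <- 1 - s1; w22 <- 1 - s2
      wbar <- x^2 * w11 + 2 * x * (1 - x) + (1 - x)^2 * w22
      xdet <- (x^2 * w11 + x * (1 - x)) / wbar
      x <- rbinom(1, 2 * N, xdet) / (2 * N)
      if (x <= 0 || x >= 1) { okpath <- FALSE; break }
      pvec[g] <- x
    }
    if (okpath) {
      attr(pvec, "rejected") <- try - 1L
      return(pvec)
    }
  }
  stop(sprintf("conditioning on segregation failed in %d attempts (%.0f%% lost)",
               max_tries, 100))
}
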