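# Coalescent times of two lineages at a neutral site linked to the balanced
# polymorphism, and the expected number of shared neutral SNPs.
#
# For an infinitely old polymorphism the two allelic classes act as the demes
# of a two-island model (sizes p*Na and q*Na) with "migration" given by
# class-switching recombination (hazard d*q per generation for an A1 lineage
# at genetic distance d, d*p for an A2 lineage). For a polymorphism of finite
# age Ts the process is a discrete-generation absorbing Markov chain: states
# (1,1), (0,2), (2,0) and (*) during the selection phase, then (**) and (*)
# in the neutral phase, with the boundary rule that lineages still carrying
# the derived allele at generation Ts are forced to coalesce (forward in
# time, the derived allele jumped to frequency p when it arose).

.chain_rates <- function(d, Na, p) {
  q <- 1 - p
  list(q = q, c1 = 1 / (2 * Na * p), c2 = 1 / (2 * Na * q),
       cN = 1 / (2 * Na), m1 = d * q, m2 = d * p)
}

#' Expected coalescent times under an infinitely old balanced polymorphism
#'
#' Solves the first-step recursions of the two-island model for the expected
#' coalescent times of two lineages both carrying A1 (`T1`), both carrying A2
#' (`T2`), or one of each (`TB`), at genetic distance `d` from the selected
#' site.
#'
#' @param d genetic distance in Morgans (>= 0).
#' @param Na ancestral diploid effective size.
#' @param p equilibrium frequency of allele A1.
#' @return A list with elements `T1`, `T2`, `TB` (generations). At `d = 0`
#'   the two classes are isolated and `TB` is `Inf`.
#' @export
island_model_times <- function(d, Na, p) {
  stopifnot(d >= 0, Na > 0, p > 0, p < 1)
  rt <- .chain_rates(d, Na, p)
  if (d == 0)
    return(list(T1 = 2 * Na * p, T2 = 2 * Na * (1 - p), TB = Inf))
  q <- rt$q
  # unknowns x = (T1, T2, TB); first-step analysis in continuous time
  A <- rbind(c(rt$c1 + 2 * d * q, 0, -2 * d * q),
             c(0, rt$c2 + 2 * d * p, -2 * d * p),
             c(-d * p, -d * q, d))
  x <- solve(A, c(1, 1, 1))
  list(T1 = x[1], T2 = x[2], TB = x[3])
}

#' Per-generation transition matrices of the coalescent chain
#'
#' Builds the selection-phase matrix `PS` over states (1,1), (0,2), (2,0),
#' (*), the neutral-phase matrix `PN` over (**), (*), and the bridge `QSN`
#' applied at the phase boundary, where (2,0) — two lineages still carrying
#' the derived allele — is forced into (*).
#'
#' @inheritParams island_model_times
#' @return An object of class `tsp_chain` with components `PS`, `PN`, `QSN`,
#'   `d`, `Na`, `p`.
#' @export
chain_matrices <- function(d, Na, p) {
  stopifnot(d >= 0, Na > 0, p > 0, p < 1)
  rt <- .chain_rates(d, Na, p)
  if (d >= 1 || 2 * d * p + rt$c2 > 1 || 2 * d * rt$q + rt$c1 > 1)
    stop("per-generation probabilities exceed 1; ",
         "use a smaller genetic distance d or a larger Na")
  st <- c("(1,1)", "(0,2)", "(2,0)", "(*)")
  PS <- rbind(c(1 - d, rt$m1, rt$m2, 0),
              c(2 * d * p, 1 - 2 * d * p - rt$c2, 0, rt$c2),
              c(2 * d * rt$q, 0, 1 - 2 * d * rt$q - rt$c1, rt$c1),
              c(0, 0, 0, 1))
  dimnames(PS) <- list(st, st)
  PN <- rbind(c(1 - rt$cN, rt$cN), c(0, 1))
  dimnames(PN) <- list(c("(**)", "(*)"), c("(**)", "(*)"))
  QSN <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  dimnames(QSN) <- list(st, c("(**)", "(*)"))
  structure(list(PS = PS, PN = PN, QSN = QSN, d = d, Na = Na, p = p),
            class = "tsp_chain")
}

#' @export
print.tsp_chain <- function(x, ...) {
  cat(sprintf("Coalescent chain at d = %g (Na = %g, p = %g)\nPS:\n",
              x$d, x$Na, x$p))
  print(round(x$PS, 8)); cat("PN:\n"); print(round(x$PN, 8))
  cat("QSN:\n"); print(x$QSN)
  invisible(x)
}

# sum_{k=0}^{n-1} Q^k and Q^n for the 3x3 transient block, by binary doubling
.chain_power_sum <- function(Q, n) {
  S <- matrix(0, nrow(Q), ncol(Q))       # sum over processed prefix
  cur <- diag(nrow(Q))                   # Q^(processed length)
  B <- Q; SB <- diag(nrow(Q))            # B = Q^(2^i), SB = sum_{k < 2^i} Q^k
  while (n > 0) {
    if (n %% 2 == 1) { S <- S + cur %*% SB; cur <- cur %*% B }
    SB <- SB + B %*% SB
    B <- B %*% B
    n <- n %/% 2
  }
  list(sum = S, power = cur)
}

#' Expected between-class coalescent time, numerical chain calculation
#'
#' The expected number of generations for two lineages starting in state
#' (1,1) to enter (*): the survival probabilities of the transient chain are
#' accumulated over the Ts selection-phase generations, the bridge is
#' applied, and the geometric neutral tail is closed analytically
#' (expected extra time 2*Na for mass reaching (**)).
#'
#' @inheritParams island_model_times
#' @param Ts age of the balanced polymorphism in generations (integer >= 0).
#' @param method `"doubling"` (binary power sums, default) or `"iterate"`
#'   (plain generation-by-generation vector iteration; used as an
#'   independent route for validation).
#' @return Expected coalescent time in generations.
#' @export
expected_tb_numeric <- function(d, Na, p, Ts, method = c("doubling", "iterate")) {
  method <- match.arg(method)
  stopifnot(Ts >= 0)
  Ts <- as.integer(round(Ts))
  cm <- chain_matrices(d, Na, p)
  Q <- t(cm$PS[1:3, 1:3])                # column-stochastic transient block
  v0 <- c(1, 0, 0)
  if (method == "doubling") {
    ps <- .chain_power_sum(Q, Ts)
    surv <- sum(ps$sum %*% v0)
    vTs <- as.numeric(ps$power %*% v0)
  } else {
    surv <- 0; v <- v0
    for (k in seq_len(Ts)) { surv <- surv + sum(v); v <- as.numeric(Q %*% v) }
    vTs <- v
  }
  # bridge: (1,1) and (0,2) feed (**); (2,0) is forced into (*) at Ts
  surv + (vTs[1] + vTs[2]) * 2 * Na
}

#' Expected between-class coalescent time, closed-form approximation
#'
#' Ignores recombination after the chain leaves (1,1) (the selection-phase
#' matrix becomes upper triangular), which gives a closed form in geometric
#' sums. The approximation slightly underestimates the numeric expectation
#' because excursions back to (1,1), where coalescence is impossible, are
#' dropped.
#'
#' @inheritParams expected_tb_numeric
#' @return Expected coalescent time in generations (<= the numeric value).
#' @export
expected_tb_approx <- function(d, Na, p, Ts) {
  stopifnot(d >= 0, Na > 0, p > 0, p < 1, Ts >= 0)
  Ts <- round(Ts)
  rt <- .chain_rates(d, Na, p)
  q <- rt$q; c1 <- rt$c1; c2 <- rt$c2
  if (d == 0) return(Ts + 2 * Na)
  u <- 1 - d; v1 <- 1 - c1; v2 <- 1 - c2
  geom <- function(v) {                  # sum_{k=0}^{Ts-1} u^k v^(Ts-1-k)
    if (abs(u - v) < 1e-14) Ts * u^(Ts - 1)
    else (u^Ts - v^Ts) / (u - v)
  }
  s_u <- (1 - u^Ts) / d                  # expected time spent in (1,1)
  G1 <- geom(v1); G2 <- geom(v2)
  s_u + u^Ts * 2 * Na +
    (d * q / c2) * (s_u - G2) + d * q * 2 * Na * G2 +
    (d * p / c1) * (s_u - G1)
}

#' Monte-Carlo simulation of the coalescent chain
#'
#' Simulates the discrete-generation chain directly (vectorised over
#' replicates via geometric waiting times between events), as an independent
#' check of [expected_tb_numeric()].
#'
#' @inheritParams expected_tb_numeric
#' @param nrep number of replicates.
#' @return A numeric vector of absorption times (generations).
#' @export
sim_tb_chain <- function(nrep, d, Na, p, Ts) {
  cm <- chain_matrices(d, Na, p)          # validates rates
  rt <- .chain_rates(d, Na, p)
  q <- rt$q; c1 <- rt$c1; c2 <- rt$c2; cN <- rt$cN
  Ts <- round(Ts)
  t <- numeric(nrep); st <- rep(1L, nrep); out <- rep(NA_real_, nrep)
  neutral_tail <- function(k) Ts + rgeom(k, cN) + 1
  while (any(is.na(out))) {
    i1 <- which(is.na(out) & st == 1L)
    if (length(i1)) {
      if (d == 0) { out[i1] <- neutral_tail(length(i1)) }
      else {
        g <- rgeom(length(i1), d) + 1
        over <- t[i1] + g > Ts
        out[i1[over]] <- neutral_tail(sum(over))
        stay <- i1[!over]
        t[stay] <- t[stay] + g[!over]
        st[stay] <- ifelse(runif(length(stay)) < q, 2L, 3L)
      }
    }
    i2 <- which(is.na(out) & st == 2L)
    if (length(i2)) {
      h <- c2 + 2 * d * p
      g <- rgeom(length(i2), h) + 1
      over <- t[i2] + g > Ts
      out[i2[over]] <- neutral_tail(sum(over))
      stay <- i2[!over]
      t[stay] <- t[stay] + g[!over]
      coal <- runif(length(stay)) < c2 / h
      out[stay[coal]] <- t[stay[coal]]
      st[stay[!coal]] <- 1L
    }
    i3 <- which(is.na(out) & st == 3L)
    if (length(i3)) {
      h <- c1 + 2 * d * q
      g <- rgeom(length(i3), h) + 1
      over <- t[i3] + g > Ts
      out[i3[over]] <- Ts                # forced coalescence of (2,0)
      stay <- i3[!over]
      t[stay] <- t[stay] + g[!over]
      coal <- runif(length(stay)) < c1 / h
      out[stay[coal]] <- t[stay[coal]]
      st[stay[!coal]] <- 1L
    }
  }
  out
}

#' Expected number of shared neutral SNPs in the ancestral segment
#'
#' Sums, over base-pair distances i on both sides of the selected site, the
#' probability that site i lies inside the (one-sided) ancestral segment
#' times the expected number of mutations on the two stage-III branches,
#' 2 * mu * E[TB(r * i)], and adds 1 for the selected SNP itself. In
#' `"marginal"` mode the inclusion probability is the segment-length survival
#' function; in `"fixed"` mode a segment of total length `L_fixed` bp
#' (excluding the selected site, split evenly between the sides) is assumed.
#'
#' The polymorphism age can be given either as `Ts` (generations before the
#' end of stage II) or as `age` measured from the present, which is converted
#' by subtracting the expected span of stages I and II: the split time T plus
#' E[max(t1, t2)] (plus 4*Ne when `include_stage1 = TRUE`, an optional extra
#' allowance for within-species coalescence in large samples).
#'
#' @param params optional `tsp_params`; individual arguments override it.
#' @param Na,T,p,r,mu,Ne model parameters.
#' @param Ts polymorphism age in generations from the end of stage II.
#' @param age polymorphism age in generations from the present (alternative
#'   to `Ts`; must exceed the expected stage I+II span).
#' @param mode `"marginal"` (default) or `"fixed"`.
#' @param L_fixed total segment length in bp for `"fixed"` mode.
#' @param include_stage1 subtract an extra 4*Ne when converting `age`.
#' @return Expected total number of shared SNPs (including the selected one),
#'   with the `Ts` used attached as an attribute.
#' @export
expected_shared_snps <- function(params = NULL, Na = NULL, T = NULL, p = NULL,
                                 r = NULL, mu = NULL, Ne = NULL,
                                 Ts = NULL, age = NULL,
                                 mode = c("marginal", "fixed"),
                                 L_fixed = NULL, include_stage1 = FALSE) {
  mode <- match.arg(mode)
  if (!is.null(params)) {
    stopifnot(inherits(params, "tsp_params"))
    if (is.null(Na)) Na <- params$Na
    if (is.null(T)) T <- params$T
    if (is.null(p)) p <- params$p
    if (is.null(r)) r <- params$r
    if (is.null(mu)) mu <- params$mu
    if (is.null(Ne)) Ne <- params$Ne
    if (is.null(Ts) && is.null(age)) Ts <- params$Ts
  }
  stopifnot(Na > 0, T > 0, p > 0, p < 1, r > 0, mu >= 0)
  if (is.null(Ts)) {
    if (is.null(age)) stop("supply either `Ts` or `age`")
    rt <- .seg_rates(Na, p)
    emax <- 1 / rt$a + 1 / rt$b - 1 / (rt$a + rt$b)
    stage12 <- T + emax + if (include_stage1) {
      if (is.null(Ne)) stop("`Ne` needed when include_stage1 = TRUE")
      4 * Ne
    } else 0
    if (age < stage12)
      stop("`age` is smaller than the expected span of stages I and II (",
           round(stage12), " generations)")
    Ts <- age - stage12
  }
  if (mu == 0) {
    res <- 1
    attr(res, "Ts") <- Ts
    return(res)
  }
  d1 <- one_sided_length(Na = Na, T = T, p = p, r = r)
  if (mode == "marginal") {
    imax <- 10 * ceiling(mean(d1))
    while (seg_survival(d1, imax) > 1e-7) imax <- imax * 2
    i <- seq_len(imax)
    w <- seg_survival(d1, i)
    keep <- w > 1e-9
    i <- i[keep]; w <- w[keep]
  } else {
    if (is.null(L_fixed)) stop("`L_fixed` required for mode = \"fixed\"")
    if (L_fixed < 1) {
      res <- 1
      attr(res, "Ts") <- Ts
      return(res)
    }
    i <- seq_len(round(L_fixed / 2))
    w <- rep(1, length(i))
  }
  etb <- vapply(i * r, expected_tb_numeric, 0, Na = Na, p = p, Ts = Ts)
  res <- 1 + 2 * sum(w * 2 * mu * etb)
  attr(res, "Ts") <- Ts
  res
}
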