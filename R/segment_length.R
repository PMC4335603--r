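# Length distribution of the ancestral segment.
#
# Around the selected site, the ancestral segment is eroded by class-switching
# (between-class) recombination on the four stage-II lineages. Conditional on
# the extra coalescence time t in the ancestral species, the one-sided length
# X (in Morgans) is exponential with rate 2(T + t): each of the four lineages
# accrues switching hazard r * (opposite-class frequency) per bp, and the four
# opposite-class frequencies sum to 2(p + q) = 2 per Morgan, so the total does
# not depend on p. Marginalising over t = max(t1, t2), with t1 ~ Exp(rate
# 1/(2*Na*p)) and t2 ~ Exp(rate 1/(2*Na*q)), gives closed forms in terms of
# the Laplace transform of the density of t.

# e^z * E1(z), stable for large z (continued fraction beyond the range where
# exp(z) is representable).
.expE1 <- function(z) {
  out <- numeric(length(z))
  small <- z < 50
  if (any(small)) out[small] <- exp(z[small]) * pracma::expint_E1(z[small])
  if (any(!small)) {
    zz <- z[!small]
    # Lentz continued fraction for e^z E1(z) = 1/(z + 1/(1 + 1/(z + 2/(1 + ...))))
    f <- vapply(zz, function(x) {
      b0 <- x; C <- b0; D <- 0; f <- b0
      for (i in 1:60) {
        a <- ceiling(i / 2)
        b <- if (i %% 2 == 1) 1 else x
        D <- b + a * D; if (D == 0) D <- 1e-300
        C <- b + a / C; if (C == 0) C <- 1e-300
        D <- 1 / D
        delta <- C * D
        f <- f * delta
        if (abs(delta - 1) < 1e-15) break
      }
      1 / f
    }, 0)
    out[!small] <- f
  }
  out
}

# rates of the two within-class coalescence processes in the ancestral species
.seg_rates <- function(Na, p) {
  list(a = 1 / (2 * Na * p), b = 1 / (2 * Na * (1 - p)))
}

#' Density of the stage-II extra coalescence time
#'
#' The two A1 lineages coalesce in the ancestral species after
#' t1 ~ Exponential(rate 1/(2*Na*p)) generations, the two A2 lineages after
#' t2 ~ Exponential(rate 1/(2*Na*q)); the extra duration of stage II is
#' t = max(t1, t2). This returns the density of t.
#'
#' @param t time in generations (vectorised, >= 0).
#' @param Na ancestral diploid effective size.
#' @param p equilibrium frequency of allele A1.
#' @return Density values.
#' @export
stage2_time_density <- function(t, Na, p) {
  stopifnot(all(t >= 0), Na > 0, p > 0, p < 1)
  r <- .seg_rates(Na, p)
  a <- r$a; b <- r$b
  a * exp(-a * t) * (1 - exp(-b * t)) + b * exp(-b * t) * (1 - exp(-a * t))
}

# Laplace transform M(s) = E[e^(-s t)] of the stage-II time and its negated
# derivative G(s) = E[t e^(-s t)].
.seg_M <- function(s, a, b) a / (a + s) + b / (b + s) - (a + b) / (a + b + s)
.seg_G <- function(s, a, b) a / (a + s)^2 + b / (b + s)^2 - (a + b) / (a + b + s)^2

#' One-sided length distribution of the ancestral segment
#'
#' Builds the marginal law of the one-sided segment length X (distance from
#' the selected site to the nearest class-switching crossover accrued during
#' stage II) for given ancestral size, split time and allele frequency.
#' Survival, density, mean and quantiles are available through
#' [seg_survival()], [seg_density()], [mean()][mean.seglen_dist] and
#' [quantile()][quantile.seglen_dist], in Morgans or in base pairs (using the
#' recombination rate `r` as the conversion factor).
#'
#' @param params optional `tsp_params`; individual arguments override it.
#' @param Na,T,p,r model parameters (see [model_params()]).
#' @return An object of class `seglen_dist`.
#' @examples
#' d <- one_sided_length(Na = 5e4, T = 2.5e5, p = 0.5, r = 1.2e-8)
#' mean(d)                      # about 131 bp
#' quantile(d, 0.95)            # about 400 bp
#' @export
one_sided_length <- function(params = NULL, Na = NULL, T = NULL, p = NULL,
                             r = NULL) {
  if (!is.null(params)) {
    stopifnot(inherits(params, "tsp_params"))
    if (is.null(Na)) Na <- params$Na
    if (is.null(T)) T <- params$T
    if (is.null(p)) p <- params$p
    if (is.null(r)) r <- params$r
  }
  stopifnot(is.finite(Na), Na > 0, is.finite(T), T > 0,
            is.finite(p), p > 0, p < 1, is.finite(r), r > 0)
  rt <- .seg_rates(Na, p)
  a <- rt$a; b <- rt$b
  mean_m <- (a / 2) * .expE1(a * T) + (b / 2) * .expE1(b * T) -
    ((a + b) / 2) * .expE1((a + b) * T)
  structure(list(side = "one", Na = Na, T = T, p = p, r = r,
                 a = a, b = b, mean_morgans = mean_m),
            class = "seglen_dist")
}

# survival/density of the one-sided law at x in Morgans
.seg1_surv <- function(d, x) {
  ifelse(x < 0, 1, exp(-2 * d$T * x) * .seg_M(2 * x, d$a, d$b))
}
.seg1_dens <- function(d, x) {
  ifelse(x < 0, 0,
         exp(-2 * d$T * x) *
           (2 * d$T * .seg_M(2 * x, d$a, d$b) + 2 * .seg_G(2 * x, d$a, d$b)))
}

#' Two-sided length distribution of the ancestral segment
#'
#' Erosion on the two sides of the selected site is treated as independent,
#' so the total length is distributed as the convolution of the one-sided law
#' with itself. The convolution is carried out numerically on a regular grid;
#' the grid spacing is `resolution_bp` base-pair equivalents (default 0.05 bp).
#'
#' @inheritParams one_sided_length
#' @param resolution_bp grid spacing of the numeric convolution, in bp.
#' @return An object of class `seglen_dist` with `side = "two"`.
#' @examples
#' d2 <- two_sided_length(Na = 5e4, T = 2.5e5, p = 0.5, r = 1.2e-8)
#' mean(d2)                     # about 263 bp
#' @export
two_sided_length <- function(params = NULL, Na = NULL, T = NULL, p = NULL,
                             r = NULL, resolution_bp = 0.05) {
  d1 <- one_sided_length(params, Na = Na, T = T, p = p, r = r)
  if (resolution_bp <= 0) stop("`resolution_bp` must be positive")
  dx <- resolution_bp * d1$r                   # grid step in Morgans
  # extend until the one-sided survival is negligible
  xmax <- 10 * d1$mean_morgans
  while (.seg1_surv(d1, xmax) > 1e-12) xmax <- xmax * 2
  ngrid <- ceiling(xmax / dx)
  if (ngrid > 4e6)
    stop("convolution grid too large; increase `resolution_bp`")
  if (ngrid < 200)
    stop("convolution grid too coarse for the requested tolerance; ",
         "decrease `resolution_bp`")
  x <- seq(0, by = dx, length.out = ngrid)
  f1 <- .seg1_dens(d1, x)
  f2 <- convolve(f1, rev(f1), type = "open")[seq_len(2 * ngrid - 1)] * dx
  f2[f2 < 0] <- 0
  x2 <- seq(0, by = dx, length.out = 2 * ngrid - 1)
  cdf <- cumsum(f2) * dx
  cdf <- pmin(cdf / max(cdf[length(cdf)], 1), 1)
  structure(list(side = "two", Na = d1$Na, T = d1$T, p = d1$p, r = d1$r,
                 a = d1$a, b = d1$b,
                 mean_morgans = 2 * d1$mean_morgans,
                 grid = list(x = x2, dens = f2, cdf = cdf)),
            class = "seglen_dist")
}

.seg_units <- function(units) match.arg(units, c("bp", "morgans"))

#' Survival function of a segment-length distribution
#'
#' @param dist a `seglen_dist`.
#' @param x lengths (vectorised).
#' @param units `"bp"` or `"morgans"`.
#' @return P(X > x).
#' @export
seg_survival <- function(dist, x, units = c("bp", "morgans")) {
  stopifnot(inherits(dist, "seglen_dist"))
  units <- .seg_units(units)
  xm <- if (units == "bp") x * dist$r else x
  if (dist$side == "one") return(.seg1_surv(dist, xm))
  g <- dist$grid
  1 - approx(g$x, g$cdf, xout = pmax(xm, 0), yleft = 0, yright = 1,
             rule = 2)$y
}

#' Density of a segment-length distribution
#'
#' @inheritParams seg_survival
#' @return Density values (per bp or per Morgan according to `units`).
#' @export
seg_density <- function(dist, x, units = c("bp", "morgans")) {
  stopifnot(inherits(dist, "seglen_dist"))
  units <- .seg_units(units)
  xm <- if (units == "bp") x * dist$r else x
  dens <- if (dist$side == "one") .seg1_dens(dist, xm)
  else approx(dist$grid$x, dist$grid$dens, xout = xm, yleft = 0,
              yright = 0, rule = 2)$y
  if (units == "bp") dens * dist$r else dens
}

#' @describeIn one_sided_length Mean segment length.
#' @param x a `seglen_dist`.
#' @param units `"bp"` or `"morgans"`.
#' @param ... unused.
#' @export
mean.seglen_dist <- function(x, units = c("bp", "morgans"), ...) {
  units <- .seg_units(units)
  if (units == "bp") x$mean_morgans / x$r else x$mean_morgans
}

#' Quantiles of a segment-length distribution
#'
#' Solves the survival function for the requested level to a relative
#' tolerance of 1e-8.
#'
#' @param x a `seglen_dist`.
#' @param probs probability levels in [0, 1).
#' @param units `"bp"` or `"morgans"`.
#' @param ... unused.
#' @return Quantiles in the requested units.
#' @export
quantile.seglen_dist <- function(x, probs = c(0.5, 0.95),
                                 units = c("bp", "morgans"), ...) {
  stopifnot(all(probs >= 0), all(probs < 1))
  units <- .seg_units(units)
  qm <- vapply(probs, function(pr) {
    if (pr == 0) return(0)
    hi <- 4 * x$mean_morgans
    while (seg_survival(x, hi, units = "morgans") > 1 - pr) hi <- hi * 2
    uniroot(function(z) seg_survival(x, z, units = "morgans") - (1 - pr),
            lower = 0, upper = hi, tol = 1e-8 * hi)$root
  }, 0)
  if (units == "bp") qm / x$r else qm
}

#' @export
print.seglen_dist <- function(x, ...) {
  cat(sprintf("%s-sided ancestral-segment length distribution\n",
              if (x$side == "one") "One" else "Two"))
  cat(sprintf("  Na = %g, T = %g, p = %g, r = %g\n", x$Na, x$T, x$p, x$r))
  cat(sprintf("  mean = %.4g bp (%.4g Morgans), 95%% quantile = %.4g bp\n",
              mean(x), x$mean_morgans, quantile(x, 0.95)))
  invisible(x)
}

#' Monte-Carlo draws from the stage-wise segment-length model
#'
#' Draws segment lengths by simulating the stages directly: t1 and t2 are
#' drawn from their exponentials, and conditional on t = max(t1, t2) the
#' nearest class-switching crossover is exponential with the summed exposure
#' of the four stage-II lineages, 2(T + t) per Morgan (the same exposure
#' convention as the analytic law, which this sampler exists to validate).
#' For `side = "two"` the two sides are drawn independently and summed.
#'
#' @inheritParams one_sided_length
#' @param nrep number of draws.
#' @param side `"one"` or `"two"`.
#' @param units `"bp"` or `"morgans"`.
#' @return A numeric vector of segment lengths.
#' @export
rseglen <- function(nrep, params = NULL, Na = NULL, T = NULL, p = NULL,
                    r = NULL, side = c("one", "two"),
                    units = c("bp", "morgans")) {
  side <- match.arg(side)
  units <- .seg_units(units)
  d <- one_sided_length(params, Na = Na, T = T, p = p, r = r)
  draw1 <- function(n) {
    t1 <- rexp(n, d$a); t2 <- rexp(n, d$b)
    rexp(n, 2 * (d$T + pmax(t1, t2)))
  }
  xm <- draw1(nrep)
  if (side == "two") xm <- xm + draw1(nrep)
  if (units == "bp") xm / d$r else xm
}
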