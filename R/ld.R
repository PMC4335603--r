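# Pairwise LD summaries for phased haplotype counts, the coupling-phase
# comparison across species, and the stage-I retention probability R_n that
# underlies the LD expected between the selected site and shared SNPs.

#' Two-locus haplotype counts
#'
#' Counts of the four phased haplotypes A1B1, A1B2, A2B1, A2B2 for one
#' species. Allele labels must be assigned consistently across species when
#' phases are to be compared; [coupling_phase()] relies on a fixed labelling.
#'
#' @param n11,n12,n21,n22 haplotype counts (or a single length-4 vector in
#'   that order as `n11`).
#' @return An object of class `hap_table`.
#' @examples
#' haplotype_table(10, 0, 0, 10)   # two haplotypes, perfect LD
#' @export
haplotype_table <- function(n11, n12 = NULL, n21 = NULL, n22 = NULL) {
  if (is.null(n12) && length(n11) == 4) {
    n <- as.numeric(n11)
  } else {
    n <- c(n11, n12, n21, n22)
  }
  stopifnot(length(n) == 4, all(n >= 0), sum(n) >= 2)
  structure(matrix(n, 2, 2, byrow = TRUE,
                   dimnames = list(c("A1", "A2"), c("B1", "B2"))),
            class = c("hap_table", "matrix"))
}

#' Pairwise linkage disequilibrium from phased haplotype counts
#'
#' Standard two-locus summaries: D = f(A1B1) - f(A1) f(B1), D' (D scaled by
#' its frequency bound) and r^2 = D^2 / (f(A1) f(A2) f(B1) f(B2)). If either
#' locus is monomorphic the LD is undefined and all values are `NA` (with
#' `defined = FALSE`).
#'
#' @param table a [haplotype_table()].
#' @return A list with `D`, `Dprime`, `r2`, `n`, and `defined`.
#' @export
pairwise_ld <- function(table) {
  stopifnot(inherits(table, "hap_table"))
  n <- sum(table)
  f <- table / n
  pA <- sum(f[1, ]); pB <- sum(f[, 1])
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    return(list(D = NA_real_, Dprime = NA_real_, r2 = NA_real_, n = n,
                defined = FALSE))
  D <- f[1, 1] - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
  else min(pA * pB, (1 - pA) * (1 - pB))
  list(D = D,
       Dprime = if (dmax == 0) 0 else abs(D) / dmax,
       r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)),
       n = n, defined = TRUE)
}

#' Chi-squared test of LD on phased haplotypes
#'
#' The 1-df statistic chi^2 = n * r^2, without continuity correction, on
#' phased haplotype counts.
#'
#' @param table a [haplotype_table()].
#' @param alpha significance level (default 0.05).
#' @return A list with `chi2`, `p_value`, `significant`; all `NA`/`FALSE` if
#'   LD is undefined.
#' @export
ld_significance <- function(table, alpha = 0.05) {
  ld <- pairwise_ld(table)
  if (!ld$defined)
    return(list(chi2 = NA_real_, p_value = NA_real_, significant = FALSE))
  chi2 <- ld$n * ld$r2
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  list(chi2 = chi2, p_value = p, significant = p < alpha)
}

#' Coupling phase of a SNP pair across two species
#'
#' Compares the sign of D in the two species under a common allele
#' labelling: `"same"` alleles in coupling when the signs agree, `"opposite"`
#' when they differ, `"indeterminate"` when D = 0 or undefined in either.
#'
#' @param tableA,tableB [haplotype_table()]s for the two species, with the
#'   same allele labelling at both loci.
#' @return `"same"`, `"opposite"`, or `"indeterminate"`.
#' @export
coupling_phase <- function(tableA, tableB) {
  la <- pairwise_ld(tableA); lb <- pairwise_ld(tableB)
  if (!la$defined || !lb$defined || la$D == 0 || lb$D == 0)
    return("indeterminate")
  if (sign(la$D) == sign(lb$D)) "same" else "opposite"
}

#' Stage-I retention probability R_n
#'
#' The probability that a sampled lineage from a class of n same-allele
#' chromosomes experiences no class-switching recombination during stage I
#' (the within-species coalescence of the n class members into one), at
#' genetic distance d. The default method simulates the class coalescent
#' (coalescence rate k(k-1)/2 / (2*Ne*p) among k lineages, switch-out hazard
#' d*q per lineage) and reports the mean fraction of the n tips whose
#' ancestral path reaches the class MRCA unswitched. The `"approx"` method
#' is the closed form E[exp(-d*q*T_mrca)] (the Laplace transform of the
#' class T_mrca), which ignores the feedback of switched lineages on the
#' coalescent and underestimates retention.
#'
#' @param n lineages sampled from the class.
#' @param p frequency of the focal class (class size is p * Ne).
#' @param Ne diploid effective size of the species.
#' @param d genetic distance in Morgans (vectorised).
#' @param method `"simulation"` or `"approx"`.
#' @param nrep simulation replicates per d.
#' @return A data.frame with columns `d`, `Rn`, and (for the simulation)
#'   `se`.
#' @export
retention_probability <- function(n, p, Ne, d, method = c("simulation", "approx"),
                                  nrep = 2000) {
  method <- match.arg(method)
  stopifnot(n >= 1, p > 0, p < 1, Ne > 0, all(d >= 0))
  q <- 1 - p
  if (method == "approx") {
    lam <- (2:max(n, 2)) * ((2:max(n, 2)) - 1) / 2 / (2 * Ne * p)
    Rn <- vapply(d, function(dd) {
      if (n == 1 || dd == 0) return(1)
      prod(lam / (lam + dd * q))
    }, 0)
    return(data.frame(d = d, Rn = Rn))
  }
  sim_one <- function(dd) {
    if (n == 1 || dd == 0) return(1)
    kept <- vapply(seq_len(nrep), function(i) {
      sets <- as.list(seq_len(n))       # tip sets below each active lineage
      ok <- rep(TRUE, n)
      while (length(sets) > 1) {
        k <- length(sets)
        crate <- k * (k - 1) / 2 / (2 * Ne * p)
        srate <- k * dd * q
        if (runif(1) < srate / (crate + srate)) {
          i <- sample.int(k, 1)          # this path switches class
          ok[sets[[i]]] <- FALSE
          sets[[i]] <- NULL
        } else {
          ij <- sample.int(k, 2)
          sets[[ij[1]]] <- c(sets[[ij[1]]], sets[[ij[2]]])
          sets[[ij[2]]] <- NULL
        }
      }
      mean(ok)
    }, 0)
    c(mean(kept), sd(kept) / sqrt(nrep))
  }
  res <- vapply(d, function(dd) {
    v <- sim_one(dd)
    if (length(v) == 1) c(v, 0) else v
  }, c(0, 0))
  data.frame(d = d, Rn = res[1, ], se = res[2, ])
}
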