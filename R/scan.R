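# Scanner for trans-species polymorphism candidates in two-species variant
# data: identical-allele shared SNPs, single-linkage clusters, LD/coupling
# tests, CpG annotation and a Table-style report.
#
# Coordinates are 0-based half-open internally; VCF positions (1-based) are
# converted at the boundary. Allele matching requires literal identity of
# REF and ALT — no strand-complement rescue — and mismatches are counted so
# that systematic strand problems surface.

#' Read a phased biallelic SNP table from a VCF file
#'
#' Keeps biallelic SNP records with fully phased genotypes; multiallelic or
#' non-SNP records are skipped with a warning. Positions are returned
#' 0-based.
#'
#' @param path VCF file path (or a `vcfR` object).
#' @return A list with `pos` (0-based), `ref`, `alt`, `hap` (chromosomes x
#'   sites matrix of 0 = REF / 1 = ALT), `n_skipped`.
#' @export
read_species_vcf <- function(path) {
  v <- if (inherits(path, "vcfR")) path
  else vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- !is.na(ref) & !is.na(alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snp)
  if (n_skipped)
    warning(n_skipped, " non-biallelic-SNP record(s) skipped")
  gt <- vcfR::extract.gt(v)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  gt <- gt[snp, , drop = FALSE]
  pos <- as.numeric(fix[snp, "POS"]) - 1
  if (is.unsorted(pos)) stop("VCF positions are not sorted")
  if (any(grepl("/", gt)))
    stop("unphased genotypes found; the scanner requires phased GT")
  hapl <- do.call(rbind, strsplit(as.vector(t(gt)), "|", fixed = TRUE))
  nsamp <- ncol(gt)
  ploidy <- ncol(hapl)
  hap <- matrix(as.integer(t(hapl)), nrow = nsamp * ploidy,
                ncol = length(pos))
  list(pos = pos, ref = ref[snp], alt = alt[snp], hap = hap,
       n_skipped = n_skipped)
}

#' Find SNPs shared between two species with identical alleles
#'
#' Positions segregating in both species with literally identical REF and
#' ALT alleles. Positions present in both with mismatched alleles are
#' excluded and counted (attribute `n_mismatched`).
#'
#' @param sp1,sp2 results of [read_species_vcf()] (or VCF paths).
#' @return A data.frame (class `shared_snps`) with columns `pos`, `ref`,
#'   `alt`, `af1`, `af2`, `idx1`, `idx2`; the two haplotype matrices are
#'   attached as attributes `hap1`, `hap2`.
#' @export
find_shared_snps <- function(sp1, sp2) {
  if (!is.list(sp1) || is.null(sp1$hap)) sp1 <- read_species_vcf(sp1)
  if (!is.list(sp2) || is.null(sp2$hap)) sp2 <- read_species_vcf(sp2)
  common <- intersect(sp1$pos, sp2$pos)
  i1 <- match(common, sp1$pos); i2 <- match(common, sp2$pos)
  seg1 <- colMeans(sp1$hap[, i1, drop = FALSE])
  seg2 <- colMeans(sp2$hap[, i2, drop = FALSE])
  segregating <- seg1 > 0 & seg1 < 1 & seg2 > 0 & seg2 < 1
  match_alleles <- sp1$ref[i1] == sp2$ref[i2] & sp1$alt[i1] == sp2$alt[i2]
  keep <- segregating & match_alleles
  res <- data.frame(pos = common[keep],
                    ref = sp1$ref[i1][keep], alt = sp1$alt[i1][keep],
                    af1 = seg1[keep], af2 = seg2[keep],
                    idx1 = i1[keep], idx2 = i2[keep])
  res <- res[order(res$pos), ]
  rownames(res) <- NULL
  class(res) <- c("shared_snps", "data.frame")
  attr(res, "n_mismatched") <- sum(segregating & !match_alleles)
  attr(res, "hap1") <- sp1$hap
  attr(res, "hap2") <- sp2$hap
  attr(res, "sp1") <- sp1[c("pos", "ref", "alt")]
  attr(res, "sp2") <- sp2[c("pos", "ref", "alt")]
  attr(res, "af_all1") <- colMeans(sp1$hap)
  attr(res, "af_all2") <- colMeans(sp2$hap)
  res
}

# 2x2 phased haplotype table for shared SNPs a, b (rows of `shared`)
.shared_hap_table <- function(hap, ia, ib) {
  haplotype_table(sum(hap[, ia] == 1 & hap[, ib] == 1),
                  sum(hap[, ia] == 1 & hap[, ib] == 0),
                  sum(hap[, ia] == 0 & hap[, ib] == 1),
                  sum(hap[, ia] == 0 & hap[, ib] == 0))
}

#' Flag a CpG dinucleotide context
#'
#' TRUE when the site lies in a CG dinucleotide on either strand, i.e. the
#' reference trinucleotide around the site contains CG overlapping the
#' middle base; `NA` when the context is unavailable.
#'
#' @param context character vector of reference trinucleotides (site in the
#'   middle), or `NA`.
#' @return Logical vector (`NA` = unknown).
#' @export
cpg_flag <- function(context) {
  vapply(toupper(context), function(ctx) {
    if (is.na(ctx) || nchar(ctx) != 3) return(NA)
    substr(ctx, 1, 2) == "CG" || substr(ctx, 2, 3) == "CG"
  }, NA, USE.NAMES = FALSE)
}

# trinucleotide contexts from a reference sequence (character vector of
# bases, 0-based positions)
.contexts_from_ref <- function(refseq, pos) {
  vapply(pos, function(x) {
    if (x < 1 || x + 1 >= length(refseq)) return(NA_character_)
    paste(toupper(refseq[(x):(x + 2)]), collapse = "")
  }, "")
}

#' Cluster shared SNPs and build a report
#'
#' Single-linkage clustering at `window_bp`; per cluster the span (distance
#' between the two outermost shared SNPs in significant LD in both species),
#' SNP counts (all and non-CpG when a reference is supplied), the coupling
#' phase consensus within the cluster, and whether any fixed inter-species
#' difference falls inside the span. Cross-cluster coupling phases are
#' reported for cluster pairs with at least one both-species-significant SNP
#' pair.
#'
#' @param shared a [find_shared_snps()] result.
#' @param window_bp clustering window (default 400).
#' @param alpha significance level of the chi-squared LD test.
#' @param ref_fasta optional reference FASTA path (or a character vector of
#'   bases) for CpG context.
#' @return A list of class `shared_snp_report` with elements `clusters`,
#'   `snps`, `between`, `n_mismatched`.
#' @export
cluster_and_report <- function(shared, window_bp = 400, alpha = 0.05,
                               ref_fasta = NULL) {
  stopifnot(inherits(shared, "shared_snps"))
  hap1 <- attr(shared, "hap1"); hap2 <- attr(shared, "hap2")
  ns <- nrow(shared)
  cpg <- rep(NA, ns)
  if (!is.null(ref_fasta) && ns > 0) {
    refseq <- if (is.character(ref_fasta) && length(ref_fasta) == 1 &&
                  file.exists(ref_fasta)) {
      as.character(ape::read.FASTA(ref_fasta))[[1]]
    } else as.character(ref_fasta)
    cpg <- cpg_flag(.contexts_from_ref(refseq, shared$pos))
  }
  if (ns == 0) {
    out <- list(clusters = data.frame(), snps = data.frame(),
                between = data.frame(),
                n_mismatched = attr(shared, "n_mismatched"))
    class(out) <- "shared_snp_report"
    return(out)
  }
  cl <- cumsum(c(1, diff(shared$pos) > window_bp))
  snps <- data.frame(pos = shared$pos, ref = shared$ref, alt = shared$alt,
                     af1 = shared$af1, af2 = shared$af2,
                     cpg = cpg, cluster = cl)
  # pairwise LD among all shared SNPs, both species
  prs <- if (ns >= 2) combn(ns, 2) else matrix(integer(0), 2, 0)
  pair_tab <- data.frame()
  if (ncol(prs)) {
    pair_tab <- do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
      a <- prs[1, j]; b <- prs[2, j]
      t1 <- .shared_hap_table(hap1, shared$idx1[a], shared$idx1[b])
      t2 <- .shared_hap_table(hap2, shared$idx2[a], shared$idx2[b])
      s1 <- ld_significance(t1, alpha); s2 <- ld_significance(t2, alpha)
      data.frame(a = a, b = b, cl_a = cl[a], cl_b = cl[b],
                 r2_1 = pairwise_ld(t1)$r2, r2_2 = pairwise_ld(t2)$r2,
                 sig_both = isTRUE(s1$significant) && isTRUE(s2$significant),
                 phase = coupling_phase(t1, t2))
    }))
  }
  fixed_pos <- .fixed_difference_positions(shared)
  clusters <- do.call(rbind, lapply(sort(unique(cl)), function(cc) {
    ii <- which(cl == cc)
    span <- 0
    if (length(ii) >= 2) {
      pp <- pair_tab[pair_tab$cl_a == cc & pair_tab$cl_b == cc &
                       pair_tab$sig_both, , drop = FALSE]
      if (nrow(pp))
        span <- max(abs(shared$pos[pp$b] - shared$pos[pp$a]))
    }
    within <- pair_tab[pair_tab$cl_a == cc & pair_tab$cl_b == cc, ,
                       drop = FALSE]
    phase <- if (!nrow(within)) "indeterminate"
    else if (all(within$phase == "same")) "same"
    else if (all(within$phase == "opposite")) "opposite"
    else "mixed"
    lo <- min(shared$pos[ii]); hi <- max(shared$pos[ii])
    data.frame(cluster = cc, start = lo, end = hi,
               n_snps = length(ii),
               n_noncpg = if (all(is.na(cpg[ii]))) NA_integer_
               else sum(!cpg[ii], na.rm = TRUE),
               span = span, phase_within = phase,
               fixed_diff_in_span = any(fixed_pos >= lo & fixed_pos <= hi))
  }))
  between <- data.frame()
  if (ncol(prs)) {
    cross <- pair_tab[pair_tab$cl_a != pair_tab$cl_b, , drop = FALSE]
    if (nrow(cross)) {
      key <- paste(cross$cl_a, cross$cl_b)
      between <- do.call(rbind, lapply(unique(key), function(k) {
        g <- cross[key == k, , drop = FALSE]
        gs <- g[g$sig_both, , drop = FALSE]
        ph <- if (!nrow(gs)) "indeterminate"
        else if (all(gs$phase == "same")) "same"
        else if (all(gs$phase == "opposite")) "opposite" else "mixed"
        data.frame(cluster_a = g$cl_a[1], cluster_b = g$cl_b[1],
                   n_pairs = nrow(g), n_sig_both = nrow(gs), phase = ph)
      }))
    }
  }
  out <- list(clusters = clusters, snps = snps, between = between,
              pairs = pair_tab,
              n_mismatched = attr(shared, "n_mismatched"))
  class(out) <- "shared_snp_report"
  out
}

# positions fixed for different alleles in the two species, as far as the
# two single-species VCFs reveal them: a record with allele frequency 1 in
# one species while the other species is fixed REF there (no record), or
# records at the same position fixed for different ALTs
.fixed_difference_positions <- function(shared) {
  s1 <- attr(shared, "sp1"); s2 <- attr(shared, "sp2")
  af1 <- attr(shared, "af_all1"); af2 <- attr(shared, "af_all2")
  fix1 <- s1$pos[af1 == 1]; fix2 <- s2$pos[af2 == 1]
  alt1 <- s1$alt[af1 == 1]; alt2 <- s2$alt[af2 == 1]
  poly2 <- s2$pos[af2 > 0 & af2 < 1]; poly1 <- s1$pos[af1 > 0 & af1 < 1]
  out <- c(fix1[!(fix1 %in% c(fix2, poly2))],
           fix2[!(fix2 %in% c(fix1, poly1))])
  both <- intersect(fix1, fix2)
  if (length(both)) {
    d <- alt1[match(both, fix1)] != alt2[match(both, fix2)]
    out <- c(out, both[d])
  }
  sort(unique(out))
}

#' @export
print.shared_snp_report <- function(x, ...) {
  cat(sprintf("Shared-SNP scan: %d SNP(s) in %d cluster(s); %d allele-mismatched position(s) excluded\n",
              nrow(x$snps), nrow(x$clusters), x$n_mismatched))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  if (is.data.frame(x$between) && nrow(x$between)) {
    cat("between-cluster phases:\n")
    print(x$between, row.names = FALSE)
  }
  invisible(x)
}
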