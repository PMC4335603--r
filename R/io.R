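# Writers for the standard interchange formats (ms-style haplotype blocks,
# Newick marginal trees, TSV with a '#' header, JSON run metadata) and the
# deterministic fixture generator used by the tests and the examples.

#' Write haplotypes in ms style
#'
#' `//` block, `segsites:`, `positions:` scaled to [0, 1], one 0/1 row per
#' chromosome. Species and class annotations go into `#` comment lines
#' before the block.
#'
#' @param x a `tsp_sim` or `tsp_neutral` object.
#' @param file output path or connection ("" for stdout).
#' @export
write_ms <- function(x, file = "") {
  con <- if (is.character(file) && nzchar(file)) file(file, "w") else
    if (is.character(file)) stdout() else file
  if (is.character(file) && nzchar(file)) on.exit(close(con))
  lines <- character(0)
  if (inherits(x, "tsp_sim")) {
    lines <- c(lines,
               sprintf("# species: %s", paste(x$tips$species, collapse = " ")),
               sprintf("# class:   %s", paste(x$tips$cls, collapse = " ")),
               sprintf("# selected_pos: %g (column %d)", x$selected_pos,
                       x$selected_index),
               "//",
               sprintf("segsites: %d", length(x$positions)),
               paste("positions:",
                     paste(sprintf("%.6f", x$positions / x$L), collapse = " ")),
               apply(x$haplotypes, 1, paste, collapse = ""))
  } else if (inherits(x, "tsp_neutral")) {
    hap <- rbind(x$hap1, x$hap2)
    lines <- c(lines,
               sprintf("# species: %s",
                       paste(rep(1:2, each = x$n), collapse = " ")),
               "//",
               sprintf("segsites: %d", length(x$positions)),
               paste("positions:",
                     paste(sprintf("%.6f", x$positions / x$region_bp),
                           collapse = " ")),
               apply(hap, 1, paste, collapse = ""))
  } else stop("unsupported object")
  writeLines(lines, con)
  invisible(file)
}

#' Write the marginal trees of a simulated sample as Newick
#'
#' One tree per non-recombining segment, preceded by a comment line with the
#' segment interval.
#'
#' @param sim a `tsp_sim`.
#' @param file output path.
#' @export
write_marginal_trees <- function(sim, file) {
  stopifnot(inherits(sim, "tsp_sim"))
  con <- file(file, "w"); on.exit(close(con))
  seg <- sim$segments
  for (i in seq_len(nrow(seg))) {
    phy <- site_tree_phylo(site_tree(sim, (seg$left[i] + seg$right[i]) / 2))
    writeLines(sprintf("# segment [%g, %g)", seg$left[i], seg$right[i]), con)
    writeLines(ape::write.tree(phy), con)
  }
  invisible(file)
}

#' Write a data.frame as TSV with a single '#' header line
#'
#' @param df a data.frame; numeric columns are printed at 6 significant
#'   digits.
#' @param file path or "" for stdout.
#' @export
write_tsv <- function(df, file = "") {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) signif(v, 6))
  hdr <- paste0("#", paste(names(df), collapse = "\t"))
  body <- do.call(paste, c(unname(as.list(df)), sep = "\t"))
  writeLines(c(hdr, body), if (nzchar(file)) file else stdout())
  invisible(file)
}

#' Write JSON run metadata beside an output file
#'
#' @param out_file the artifact the metadata describes.
#' @param params named list of parameters.
#' @param seed the seed used (or NULL).
#' @param command the subcommand name.
#' @export
write_run_meta <- function(out_file, params, seed = NULL, command = "") {
  meta <- list(command = command, parameters = params, seed = seed,
               version = as.character(utils::packageVersion("transpoly")),
               written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(meta, paste0(out_file, ".meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_file)
}

# minimal VCF writer for the fixture generator (phased haploid-coded GT)
.write_vcf <- function(path, contig, pos1, ref, alt, gt, sample_prefix) {
  n <- nrow(gt) / 2
  samples <- sprintf("%s%02d", sample_prefix, seq_len(n))
  gt_str <- vapply(seq_along(pos1), function(j) {
    paste(sprintf("%d|%d", gt[seq(1, 2 * n, 2), j], gt[seq(2, 2 * n, 2), j]),
          collapse = "\t")
  }, "")
  lines <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s>", contig),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"),
             sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                     contig, pos1, ref, alt, gt_str))
  writeLines(lines, path)
  invisible(path)
}

#' Generate deterministic toy fixtures
#'
#' Three kinds: `"toy-vcf-pair"` (paired VCFs with known shared, private and
#' allele-mismatched SNPs plus a reference FASTA with CpG and non-CpG
#' contexts, and a JSON truth table), `"planted-cluster"` (a two-cluster
#' arrangement with same coupling within clusters and opposite coupling
#' between them, emulating a reported two-haplotype-block pattern), and
#' `"simulator-replicates"` (ms-style output and extents from a few
#' structured-coalescent replicates).
#'
#' @param kind fixture kind.
#' @param dir output directory (created if needed).
#' @param seed integer seed; identical seeds give byte-identical files.
#' @return Invisibly, the list of files written plus the truth table.
#' @export
generate_fixtures <- function(kind = c("toy-vcf-pair", "planted-cluster",
                                       "simulator-replicates"),
                              dir = ".", seed = 1) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  files <- character(0)
  truth <- NULL
  if (kind == "toy-vcf-pair") {
    # 10 haplotypes per species; 3 shared SNPs (one CpG), 2 allele-mismatched
    # positions, 1 private SNP each, 1 fixed difference
    pos1 <- c(101, 151, 180, 220, 260, 300, 340)   # 1-based
    ref <- c("C", "C", "G", "T", "A", "C", "G")    # site 101 sits in a CpG
    alt1 <- c("T", "T", "A", "C", "G", "T", "A")
    alt2 <- c("T", "T", "A", "A", "C", "T", "A")   # mismatches at 220, 260
    af1 <- c(.5, .3, .2, .4, .5, .3, 1)            # 340 fixed ALT in sp1
    af2 <- c(.4, .5, .3, .5, .2, 0, 0)             # 300 private to sp1
    g1 <- sapply(af1, function(f) as.integer(seq_len(10) <= round(10 * f)))
    g2 <- sapply(af2, function(f) as.integer(seq_len(10) <= round(10 * f)))
    keep2 <- af2 > 0
    f1 <- file.path(dir, "species1.vcf"); f2 <- file.path(dir, "species2.vcf")
    .write_vcf(f1, "toy", pos1, ref, alt1, g1, "h")
    .write_vcf(f2, "toy", pos1[keep2], ref[keep2], alt2[keep2],
               g2[, keep2, drop = FALSE], "c")
    # reference: background 'T', CpG context at the first shared SNP (0-based
    # 100): bases 100-101 = "CG"; REF must agree at variant positions
    refseq <- rep("T", 400)
    refseq[pos1] <- ref
    refseq[102] <- "G"                              # 0-based 101 => CG at 100
    fa <- file.path(dir, "reference.fa")
    writeLines(c(">toy", paste(refseq, collapse = "")), fa)
    truth <- list(shared_pos0 = c(100, 150, 179),
                  mismatched_pos0 = c(219, 259),
                  cpg_pos0 = 100,
                  fixed_diff_pos0 = 339)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    files <- c(f1, f2, fa, file.path(dir, "truth.json"))
  } else if (kind == "planted-cluster") {
    # two clusters of shared SNPs 600 bp apart: same coupling within each
    # cluster in both species, opposite coupling between clusters
    pos1 <- c(101, 161, 221, 821, 881)
    ref <- c("A", "A", "A", "A", "A")
    alt <- c("G", "G", "G", "G", "G")
    hapA <- c(rep(1L, 5), rep(0L, 5))               # cluster-1 haplotype
    g1 <- cbind(hapA, hapA, hapA, hapA, hapA)       # same coupling in sp1
    g2 <- cbind(hapA, hapA, hapA, 1L - hapA, 1L - hapA)  # flipped cluster 2
    f1 <- file.path(dir, "cluster_sp1.vcf"); f2 <- file.path(dir, "cluster_sp2.vcf")
    .write_vcf(f1, "toy", pos1, ref, alt, g1, "h")
    .write_vcf(f2, "toy", pos1, ref, alt, g2, "c")
    truth <- list(clusters = 2, span1 = 120, span2 = 60,
                  between_phase = "opposite")
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    files <- c(f1, f2, file.path(dir, "truth.json"))
  } else {
    pp <- model_params(Ne = 2000, Na = 5000, T = 20000, Ts = 50000,
                       L = 2001, r = 1e-7, mu = 1e-7)
    ext <- matrix(0, 3, 2)
    fms <- file.path(dir, "replicates.ms")
    con <- file(fms, "w")
    for (i in 1:3) {
      sim <- simulate_sample(pp, seed = seed * 1000 + i)
      writeLines(utils::capture.output(write_ms(sim)), con)
      ext[i, ] <- ancestral_segment_extent(sim)
    }
    close(con)
    fext <- file.path(dir, "extents.tsv")
    write_tsv(data.frame(replicate = 1:3, left = ext[, 1], right = ext[, 2]),
              fext)
    files <- c(fms, fext)
  }
  invisible(list(files = files, truth = truth))
}
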