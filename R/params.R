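#' Model parameter bundle
#'
#' Collects the demographic, selection, locus and sampling parameters used
#' throughout the package. Time is always in generations and effective sizes
#' are numbers of diploids, so that two lineages in a population of size N
#' coalesce at rate 1/(2N) per generation. `p` is the equilibrium frequency of
#' the derived allele A1 (the allele that arose when the balanced polymorphism
#' was established); `q = 1 - p` is stored for convenience.
#'
#' @param Ne effective size of each descendant species (diploids).
#' @param Na effective size of the ancestral species (diploids).
#' @param T split time between the two species, in generations.
#' @param p equilibrium frequency of the derived allele A1, in (0, 1).
#' @param Ts age of the balanced polymorphism in generations, measured
#'   backwards from the end of stage II (the coalescence of the four
#'   class lineages into the two class ancestors).
#' @param s harmonic mean of the homozygote selection coefficients, used only
#'   by the fluctuating-frequency overdominance mode.
#' @param r recombination rate per base pair per generation.
#' @param mu mutation rate per base pair per generation.
#' @param L window length in base pairs.
#' @param selected_pos position of the selected site within the window
#'   (0-based); defaults to the window midpoint.
#' @param n chromosomes sampled per species.
#' @param gen_time generation time in years, used only to convert ages given
#'   in years (default 20, a common value for apes).
#' @return An object of class `tsp_params` (a validated list).
#' @examples
#' pp <- model_params()           # human-chimpanzee defaults
#' pp$Na
#' @export
model_params <- function(Ne = 1e4, Na = 5e4, T = 2.5e5, p = 0.5,
                         Ts = 6e5, s = 0, r = 1.2e-8, mu = 1.2e-8,
                         L = 10001, selected_pos = NULL, n = 4,
                         gen_time = 20) {
  stopifnot(is.numeric(Ne), Ne > 0, is.numeric(Na), Na > 0,
            is.numeric(T), T > 0, is.numeric(p), p > 0, p < 1,
            is.numeric(Ts), Ts >= 0, is.numeric(s), s >= 0,
            is.numeric(r), r >= 0, is.numeric(mu), mu >= 0,
            is.numeric(L), L >= 1, is.numeric(n), n >= 1,
            is.numeric(gen_time), gen_time > 0)
  if (is.null(selected_pos)) selected_pos <- floor(L / 2)
  if (selected_pos < 0 || selected_pos >= L)
    stop("`selected_pos` must lie inside the window [0, L)")
  structure(list(Ne = Ne, Na = Na, T = T, p = p, q = 1 - p, Ts = Ts, s = s,
                 r = r, mu = mu, L = L, selected_pos = selected_pos, n = n,
                 gen_time = gen_time),
            class = "tsp_params")
}

#' @export
print.tsp_params <- function(x, ...) {
  cat("Trans-species polymorphism model parameters\n")
  cat(sprintf("  demography: Ne = %g, Na = %g, T = %g generations\n",
              x$Ne, x$Na, x$T))
  cat(sprintf("  selection:  p = %g, Ts = %g generations, s = %g\n",
              x$p, x$Ts, x$s))
  cat(sprintf("  locus:      r = %g, mu = %g per bp per generation, L = %g bp\n",
              x$r, x$mu, x$L))
  cat(sprintf("  sampling:   n = %g chromosomes per species\n", x$n))
  invisible(x)
}

#' Read model parameters from a flat key=value config file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment.
#' Recognised keys are the arguments of [model_params()] plus `seed`. Unknown
#' keys are an error, so typos do not silently fall back to defaults.
#'
#' @param path path to the config file.
#' @return A list with elements `params` (a `tsp_params`) and `seed`
#'   (integer or NULL).
#' @export
read_config <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  kv <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*[=:]\\s*(\\S+)$", ln))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) stop("malformed config line(s): ", paste(ln[bad], collapse = "; "))
  keys <- vapply(kv, `[`, "", 2L)
  vals <- as.numeric(vapply(kv, `[`, "", 3L))
  known <- c(names(formals(model_params)), "seed")
  unk <- setdiff(keys, known)
  if (length(unk)) stop("unknown config key(s): ", paste(unk, collapse = ", "))
  if (anyDuplicated(keys)) stop("duplicated config key(s)")
  args <- as.list(vals[keys != "seed"])
  names(args) <- keys[keys != "seed"]
  seed <- if ("seed" %in% keys) as.integer(vals[keys == "seed"]) else NULL
  list(params = do.call(model_params, args), seed = seed)
}

#' Probability of capturing both selected alleles in both species
#'
#' With `n` chromosomes sampled at random from each species and the selected
#' alleles at frequencies p and q = 1 - p in each, the probability that both
#' alleles are present at the selected site in both samples is
#' (1 - p^n - q^n)^2.
#'
#' @param p allele frequency in (0, 1).
#' @param n chromosomes sampled per species (>= 1).
#' @return The capture probability.
#' @examples
#' capture_probability(0.5, 2)   # 0.25
#' @export
capture_probability <- function(p, n) {
  stopifnot(is.numeric(p), all(p > 0), all(p < 1), is.numeric(n), all(n >= 1))
  (1 - p^n - (1 - p)^n)^2
}

#' Probability that a neutral polymorphism is trans-specific
#'
#' The leading term is the probability that, in each species independently,
#' two lineages fail to coalesce in the T generations since the split:
#' (e^(-T/(2Ne)))^2. With T much larger than Ne this is negligible, which is
#' what makes a trans-species polymorphism diagnostic of balancing selection.
#'
#' @param T split time in generations (>= 0).
#' @param Ne diploid effective size of each descendant species.
#' @return The approximate probability of neutral incomplete lineage sorting
#'   producing a shared polymorphism.
#' @export
neutral_ils_probability <- function(T, Ne) {
  stopifnot(is.numeric(T), all(T >= 0), is.numeric(Ne), all(Ne > 0))
  exp(-T / (2 * Ne))^2
}

#' Fold increase in ILS probability due to archaic introgression
#'
#' Gene flow from an archaic lineage that split T_archaic generations ago
#' shortens, for the introgressed regions, the time over which one species'
#' lineages must avoid coalescing, inflating the neutral trans-species
#' polymorphism probability by e^(T_archaic/(2Ne)).
#'
#' @param T_archaic split time of the archaic donor from the focal species,
#'   in generations.
#' @param Ne diploid effective size.
#' @return The fold change (>= 1).
#' @examples
#' introgression_fold_change(440000 / 20, 1e4)  # about 3
#' @export
introgression_fold_change <- function(T_archaic, Ne) {
  stopifnot(is.numeric(T_archaic), all(T_archaic >= 0),
            is.numeric(Ne), all(Ne > 0))
  exp(T_archaic / (2 * Ne))
}
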