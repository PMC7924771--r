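#' Observations: variant sites along the genome
#'
#' A set of variant sites with their allelic patterns over the n sampled
#' haplotypes, modelling the data as events of a Cox process driven by the
#' local genealogy (mutations arise at rate \eqn{\mu B(x_s)} per nucleotide).
#' Only variant sites are events; monomorphic positions enter through the
#' no-mutation survival factor.
#'
#' @param loci strictly increasing variant positions, continuous 0-based
#'   coordinates in \code{[0, L)}.
#' @param patterns for phased data, an n x m integer matrix of 0/1/NA (NA =
#'   missing haplotype call); columns align with \code{loci}.
#' @param genotypes for unphased data, an (n/2) x m matrix of alt-allele
#'   dosages 0/1/2/NA per diploid individual.
#' @param L total sequence length in bp.
#' @param n number of haplotypes (required when \code{patterns} is NULL).
#' @return an object of class \code{coalpf_obs}.
#' @export
observation <- function(loci, patterns = NULL, genotypes = NULL, L, n = NULL) {
  loci <- as.numeric(loci)
  if (is.unsorted(loci, strictly = TRUE)) stop("loci must be strictly increasing")
  if (length(loci) && (loci[1] < 0 || loci[length(loci)] >= L))
    stop("loci must lie in [0, L)")
  phased <- !is.null(patterns)
  if (phased) {
    patterns <- as.matrix(patterns)
    if (ncol(patterns) != length(loci)) stop("one pattern column per locus required")
    n <- nrow(patterns)
    bad <- vapply(seq_len(ncol(patterns)), function(j) {
      a <- patterns[, j]
      sum(a == 1, na.rm = TRUE) == 0
    }, logical(1))
    if (any(bad)) stop("every pattern must have at least one carrier")
  } else {
    if (is.null(genotypes)) {
      if (is.null(n)) stop("n required when no patterns are given")
    } else {
      genotypes <- as.matrix(genotypes)
      if (ncol(genotypes) != length(loci)) stop("one genotype column per locus required")
      n <- 2L * nrow(genotypes)
    }
  }
  structure(list(loci = loci, patterns = patterns, genotypes = genotypes,
                 phased = phased, L = as.numeric(L), n = as.integer(n)),
            class = "coalpf_obs")
}

#' @export
print.coalpf_obs <- function(x, ...) {
  cat("Observation:", length(x$loci), if (x$phased) "phased" else "unphased",
      "variant sites over", x$n, "haplotypes, L =", format(x$L), "bp\n")
  invisible(x)
}

#' Observed-region mask
#'
#' Disjoint half-open genomic intervals where data exist; positions outside
#' the mask carry no information and are simply left out of the emission
#' integral.  An absent mask means the full sequence is observed.
#'
#' @param start,end interval bounds (0-based, half-open), sorted and
#'   non-overlapping.
#' @param L sequence length.
#' @return an object of class \code{coalpf_mask}.
#' @export
observed_mask <- function(start, end, L) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != length(end)) stop("start/end length mismatch")
  if (any(end <= start)) stop("intervals must be non-empty")
  o <- order(start)
  start <- start[o]; end <- end[o]
  if (any(start[-1] < end[-length(end)])) stop("intervals must be disjoint")
  if (length(start) && (start[1] < 0 || end[length(end)] > L))
    stop("intervals must lie within [0, L)")
  structure(list(start = start, end = end, L = as.numeric(L)),
            class = "coalpf_mask")
}

# observed length of [a, b) under a mask (NULL = fully observed)
mask_obslen <- function(mask, a, b) {
  if (is.null(mask)) return(b - a)
  sum(pmax(0, pmin(mask$end, b) - pmax(mask$start, a)))
}

# subset an observation to a window; closed_right switches (a,b] vs [a,b)
obs_window <- function(obs, a, b, closed_right = FALSE) {
  if (is.null(obs)) return(NULL)
  keep <- if (closed_right) obs$loci > a - 1e-12 & obs$loci <= b
          else obs$loci >= a & obs$loci < b
  out <- obs
  out$loci <- obs$loci[keep]
  if (!is.null(obs$patterns)) out$patterns <- obs$patterns[, keep, drop = FALSE]
  if (!is.null(obs$genotypes)) out$genotypes <- obs$genotypes[, keep, drop = FALSE]
  out
}

#' Allelic pattern likelihood on a genealogy
#'
#' Under the one-mutation-per-variant-site (infinite sites) model the
#' probability density of observing pattern A at a site is \eqn{\mu} times
#' the total length of branches whose set of (non-missing) descendant tips
#' equals A's carrier set; missing tips are marginalized.  Summed over all
#' non-wildtype fully-observed patterns this gives exactly \eqn{\mu B(g)}.
#'
#' @param g a \code{\link{genealogy}}.
#' @param A integer vector of length n with entries 0/1/NA; at least one
#'   non-missing carrier.
#' @param mu mutation rate per nucleotide per generation.
#' @return probability density per nucleotide.
#' @export
pattern_likelihood <- function(g, A, mu) {
  if (length(A) != g$n) stop("pattern length must equal the number of tips")
  if (all(is.na(A))) stop("pattern is entirely missing")
  if (sum(A == 1, na.rm = TRUE) < 1) stop("pattern needs at least one carrier")
  carriers <- sum(2^(which(A == 1) - 1))
  missing <- if (anyNA(A)) sum(2^(which(is.na(A)) - 1)) else 0
  mu * cpp_match_len(as_cpp_tree(g), carriers, missing)
}

#' Unphased genotype-pattern likelihood
#'
#' Sums the phased pattern likelihood over all haplotype-phase assignments
#' consistent with the observed diploid genotypes; equivalently, a single
#' pass over branches matching each branch's implied dosage vector.
#' Individuals map to consecutive haplotype pairs (1,2), (3,4), ...
#'
#' @param g a \code{\link{genealogy}} (even number of tips).
#' @param geno integer vector of alt-allele dosages 0/1/2/NA, one per
#'   individual.
#' @param mu mutation rate per nucleotide per generation.
#' @return probability density per nucleotide.
#' @export
unphased_pattern_likelihood <- function(g, geno, mu) {
  if (g$n %% 2 != 0) stop("unphased input requires an even number of haplotypes")
  if (length(geno) != g$n / 2) stop("one genotype per diploid individual required")
  gi <- as.integer(geno)
  gi[is.na(gi)] <- -1L
  mu * cpp_match_len_unphased(as_cpp_tree(g), gi)
}

#' Emission log-density of a constant-tree segment
#'
#' For a genomic interval over which the genealogy is constant, returns
#' \eqn{-\mu B_{\mathrm{eff}} + \sum_j \log P(A_j | g, \mu)} where
#' \eqn{B_{\mathrm{eff}}} integrates branch length over masked-in sequence
#' only.  The combinatorial constant of the Cox-process density is identical
#' across particles and omitted.
#'
#' @param g a \code{\link{genealogy}}.
#' @param interval numeric length-2 half-open genomic interval.
#' @param events an \code{\link{observation}} restricted to the interval (or
#'   NULL for none).
#' @param mu mutation rate per nucleotide per generation.
#' @param mask optional \code{\link{observed_mask}}.
#' @return log-density.
#' @export
segment_log_density <- function(g, interval, events = NULL, mu, mask = NULL) {
  lw <- -mu * total_branch_length(g) * mask_obslen(mask, interval[1], interval[2])
  if (!is.null(events) && length(events$loci)) {
    if (any(events$loci < interval[1] | events$loci >= interval[2]))
      stop("event outside the segment")
    if (!is.null(mask) &&
        any(vapply(events$loci, function(s) mask_obslen(mask, s, s + 1e-9) <= 0, logical(1))))
      stop("event outside the observed mask")
    lw <- lw + segment_site_loglik(g, events, mu)
  }
  lw
}

# sum of per-site log-likelihoods of an observation subset
segment_site_loglik <- function(g, events, mu) {
  s <- 0
  for (j in seq_along(events$loci)) {
    p <- if (events$phased) pattern_likelihood(g, events$patterns[, j], mu)
         else unphased_pattern_likelihood(g, events$genotypes[, j], mu)
    s <- s + if (p > 0) log(p) else -Inf
  }
  s
}
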