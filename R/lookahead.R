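#' Build the lookahead data digest
#'
#' Scanning forward from the current locus, the digest keeps (i) for each
#' haploid sequence (or diploid individual, for unphased data) the distance
#' to its nearest future singleton, censored at the end of the data when none
#' remains; and (ii) at most n/2 mutually consistent cherries, fixed greedily
#' in locus order from future doubletons: a doubleton incompatible with an
#' already-fixed cherry (sharing exactly one leaf) is discarded.  For
#' unphased data, singletons are lone heterozygous individuals and cherries
#' come from lone homozygous-alternative individuals or are greedily assigned
#' to haplotype pairs for two-heterozygote doubletons.
#'
#' @param obs an \code{\link{observation}}.
#' @param s current locus; only variants strictly beyond \code{s} enter.
#' @return list with \code{s_dist} (per-unit next-singleton distance),
#'   \code{censored} (logical), \code{cherries} (list of \code{a}, \code{b}
#'   haplotype labels with \code{support} locus vector), \code{unit}
#'   ("haplotype" or "individual") and the scan origin \code{s}.
#' @export
build_digest <- function(obs, s = 0) {
  if (s >= obs$L) stop("current locus beyond the sequence end")
  keep <- obs$loci > s
  loci <- obs$loci[keep]
  n <- obs$n
  cherries <- list()
  used <- rep(FALSE, n)
  maxch <- floor(n / 2)
  if (obs$phased) {
    pat <- obs$patterns[, keep, drop = FALSE]
    units <- n
    sing_loc <- rep(NA_real_, n)
    for (j in seq_along(loci)) {
      carriers <- which(pat[, j] == 1)
      if (length(carriers) == 1) {
        i <- carriers
        if (is.na(sing_loc[i])) sing_loc[i] <- loci[j]
      } else if (length(carriers) == 2) {
        a <- carriers[1]; b <- carriers[2]
        hit <- FALSE
        for (k in seq_along(cherries)) {
          if (cherries[[k]]$a == a && cherries[[k]]$b == b) {
            cherries[[k]]$support <- c(cherries[[k]]$support, loci[j])
            hit <- TRUE; break
          }
        }
        if (!hit && !used[a] && !used[b] && length(cherries) < maxch) {
          cherries[[length(cherries) + 1]] <- list(a = a, b = b, support = loci[j])
          used[a] <- used[b] <- TRUE
        }
      }
    }
  } else {
    gen <- obs$genotypes[, keep, drop = FALSE]
    units <- n / 2
    sing_loc <- rep(NA_real_, units)
    for (j in seq_along(loci)) {
      gj <- gen[, j]
      het <- which(gj == 1); hom <- which(gj == 2)
      if (length(het) == 1 && length(hom) == 0) {
        if (is.na(sing_loc[het])) sing_loc[het] <- loci[j]
      } else if (length(hom) == 1 && length(het) == 0) {
        a <- 2 * hom - 1; b <- 2 * hom
        hit <- FALSE
        for (k in seq_along(cherries))
          if (cherries[[k]]$a == a && cherries[[k]]$b == b) {
            cherries[[k]]$support <- c(cherries[[k]]$support, loci[j])
            hit <- TRUE; break
          }
        if (!hit && !used[a] && !used[b] && length(cherries) < maxch) {
          cherries[[length(cherries) + 1]] <- list(a = a, b = b, support = loci[j])
          used[a] <- used[b] <- TRUE
        }
      } else if (length(het) == 2 && length(hom) == 0) {
        hit <- FALSE
        for (k in seq_along(cherries)) {
          ck <- cherries[[k]]
          ia <- ceiling(ck$a / 2); ib <- ceiling(ck$b / 2)
          if ((ia == het[1] && ib == het[2]) || (ia == het[2] && ib == het[1])) {
            cherries[[k]]$support <- c(cherries[[k]]$support, loci[j])
            hit <- TRUE; break
          }
        }
        if (!hit) {
          ha <- 2 * het[1] - 1:0; hb <- 2 * het[2] - 1:0
          a <- ha[!used[ha]][1]; b <- hb[!used[hb]][1]
          if (!is.na(a) && !is.na(b) && length(cherries) < maxch) {
            cherries[[length(cherries) + 1]] <- list(a = a, b = b, support = loci[j])
            used[a] <- used[b] <- TRUE
          }
        }
      }
    }
  }
  list(s = s,
       s_dist = ifelse(is.na(sing_loc), obs$L - s, sing_loc - s),
       censored = is.na(sing_loc),
       cherries = cherries,
       unit = if (obs$phased) "haplotype" else "individual")
}

#' Singleton lookahead likelihood
#'
#' Approximate likelihood that the first future singleton on a lineage with
#' terminal branch length \code{l} is observed at distance \code{s} (or, if
#' \code{censored}, that none is observed up to \code{s}).  The terminal
#' branch changes (by a recombination on it that coalesces away, or one
#' elsewhere that coalesces into it) at total rate
#' \eqn{\rho_i = 2 l \rho' (n-1)/n} per bp, after which its length is
#' hypothesised to jump to \eqn{l'}, marginalised over the supplied empirical
#' distribution.  With \code{mixture = TRUE} the likelihood is averaged over
#' \eqn{\rho' \in \{\rho, \rho/2\}} with equal weight, modelling correlated
#' successive changes.  The removable singularity at
#' \eqn{\rho_i + \mu_i = \mu_i'} is handled by its limit.
#'
#' @param l terminal branch length in generations (positive).
#' @param s distance to the singleton (bp, non-negative).
#' @param censored no singleton seen before data ran out at distance s.
#' @param rho,mu per-bp per-generation rates.
#' @param n number of haplotypes.
#' @param lprime numeric vector: empirical distribution (atoms, equal weight)
#'   of the post-change terminal branch length; default \code{l} (no change).
#' @param mixture average over the rho' mixture.
#' @return likelihood value (a density per bp when uncensored).
#' @export
singleton_lookahead <- function(l, s, censored = FALSE, rho, mu, n,
                                lprime = l, mixture = TRUE) {
  if (l <= 0 || s < 0 || rho < 0 || mu < 0) stop("negative or degenerate inputs")
  mixes <- if (mixture) c(rho, rho / 2) else rho
  mu_i <- mu * l
  val <- 0
  for (rhoP in mixes) {
    rho_i <- 2 * l * rhoP * (n - 1) / n
    terms <- vapply(lprime, function(lp)
      cpp_singleton_term(rho_i, mu_i, mu * lp, s, censored), numeric(1))
    val <- val + mean(terms)
  }
  val / length(mixes)
}

#' Cherry lookahead likelihood terms
#'
#' Likelihood of the doubleton evidence for a cherry (a, b), conditional on
#' the current genealogy containing it (\code{cherry_present_lookahead},
#' with \code{s2} the distance to the last supporting doubleton) or not
#' (\code{cherry_absent_lookahead}, with \code{s1} the distance to the first
#' supporting doubleton).  A cherry is destroyed at rate
#' \eqn{\rho_C = 4 l \rho (n-2)/n} and created at rate
#' \eqn{\rho'_C = (n-1) \bar{l} \rho}; after a change the tree is assumed to
#' be at equilibrium, where a specific pair forms a cherry with probability
#' \eqn{2/(3(n-1))}.
#'
#' @param s1,s2 distances in bp (non-negative).
#' @param rho_C,rho_Cp total change/creation rates per bp.
#' @param n number of haplotypes, at least 3.
#' @return likelihood value in (0, 1].
#' @export
cherry_present_lookahead <- function(s2, rho_C, n) {
  if (n < 3) stop("cherry terms require n >= 3")
  if (s2 < 0 || rho_C < 0) stop("negative inputs")
  q <- 2 / (3 * (n - 1))
  e <- exp(-rho_C * s2)
  e + q * (1 - e)
}

#' @rdname cherry_present_lookahead
#' @export
cherry_absent_lookahead <- function(s1, rho_Cp, n) {
  if (n < 3) stop("cherry terms require n >= 3")
  if (s1 < 0 || rho_Cp < 0) stop("negative inputs")
  q <- 2 / (3 * (n - 1))
  q * (1 - exp(-rho_Cp * s1))
}

#' Lookahead likelihood of a genealogy
#'
#' The product over lineages of the singleton terms (terminal branch lengths
#' read from the genealogy) and over digest cherries of the present/absent
#' cherry terms, according to whether the genealogy contains each cherry as a
#' sibling tip pair.  The \eqn{\rho'} mixture is applied as a two-component
#' average of the full product.  For unphased data the singleton term of an
#' individual uses the sum of its two terminal branch lengths.  Strictly
#' positive for every genealogy with positive branch lengths, as importance
#' sampling requires.
#'
#' @param g a \code{\link{genealogy}}.
#' @param digest a \code{\link{build_digest}} result.
#' @param model a \code{\link{demographic_model}} (supplies rho and mu).
#' @param lprime optional list of per-unit atom vectors for the post-change
#'   terminal branch length; default: each unit's own current length.
#' @param mu_eff optional per-unit effective mutation rates (mask-reduced);
#'   default \code{model$mu}.
#' @return the lookahead likelihood h (positive scalar).
#' @export
lookahead_likelihood <- function(g, digest, model, lprime = NULL, mu_eff = NULL) {
  n <- g$n
  units <- length(digest$s_dist)
  tbl <- function(i) {
    if (digest$unit == "haplotype") g$time[g$parent[i]]
    else g$time[g$parent[2 * i - 1]] + g$time[g$parent[2 * i]]
  }
  if (is.null(mu_eff)) mu_eff <- rep(model$mu, units)
  lbar <- mean(g$time[g$parent[seq_len(n)]])
  h <- 0
  for (rhoP in c(model$rho, model$rho / 2)) {
    val <- 1
    for (i in seq_len(units)) {
      l <- tbl(i)
      lp <- if (is.null(lprime)) l else lprime[[i]]
      rho_i <- 2 * l * rhoP * (n - 1) / n
      mu_i <- mu_eff[i] * l
      terms <- vapply(lp, function(x)
        cpp_singleton_term(rho_i, mu_i, mu_eff[i] * x, digest$s_dist[i],
                           digest$censored[i]), numeric(1))
      val <- val * mean(terms)
    }
    if (n >= 3) {
      for (ck in digest$cherries) {
        fut <- ck$support[ck$support > digest$s]
        if (!length(fut)) next
        s1 <- fut[1] - digest$s
        s2 <- max(fut) - digest$s
        if (is_cherry(g, ck$a, ck$b)) {
          l <- g$time[g$parent[ck$a]]
          val <- val * cherry_present_lookahead(s2, 4 * l * rhoP * (n - 2) / n, n)
        } else {
          val <- val * cherry_absent_lookahead(s1, (n - 1) * lbar * rhoP, n)
        }
      }
    }
    h <- h + 0.5 * val
  }
  h
}
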