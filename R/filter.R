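#' Run the waypointed particle filter
#'
#' Sequential Monte Carlo over the genealogy jump process: N particles are
#' initialised from the stationary coalescent, propagated under the prior
#' between consecutive waypoints (the proposal equals the prior, so weight
#' updates contain only emission terms), and systematically resampled
#' whenever the effective sample size drops below \code{ess_threshold * N}.
#' When resampling, weights are reset to the pre-resampling mean so that the
#' final weight sum estimates the marginal likelihood density of the data
#' (with respect to \eqn{(ds)^{|y|}}).
#'
#' With \code{lookahead = TRUE} the filter keeps a second set of weights v
#' that additionally track an approximate likelihood h of a digest of future
#' data (next-singleton distances and cherry support intervals) given each
#' particle's current genealogy.  Resampling is then triggered by, and
#' performed proportionally to, v; the target weights w are corrected by
#' \eqn{w \leftarrow N^{-1} w / v} so posterior expectations and the
#' likelihood estimate remain those of the plain filter.
#'
#' @param obs an \code{\link{observation}}.
#' @param model a \code{\link{demographic_model}}.
#' @param n_particles number of particles (>= 2).
#' @param mask optional \code{\link{observed_mask}}.
#' @param lookahead use the auxiliary lookahead resampling distribution.
#' @param waypoints explicit waypoint plan; default
#'   \code{\link{build_waypoints}} with \code{theta}.
#' @param theta heterozygosity for the waypoint spacing rule; default
#'   \code{4 * ne[1] * mu} from the model.
#' @param spacing optional spacing override.
#' @param ess_threshold resample when ESS falls below this fraction of N.
#' @param lags per-epoch fixed-lag harvest distances in bp (default
#'   \code{Inf}: harvest everything at the end of the sequence with final
#'   weights).
#' @param eta optional per-event weight factors for a Variational Bayes pass:
#'   list with \code{rho} (scalar) and \code{coal} (per epoch).
#' @param atoms number of quantile atoms used to marginalise the hypothesised
#'   post-change terminal branch length in the lookahead likelihood.
#' @param atom_refresh refresh the atom set every this many waypoints (atoms
#'   are also refreshed at every resampling event).
#' @param harvest_stride harvest matured event records every this many
#'   waypoints.
#' @param track_life record tree-node lifetimes per epoch (used to estimate
#'   correlation distances between inference iterations).
#' @param track_loci loci at which to record posterior means of total branch
#'   length and TMRCA.
#' @param return_final_trees also return the final ensemble's genealogies.
#' @return an object of class \code{coalpf_filter}: the log marginal
#'   likelihood estimate, per-waypoint ESS traces (for w and, with lookahead,
#'   v), resampling indicators, harvested per-epoch sufficient statistics
#'   (expected counts and opportunities), node-lifetime summaries, and final
#'   ensemble summaries.
#' @export
run_filter <- function(obs, model, n_particles = 1000, mask = NULL,
                       lookahead = FALSE, waypoints = NULL, theta = NULL,
                       spacing = NULL, ess_threshold = 0.5, lags = NULL,
                       eta = NULL, atoms = 32, atom_refresh = 32,
                       harvest_stride = 32, track_life = FALSE,
                       track_loci = numeric(0), return_final_trees = FALSE) {
  if (n_particles < 2) stop("need at least two particles")
  if (any(model$growth != 0)) stop("filtering requires piecewise-constant Ne (zero growth)")
  E <- length(model$ne)
  if (is.null(theta)) theta <- watterson_theta(obs, mask, model)
  if (is.null(waypoints)) waypoints <- build_waypoints(obs, theta, obs$L, spacing)
  if (is.null(lags)) lags <- rep(Inf, E)
  if (length(lags) != E) stop("one lag per epoch required")
  vb_mode <- !is.null(eta)
  if (!vb_mode) eta <- list(rho = 1, coal = rep(1, E))

  eng_obs <- engine_obs(obs, mask)
  cfg <- list(N = as.integer(n_particles), lookahead = lookahead,
              unphased = !obs$phased, ess_frac = ess_threshold,
              atoms = as.integer(atoms), atom_refresh = as.integer(atom_refresh),
              harvest_stride = as.integer(harvest_stride), vb_mode = vb_mode,
              eta_rho = eta$rho, eta_coal = eta$coal, lags = as.numeric(lags),
              waypoints = as.numeric(waypoints), track_life = track_life,
              return_final_trees = return_final_trees,
              track_loci = as.numeric(track_loci))
  res <- cpp_run_filter(eng_obs, as_engine_model(model), cfg)

  stats <- data.frame(epoch = seq_len(E), start = model$epoch_start,
                      end = c(model$epoch_start[-1], Inf),
                      recomb_count = res$stats$recomb_count,
                      recomb_opp = res$stats$recomb_opp,
                      coal_count = res$stats$coal_count,
                      coal_opp = res$stats$coal_opp)
  out <- list(loglik = res$loglik, waypoints = waypoints,
              ess_w = res$ess_w, ess_v = res$ess_v,
              resampled = as.logical(res$resampled),
              cum_loglik = res$cum_loglik, stats = stats,
              node_life = data.frame(epoch = seq_len(E),
                                     life_sum = res$node_life$sum,
                                     life_count = res$node_life$count),
              final_B = res$final_B, final_tmrca = res$final_tmrca,
              final_w = res$final_w,
              final_trees = if (return_final_trees)
                lapply(res$final_trees, from_cpp_tree) else NULL,
              dead_sites = res$dead_sites,
              peak_records = res$peak_records,
              n_particles = n_particles, lookahead = lookahead)
  class(out) <- "coalpf_filter"
  out
}

#' @rdname run_filter
#' @param ... passed on to \code{run_filter}.
#' @export
run_lookahead_filter <- function(obs, model, ...) {
  run_filter(obs, model, lookahead = TRUE, ...)
}

#' @export
print.coalpf_filter <- function(x, ...) {
  cat("Particle filter run:", x$n_particles, "particles,",
      length(x$waypoints), "waypoints",
      if (x$lookahead) "(lookahead)" else "", "\n")
  cat("  log marginal likelihood:", format(x$loglik), "\n")
  cat("  resampling events:", sum(x$resampled),
      " median ESS:", format(stats::median(x$ess_w)), "\n")
  invisible(x)
}

# flatten an observation + mask into the engine's input layout
engine_obs <- function(obs, mask = NULL) {
  n <- obs$n
  if (obs$phased) {
    m <- length(obs$loci)
    carriers <- missing <- numeric(m)
    if (m) {
      pw <- 2^(seq_len(n) - 1)
      for (j in seq_len(m)) {
        a <- obs$patterns[, j]
        carriers[j] <- sum(pw[which(a == 1)])
        missing[j] <- sum(pw[which(is.na(a))])
      }
    }
    geno <- matrix(0L, 0, 0)
  } else {
    carriers <- missing <- numeric(0)
    geno <- obs$genotypes
    if (is.null(geno)) geno <- matrix(0L, n / 2, 0)
    geno[is.na(geno)] <- -1L
    storage.mode(geno) <- "integer"
  }
  list(n = as.integer(n), L = obs$L, loci = obs$loci,
       carriers = carriers, missing = missing, genotypes = geno,
       mask_start = if (is.null(mask)) numeric(0) else mask$start,
       mask_end = if (is.null(mask)) numeric(0) else mask$end)
}

# Watterson-type heterozygosity estimate from the data, used for the
# waypoint spacing rule; falls back to the model's recent Ne when there are
# no variants
watterson_theta <- function(obs, mask = NULL, model = NULL) {
  Lobs <- if (is.null(mask)) obs$L else sum(mask$end - mask$start)
  S <- length(obs$loci)
  if (S >= 10 && Lobs > 0) S / (Lobs * sum(1 / seq_len(max(obs$n - 1, 1))))
  else 4 * model$ne[1] * model$mu
}

# per-gap ESS retention ratios over event-free waypoint gaps (diagnostic)
ess_retention <- function(filter) {
  ew <- if (filter$lookahead) filter$ess_v else filter$ess_w
  K <- length(filter$waypoints)
  N <- filter$n_particles
  post <- ifelse(filter$resampled[-K], N, ew[-K])
  ew[-1] / post
}
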