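#' Sample the next recombination locus and point
#'
#' The jump process exits the current genealogy at rate \eqn{\rho B(g)} per
#' nucleotide, so the distance to the next recombination is exponential with
#' that rate, and the recombination point falls uniformly on the tree with
#' respect to branch-length measure (a branch is chosen proportionally to its
#' length and the height uniformly within it).  The infinite branch above the
#' root attracts no recombination.
#'
#' @param g current \code{\link{genealogy}}.
#' @param s current locus (continuous, 0-based).
#' @param model a \code{\link{demographic_model}}.
#' @param L sequence length; a jump beyond \code{L} returns \code{locus = Inf}.
#' @return list with \code{locus} (next event position, or \code{Inf}),
#'   \code{branch} (node index under the cut) and \code{nu} (cut height in
#'   generations); the latter two are \code{NA} for an overshooting jump.
#' @export
sample_jump <- function(g, s, model, L = Inf) {
  B <- total_branch_length(g)
  if (B <= 0) stop("genealogy has non-positive branch length")
  if (s >= L) stop("locus beyond sequence end")
  rate <- model$rho * B
  d <- if (rate > 0) stats::rexp(1, rate) else Inf
  if (s + d >= L) return(list(locus = Inf, branch = NA_integer_, nu = NA_real_))
  len <- branch_lengths(g)
  u <- stats::runif(1) * B
  cum <- cumsum(len)
  branch <- which(u <= cum)[1]
  nu <- g$time[branch] + (u - c(0, cum)[branch])
  list(locus = s + d, branch = branch, nu = nu)
}

#' Apply a recombination and re-coalescence to a genealogy
#'
#' Detaches the lineage above the cut point \code{(branch, nu)} and lets it
#' re-coalesce at time \eqn{\tau > \nu} with the contemporary branches of the
#' current tree at instantaneous rate \eqn{b_u C(u)} (the origin branch's
#' remnant counts, and \eqn{b_u = 1} above the root).  Re-coalescing into the
#' origin branch leaves the tree unchanged (a "silent" recombination), but
#' the event is still recorded and counted: the path measure is over all
#' sampled recombinations.
#'
#' @param g current \code{\link{genealogy}}.
#' @param branch node index whose parent branch carries the cut.
#' @param nu cut height; must lie within the branch's span.
#' @param model a \code{\link{demographic_model}}.
#' @return list with the updated \code{genealogy} and the event
#'   \code{record} (locus unset; fields \code{branch}, \code{nu}, \code{tau},
#'   \code{target}, \code{changed_tree}, epoch indices, and the per-epoch
#'   coalescence opportunity \eqn{\int_\nu^\tau b_u \, du}).
#' @export
apply_recombination <- function(g, branch, nu, model) {
  pt <- g$parent[branch]
  if (is.na(pt)) stop("cannot recombine on the root branch")
  if (nu < g$time[branch] || nu >= g$time[pt]) stop("nu outside the branch's span")
  res <- cpp_apply_recomb(as_cpp_tree(g), branch - 1L, nu, as_engine_model(model))
  rec <- list(locus = NA_real_, branch = res$branch, nu = res$nu, tau = res$tau,
              target = res$target, changed_tree = res$changed_tree,
              epoch_nu = res$epoch_nu, epoch_tau = res$epoch_tau,
              coal_opp = res$coal_opp)
  list(genealogy = from_cpp_tree(res$tree), record = rec)
}

# deterministic replay of a record on the tree it was sampled from
replay_record <- function(g, rec) {
  pt <- g$parent[rec$branch]
  if (is.na(pt) || rec$nu < g$time[rec$branch] || rec$nu >= g$time[pt])
    stop("inconsistent record chain: cut point not on the current tree")
  if (!rec$changed_tree) return(g)
  from_cpp_tree(cpp_surgery(as_cpp_tree(g), rec$branch - 1L, rec$nu,
                            rec$target - 1L, rec$tau))
}

#' Log prior path density of a genealogy sequence
#'
#' Evaluates the log density (with respect to the natural reference measure)
#' of a realisation of the sequential coalescent-with-recombination process
#' over a genomic interval: the no-recombination survival term
#' \eqn{-\int \rho B(x_s) ds} plus, for each recorded event,
#' \eqn{-\int_\nu^\tau b_u C(u) du + \log\rho + \log C(\tau)}.
#'
#' @param g0 genealogy at the left edge of the interval.
#' @param records list of event records in increasing locus order; each must
#'   apply to the tree produced by its predecessor and must have its
#'   \code{locus} set.
#' @param interval numeric length-2, the half-open genomic interval.
#' @param model a \code{\link{demographic_model}}.
#' @return log-density (the initial tree's own prior is not included).
#' @export
log_prior_path_density <- function(g0, records, interval, model) {
  em <- as_engine_model(model)
  g <- g0
  pos <- interval[1]
  lp <- 0
  for (rec in records) {
    if (is.na(rec$locus) || rec$locus < pos || rec$locus >= interval[2])
      stop("records must be ordered with loci inside the interval")
    lp <- lp - model$rho * total_branch_length(g) * (rec$locus - pos)
    lp <- lp - cpp_coal_hazard(as_cpp_tree(g), rec$nu, rec$tau, em) +
      log(model$rho) + log(coalescence_rate(model, rec$tau))
    g <- replay_record(g, rec)
    pos <- rec$locus
  }
  lp - model$rho * total_branch_length(g) * (interval[2] - pos)
}

#' Sufficient statistics of a recorded path
#'
#' Accumulates, per epoch, the recombination and coalescence event counts and
#' opportunities of a realisation: the recombination opportunity integrates
#' \eqn{b_u} over the epoch and over the genomic span each tree persists; the
#' coalescence opportunity is \eqn{\int_{\nu}^{\tau} b_u du} within the
#' epoch, summed over events; counts are assigned to the epoch containing
#' \eqn{\nu} (recombination) and \eqn{\tau} (coalescence) respectively.
#' Statistics are additive across disjoint genomic intervals.
#'
#' @inheritParams log_prior_path_density
#' @return data frame with one row per epoch: \code{epoch}, \code{start},
#'   \code{end}, \code{recomb_count}, \code{recomb_opp}, \code{coal_count},
#'   \code{coal_opp}.
#' @export
accumulate_stats <- function(g0, records, interval, model) {
  em <- as_engine_model(model)
  E <- length(model$ne)
  r_cnt <- r_opp <- c_cnt <- c_opp <- numeric(E)
  g <- g0
  pos <- interval[1]
  for (rec in records) {
    if (is.na(rec$locus) || rec$locus < pos || rec$locus >= interval[2])
      stop("records must be ordered with loci inside the interval")
    if (length(rec$coal_opp) != E) stop("record epoch grid does not match the model")
    r_opp <- r_opp + cpp_b_epoch_integral(as_cpp_tree(g), em) * (rec$locus - pos)
    r_cnt[rec$epoch_nu] <- r_cnt[rec$epoch_nu] + 1
    c_cnt[rec$epoch_tau] <- c_cnt[rec$epoch_tau] + 1
    c_opp <- c_opp + rec$coal_opp
    g <- replay_record(g, rec)
    pos <- rec$locus
  }
  r_opp <- r_opp + cpp_b_epoch_integral(as_cpp_tree(g), em) * (interval[2] - pos)
  data.frame(epoch = seq_len(E), start = model$epoch_start,
             end = c(model$epoch_start[-1], Inf),
             recomb_count = r_cnt, recomb_opp = r_opp,
             coal_count = c_cnt, coal_opp = c_opp)
}

#' Advance a single particle across a genomic interval
#'
#' Reference implementation of one particle-filter propagation step: the
#' genealogy evolves under the prior jump process over \code{[from, to)}
#' (so the proposal/prior density ratio is identically 1) and the log-weight
#' absorbs the emission log-density of each constant-tree sub-segment.
#' Observation sites in \code{(from, to]} are evaluated against the tree at
#' their locus.  Event records are appended to the particle.
#'
#' @param particle list with elements \code{tree} (a genealogy),
#'   \code{log_w}, and optionally \code{records} (list).
#' @param from,to interval endpoints, \code{from <= to}.
#' @param obs an \code{\link{observation}} (or NULL for no data).
#' @param model a \code{\link{demographic_model}}.
#' @param mask optional \code{\link{observed_mask}}.
#' @return the updated particle.
#' @export
advance_particle <- function(particle, from, to, obs = NULL, model, mask = NULL) {
  if (to < from) stop("need from <= to")
  g <- particle$tree
  lw <- particle$log_w
  recs <- particle$records %||% list()
  pos <- from
  repeat {
    if (pos >= to) break
    jmp <- sample_jump(g, pos, model, L = to)
    seg_end <- if (is.finite(jmp$locus)) jmp$locus else to
    lw <- lw + segment_log_density(g, c(pos, seg_end),
                                   obs_window(obs, pos, seg_end, closed_right = FALSE),
                                   model$mu, mask)
    if (!is.finite(jmp$locus)) break
    ar <- apply_recombination(g, jmp$branch, jmp$nu, model)
    ar$record$locus <- jmp$locus
    recs[[length(recs) + 1]] <- ar$record
    g <- ar$genealogy
    pos <- jmp$locus
  }
  # site exactly at the right edge belongs to this step (waypoints sit on sites)
  edge <- obs_window(obs, to, to, closed_right = TRUE)
  if (!is.null(edge) && length(edge$loci))
    lw <- lw + segment_site_loglik(g, edge, model$mu)
  particle$tree <- g
  particle$log_w <- lw
  particle$records <- recs
  particle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Advance a particle of multiplicity k
#'
#' Particles that are identical after resampling can be stored once with a
#' multiplicity \code{k}.  The bundle is advanced by simulating the first
#' jump at a k-fold exit rate; when an event occurs, a single particle is
#' spawned off to take it (and then evolves independently) while the
#' remaining \code{k-1} continue unchanged.  The resulting set of particles
#' is statistically indistinguishable from advancing k independent copies.
#'
#' @param particle as in \code{\link{advance_particle}}, plus a
#'   \code{multiplicity} element (positive integer).
#' @inheritParams advance_particle
#' @return list of particles whose multiplicities sum to \code{k}.
#' @export
multiplicity_advance <- function(particle, from, to, obs = NULL, model, mask = NULL) {
  k <- particle$multiplicity %||% 1L
  if (k < 1) stop("multiplicity must be a positive integer")
  out <- list()
  cur <- particle
  pos <- from
  while (k > 1) {
    B <- total_branch_length(cur$tree)
    rate <- k * model$rho * B
    d <- if (rate > 0) stats::rexp(1, rate) else Inf
    if (pos + d >= to) break
    ev <- pos + d
    # shared emission over [pos, ev) applies to every member of the bundle
    dlw <- segment_log_density(cur$tree, c(pos, ev),
                               obs_window(obs, pos, ev, closed_right = FALSE),
                               model$mu, mask)
    cur$log_w <- cur$log_w + dlw
    # one particle takes the event and continues independently
    jmp_pt <- sample_point_on_tree(cur$tree)
    sp <- cur
    sp$multiplicity <- 1L
    ar <- apply_recombination(sp$tree, jmp_pt$branch, jmp_pt$nu, model)
    ar$record$locus <- ev
    sp$records <- c(sp$records %||% list(), list(ar$record))
    sp$tree <- ar$genealogy
    out[[length(out) + 1]] <- advance_particle(sp, ev, to, obs, model, mask)
    k <- k - 1L
    cur$multiplicity <- k
    pos <- ev
  }
  cur$multiplicity <- k
  tail <- advance_particle(cur[setdiff(names(cur), "multiplicity")], pos, to, obs, model, mask)
  tail$multiplicity <- k
  out[[length(out) + 1]] <- tail
  out
}

# uniform point on the tree under branch-length measure (shared helper)
sample_point_on_tree <- function(g) {
  len <- branch_lengths(g)
  u <- stats::runif(1) * sum(len)
  cum <- cumsum(len)
  branch <- which(u <= cum)[1]
  list(branch = branch, nu = g$time[branch] + (u - c(0, cum)[branch]))
}
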