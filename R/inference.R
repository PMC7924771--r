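#' Stochastic-EM rate update
#'
#' Maximum-likelihood update for Poisson-type event rates from expected
#' sufficient statistics: rate = expected count / expected opportunity.  The
#' recombination rate is a single constant (counts and opportunities are
#' pooled over epochs); the coalescence rate is piecewise constant per epoch.
#' A zero expected count with positive opportunity legitimately yields a zero
#' rate - the fixed-point pathology that motivates the Variational Bayes
#' alternative.
#'
#' @param stats per-epoch sufficient statistics, as produced by
#'   \code{\link{run_filter}} (columns \code{recomb_count},
#'   \code{recomb_opp}, \code{coal_count}, \code{coal_opp}).
#' @return list with \code{rho}, per-epoch \code{coal_rate} and \code{ne}.
#' @export
sem_update <- function(stats) {
  if (any(stats$coal_opp <= 0) || sum(stats$recomb_opp) <= 0)
    stop("zero opportunity in one or more epochs; merge epochs (see parse_epoch_spec merge patterns)")
  rho <- sum(stats$recomb_count) / sum(stats$recomb_opp)
  coal <- stats$coal_count / stats$coal_opp
  list(rho = rho, coal_rate = coal, ne = 1 / (2 * coal))
}

#' Variational Bayes rate update
#'
#' Conjugate Gamma update: the approximate posterior of each rate is
#' \eqn{\Gamma(\alpha_0 + E[count], \beta_0 + E[opportunity])}.  Posterior
#' means are strictly positive even for zero observed counts, so zero-rate
#' fixed points are avoided.
#'
#' @inheritParams sem_update
#' @param prior list with \code{alpha_rho}, \code{beta_rho} (scalars) and
#'   \code{alpha_coal}, \code{beta_coal} (per epoch).
#' @return list with Gamma parameters and posterior means: \code{alpha_rho},
#'   \code{beta_rho}, \code{rho}, \code{alpha_coal}, \code{beta_coal},
#'   \code{coal_rate}, \code{ne}.
#' @export
vb_update <- function(stats, prior) {
  if (any(c(prior$alpha_rho, prior$beta_rho, prior$alpha_coal, prior$beta_coal) <= 0))
    stop("Gamma prior parameters must be positive")
  a_r <- prior$alpha_rho + sum(stats$recomb_count)
  b_r <- prior$beta_rho + sum(stats$recomb_opp)
  a_c <- prior$alpha_coal + stats$coal_count
  b_c <- prior$beta_coal + stats$coal_opp
  list(alpha_rho = a_r, beta_rho = b_r, rho = a_r / b_r,
       alpha_coal = a_c, beta_coal = b_c, coal_rate = a_c / b_c,
       ne = b_c / (2 * a_c))
}

#' Per-event weight factor of a Variational Bayes filter pass
#'
#' Integrating the Gamma posterior over a rate out of the path likelihood
#' leaves the likelihood at the posterior-mean rate times a factor
#' \eqn{\eta = e^{\psi(\alpha)}/\alpha} per sampled event of that type
#' (\eqn{\psi} the digamma function).  \eqn{\eta < 1} for finite
#' \eqn{\alpha}, and \eqn{\eta \to 1} as \eqn{\alpha \to \infty}, where the
#' pass degenerates to the point-estimate pass.
#'
#' @param alpha Gamma shape parameter(s), positive.
#' @return the weight factor(s).
#' @examples
#' event_weight_factor(1)  # exp(-gamma) ~ 0.561
#' @export
event_weight_factor <- function(alpha) {
  if (any(alpha <= 0)) stop("alpha must be positive")
  exp(digamma(alpha)) / alpha
}

#' Estimate per-epoch correlation distances
#'
#' The genomic distance over which a tree node of a given age persists sets
#' the natural fixed-lag for harvesting that epoch's sufficient statistics.
#' Empirically, the mean distance between creation and removal of tree nodes
#' whose age falls in the epoch is pooled over particles (collected by
#' \code{run_filter(track_life = TRUE)}).  Epochs with no observed removals
#' fall back to the analytic estimate \eqn{1/(2 \rho t)} at the epoch
#' midpoint: a node of age t carries two descendant branches of total length
#' about 2t, which attract recombinations at rate \eqn{2 \rho t} per bp.
#'
#' @param node_life data frame with \code{life_sum} and \code{life_count}
#'   per epoch (or NULL: analytic estimates everywhere).
#' @param model a \code{\link{demographic_model}}.
#' @return per-epoch correlation distances in bp.
#' @export
estimate_correlation_distances <- function(node_life = NULL, model) {
  E <- length(model$ne)
  tm <- epoch_midpoints(model)
  analytic <- 1 / (2 * model$rho * tm)
  if (is.null(node_life)) return(analytic)
  emp <- ifelse(node_life$life_count > 0, node_life$life_sum / node_life$life_count,
                analytic)
  as.numeric(emp)
}

# epoch midpoints; the open-ended last epoch uses its start plus the mean
# residual coalescence depth 2*Ne
epoch_midpoints <- function(model) {
  st <- model$epoch_start
  en <- c(st[-1], st[length(st)] + 2 * model$ne[length(model$ne)] * 2)
  mid <- (st + en) / 2
  mid[1] <- max(mid[1], en[1] / 2)
  pmax(mid, 1e-8)
}

#' Fit demographic parameters by iterated filtering
#'
#' Iterates the (lookahead) particle filter with stochastic EM or Variational
#' Bayes updates of the recombination rate and the epoch-wise coalescence
#' rates.  Each iteration runs the filter under the current rates (for VB:
#' posterior-mean rates, with a per-event weight factor
#' \code{\link{event_weight_factor}}), harvests fixed-lag-smoothed expected
#' sufficient statistics, and updates the estimates.  Per-epoch lags are
#' \code{alpha_lag} times the estimated correlation distances, analytic on
#' the first iteration and empirical afterwards.  The genome may be split
#' into chunks that are filtered independently with pooled statistics.
#'
#' @param obs an \code{\link{observation}}.
#' @param model initial \code{\link{demographic_model}} (epoch grid, initial
#'   rates; zero growth).
#' @param n_particles particles per filter pass.
#' @param iterations number of update iterations (default 15).
#' @param mode "vb" (Variational Bayes, default) or "em" (stochastic EM).
#' @param lookahead use the lookahead filter; default: TRUE for phased
#'   observations, FALSE for unphased.
#' @param alpha_lag lag multiplier on the correlation distances (default 1;
#'   0 harvests at the current locus).
#' @param mask optional \code{\link{observed_mask}}.
#' @param chunk_length optional genomic chunk size in bp; chunks are
#'   independent filter runs whose statistics are summed before each update.
#' @param prior_alpha Gamma prior shape for every rate (VB); the prior rate
#'   scale is matched to the initial rates, \code{beta0 = alpha0 / rate}.
#' @param verbose print per-iteration summaries.
#' @param ... further arguments passed to \code{\link{run_filter}}.
#' @return an object of class \code{coalpf_fit}: the per-iteration
#'   \code{trace} (one row per epoch and event type), the final \code{model},
#'   the final \code{posterior} (VB), per-iteration log-likelihood estimates
#'   and mean ESS, and the settings used.
#' @export
fit <- function(obs, model, n_particles = 1000, iterations = 15,
                mode = c("vb", "em"), lookahead = NULL, alpha_lag = 1,
                mask = NULL, chunk_length = NULL, prior_alpha = 1,
                verbose = FALSE, ...) {
  mode <- match.arg(mode)
  if (any(model$growth != 0)) stop("inference requires zero growth rates")
  E <- length(model$ne)
  if (is.null(lookahead)) lookahead <- obs$phased
  if (iterations < 1) stop("need at least one iteration")

  chunks <- split_chunks(obs, mask, chunk_length)
  rho_hat <- model$rho
  coal_hat <- 1 / (2 * model$ne)
  prior <- list(alpha_rho = prior_alpha, beta_rho = prior_alpha / rho_hat,
                alpha_coal = rep(prior_alpha, E),
                beta_coal = prior_alpha / coal_hat)
  post <- prior
  life <- NULL
  trace <- list()
  loglik <- mean_ess <- numeric(iterations)

  for (it in seq_len(iterations)) {
    cur <- with_rates(model, model$epoch_start,
                      if (mode == "vb") post$alpha_coal / post$beta_coal else coal_hat,
                      if (mode == "vb") post$alpha_rho / post$beta_rho else rho_hat)
    # The first pass has no data-informed posterior: it samples from the
    # filter under the prior-mean rates.  From iteration 2 the pass targets
    # the VB path distribution, whose per-event factors eta are then close
    # to 1 for well-observed event types.
    eta <- if (mode == "vb" && it > 1)
      list(rho = event_weight_factor(post$alpha_rho),
           coal = event_weight_factor(post$alpha_coal))
    else NULL
    lags <- alpha_lag * estimate_correlation_distances(life, cur)

    pooled <- NULL
    life_it <- data.frame(epoch = seq_len(E), life_sum = 0, life_count = 0)
    ll <- 0; me <- 0
    for (ch in chunks) {
      fr <- run_filter(ch$obs, cur, n_particles = n_particles, mask = ch$mask,
                       lookahead = lookahead, lags = lags, eta = eta,
                       track_life = TRUE, ...)
      pooled <- if (is.null(pooled)) fr$stats else {
        p <- pooled
        for (cl in c("recomb_count", "recomb_opp", "coal_count", "coal_opp"))
          p[[cl]] <- p[[cl]] + fr$stats[[cl]]
        p
      }
      life_it$life_sum <- life_it$life_sum + fr$node_life$life_sum
      life_it$life_count <- life_it$life_count + fr$node_life$life_count
      ll <- ll + fr$loglik
      me <- me + mean(fr$ess_w) / length(chunks)
    }
    life <- life_it
    loglik[it] <- ll
    mean_ess[it] <- me

    if (mode == "vb") {
      post <- vb_update(pooled, prior)
      rho_hat <- post$rho
      coal_hat <- post$coal_rate
    } else {
      up <- sem_update(pooled)
      rho_hat <- up$rho
      coal_hat <- up$coal_rate
    }
    low_opp <- pooled$coal_opp < 1
    if (any(low_opp))
      warning("expected coalescence opportunity below 1 branch-generation in epoch(s) ",
              paste(which(low_opp), collapse = ", "),
              "; consider merging epochs", call. = FALSE)

    gt <- model$generation_time
    trace[[it]] <- rbind(
      data.frame(iteration = it, epoch = seq_len(E),
                 start = model$epoch_start,
                 end = c(model$epoch_start[-1], Inf),
                 start_yr = model$epoch_start * gt,
                 end_yr = c(model$epoch_start[-1], Inf) * gt,
                 type = "Coal",
                 count = pooled$coal_count, opportunity = pooled$coal_opp,
                 rate = coal_hat, ne = 1 / (2 * coal_hat),
                 alpha = if (mode == "vb") post$alpha_coal else NA_real_,
                 beta = if (mode == "vb") post$beta_coal else NA_real_,
                 mean_ess = me),
      data.frame(iteration = it, epoch = NA_integer_,
                 start = NA_real_, end = NA_real_,
                 start_yr = NA_real_, end_yr = NA_real_,
                 type = "Recomb",
                 count = sum(pooled$recomb_count),
                 opportunity = sum(pooled$recomb_opp),
                 rate = rho_hat, ne = NA_real_,
                 alpha = if (mode == "vb") post$alpha_rho else NA_real_,
                 beta = if (mode == "vb") post$beta_rho else NA_real_,
                 mean_ess = me))
    if (verbose)
      message(sprintf("iter %2d  loglik %.2f  rho %.3g  Ne[1] %.4g  mean ESS %.0f",
                      it, ll, rho_hat, 1 / (2 * coal_hat[1]), me))
  }

  out <- list(trace = do.call(rbind, trace),
              model = with_rates(model, model$epoch_start, coal_hat, rho_hat),
              posterior = if (mode == "vb") post else NULL,
              loglik = loglik, mean_ess = mean_ess,
              settings = list(n_particles = n_particles, iterations = iterations,
                              mode = mode, lookahead = lookahead,
                              alpha_lag = alpha_lag, prior_alpha = prior_alpha,
                              chunk_length = chunk_length))
  class(out) <- "coalpf_fit"
  out
}

#' @export
print.coalpf_fit <- function(x, ...) {
  s <- x$settings
  cat("coalpf fit:", s$iterations, "iterations,", s$mode, "mode,",
      s$n_particles, "particles", if (s$lookahead) "(lookahead)" else "", "\n")
  last <- x$trace[x$trace$iteration == max(x$trace$iteration) &
                    x$trace$type == "Coal", ]
  cat("Final Ne per epoch:\n")
  print(data.frame(start = last$start, end = last$end, ne = signif(last$ne, 4)),
        row.names = FALSE)
  cat("rho =", format(x$model$rho), "\n")
  invisible(x)
}

# split an observation (+ shared mask) into independent genomic chunks with
# chunk-local coordinates
split_chunks <- function(obs, mask, chunk_length) {
  if (is.null(chunk_length) || chunk_length >= obs$L)
    return(list(list(obs = obs, mask = mask)))
  starts <- chunk_length * (seq_len(ceiling(obs$L / chunk_length)) - 1)
  lapply(starts, function(a) {
    b <- min(a + chunk_length, obs$L)
    keep <- obs$loci >= a & obs$loci < b
    o <- observation(loci = obs$loci[keep] - a,
                     patterns = if (obs$phased) obs$patterns[, keep, drop = FALSE],
                     genotypes = if (!obs$phased && !is.null(obs$genotypes))
                       obs$genotypes[, keep, drop = FALSE],
                     L = b - a, n = obs$n)
    mk <- NULL
    if (!is.null(mask)) {
      s <- pmax(mask$start, a); e <- pmin(mask$end, b)
      ok <- e > s
      if (any(ok)) mk <- observed_mask(s[ok] - a, e[ok] - a, b - a)
    }
    list(obs = o, mask = mk)
  })
}
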