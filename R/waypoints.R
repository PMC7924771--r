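#' Maximum waypoint spacing
#'
#' Between observation sites, particle weights diverge because particles
#' experience different total mutation intensities \eqn{\mu B(x_s)}.  Under a
#' stationary Gaussian approximation to that intensity the effective sample
#' size over an event-free stretch of length \eqn{\ell} decays by at most
#' \eqn{\exp(-\sigma^2 \ell^2)}, with \eqn{\sigma^2 = \theta^2 \pi^2 / 6} for
#' heterozygosity \eqn{\theta = 4 N_e \mu}.  Placing waypoints no more than
#' \eqn{(2\sigma^2)^{-1/2} = \sqrt{3}/(\pi\theta) \approx 1/(2\theta)} apart
#' therefore bounds the per-gap ESS loss to a factor \eqn{e^{-1/2} \approx
#' 0.6}.  This function returns the \eqn{1/(2\theta)} rule.
#'
#' @param theta heterozygosity \eqn{4 N_e \mu} per bp (positive).
#' @return spacing in bp.
#' @examples
#' max_waypoint_spacing(1e-3)  # 500
#' @export
max_waypoint_spacing <- function(theta) {
  if (theta <= 0) stop("theta must be positive")
  1 / (2 * theta)
}

#' Build the waypoint plan
#'
#' Waypoints are the loci at which the filter evaluates weights and may
#' resample.  The plan is the union of every observation locus (mitigating
#' the weight variance induced at sites) and a regular in-fill ensuring no
#' gap exceeds the maximum spacing; 0 and L are always included.
#'
#' @param obs an \code{\link{observation}} (or NULL).
#' @param theta heterozygosity used for the spacing rule.
#' @param L sequence length.
#' @param spacing optional explicit maximum spacing, overriding
#'   \code{max_waypoint_spacing(theta)}.
#' @return increasing numeric vector of waypoint loci from 0 to L.
#' @export
build_waypoints <- function(obs = NULL, theta, L, spacing = NULL) {
  if (L <= 0) stop("L must be positive")
  if (is.null(spacing)) spacing <- max_waypoint_spacing(theta)
  anchors <- sort(unique(c(0, L, if (!is.null(obs)) obs$loci)))
  out <- numeric(0)
  for (i in seq_len(length(anchors) - 1)) {
    a <- anchors[i]; b <- anchors[i + 1]
    k <- ceiling((b - a) / spacing)
    out <- c(out, seq(a, b, length.out = k + 1)[-(k + 1)])
  }
  c(out, L)
}

#' Effective sample size
#'
#' \eqn{ESS = (\sum w)^2 / \sum w^2}: the number of equally-weighted
#' particles the ensemble is worth.
#'
#' @param weights non-negative weights (not all zero), or log-weights with
#'   \code{log = TRUE} (normalised stably via the running maximum).
#' @param log interpret \code{weights} as log-weights.
#' @return the effective sample size.
#' @export
ess <- function(weights, log = FALSE) {
  if (log) {
    m <- max(weights)
    if (!is.finite(m)) stop("all weights are zero")
    weights <- exp(weights - m)
  }
  if (any(weights < 0)) stop("weights must be non-negative")
  s <- sum(weights)
  if (s == 0) stop("all weights are zero")
  s^2 / sum(weights^2)
}

#' Systematic resampling
#'
#' Offspring counts from a single stratified sweep with offset \code{u0/N}:
#' particle i receives \code{floor(N w_i)} or \code{ceiling(N w_i)} copies
#' and the counts sum to N.  This is the minimum-variance scheme used at
#' every resampling step of the filter.
#'
#' @param weights normalised weights (summing to 1).
#' @param u0 a uniform draw in \code{[0, 1)}; defaults to a fresh draw.
#' @param N number of offspring (defaults to \code{length(weights)}).
#' @return integer vector of offspring counts.
#' @export
systematic_resample <- function(weights, u0 = stats::runif(1), N = length(weights)) {
  stopifnot(abs(sum(weights) - 1) < 1e-8, u0 >= 0, u0 < 1)
  cnt <- integer(length(weights))
  cum <- 0; k <- 0
  for (i in seq_along(weights)) {
    cum <- cum + weights[i]
    while (k < N && (k + u0) / N < cum) { cnt[i] <- cnt[i] + 1L; k <- k + 1L }
  }
  if (k < N) cnt[length(cnt)] <- cnt[length(cnt)] + (N - k)
  cnt
}

#' @rdname systematic_resample
#' @details \code{multinomial_resample} and \code{residual_resample} are
#'   provided for comparison in tests only; the filter always resamples
#'   systematically.
#' @export
multinomial_resample <- function(weights, N = length(weights)) {
  as.integer(stats::rmultinom(1, N, weights))
}

#' @rdname systematic_resample
#' @export
residual_resample <- function(weights, N = length(weights)) {
  base <- floor(N * weights)
  r <- N - sum(base)
  if (r > 0) {
    resid <- N * weights - base
    extra <- stats::rmultinom(1, r, resid / sum(resid))
    base <- base + extra
  }
  as.integer(base)
}
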