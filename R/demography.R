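#' Piecewise demographic model
#'
#' Defines the demographic history used both to simulate data and as the
#' current parameter state during inference: an epoch grid on evolutionary
#' time (generations), a diploid effective population size per epoch (with an
#' optional exponential growth rate, used by the simulator only), a
#' recombination rate \code{rho} and a mutation rate \code{mu}, both per
#' nucleotide and per generation.  The instantaneous coalescence rate is
#' \eqn{C(u) = 1/(2 N_e(u))}; epochs are half-open \eqn{[t_e, t_{e+1})} and
#' the last epoch extends to infinity.
#'
#' @param ne diploid effective population size per epoch (positive).
#' @param epoch_start epoch start times in generations; strictly increasing,
#'   first element 0.  Length must match \code{ne}.
#' @param growth per-epoch exponential growth rate (per generation, forward
#'   in time; \code{Ne(u) = ne[e] * exp(-growth[e] * (u - epoch_start[e]))}
#'   going backwards).  Supported by the simulator; inference estimates
#'   piecewise-constant rates and requires all zeros.  The final epoch must
#'   have zero growth.
#' @param rho recombination rate per nucleotide per generation.
#' @param mu mutation rate per nucleotide per generation.
#' @param generation_time years per generation, used only when reporting
#'   results in years.
#'
#' @return An object of class \code{coalpf_model}.
#' @examples
#' m <- demographic_model(ne = 10000, rho = 1e-8, mu = 2.5e-8)
#' coalescence_rate(m, 500)   # 1 / 20000
#' @export
demographic_model <- function(ne, epoch_start = 0, growth = 0,
                              rho = 1e-8, mu = 2.5e-8, generation_time = 29) {
  ne <- as.numeric(ne)
  epoch_start <- as.numeric(epoch_start)
  if (length(growth) == 1L) growth <- rep(as.numeric(growth), length(ne))
  if (length(epoch_start) != length(ne) || length(growth) != length(ne))
    stop("ne, epoch_start and growth must have equal length")
  if (epoch_start[1] != 0) stop("first epoch must start at 0")
  if (any(diff(epoch_start) <= 0)) stop("epoch boundaries must be strictly increasing")
  if (any(!is.finite(ne)) || any(ne <= 0)) stop("all Ne must be positive and finite")
  if (rho < 0 || mu <= 0) stop("need rho >= 0 and mu > 0")
  if (growth[length(growth)] != 0) stop("final epoch must have zero growth")
  structure(list(ne = ne, epoch_start = epoch_start, growth = growth,
                 rho = rho, mu = mu, generation_time = generation_time),
            class = "coalpf_model")
}

# internal: the list layout the compiled engine expects
as_engine_model <- function(model) {
  list(epoch_start = model$epoch_start,
       coal_rate = 1 / (2 * model$ne),
       growth = model$growth,
       rho = model$rho, mu = model$mu)
}

#' @export
print.coalpf_model <- function(x, ...) {
  cat("Demographic model:", length(x$ne), "epoch(s)\n")
  en <- c(x$epoch_start[-1], Inf)
  for (e in seq_along(x$ne))
    cat(sprintf("  [%8.4g, %8.4g) gen  Ne = %-10.6g growth = %g\n",
                x$epoch_start[e], en[e], x$ne[e], x$growth[e]))
  cat(sprintf("  rho = %g  mu = %g  (per bp per generation), g = %g yr\n",
              x$rho, x$mu, x$generation_time))
  invisible(x)
}

#' Instantaneous coalescence rate
#'
#' Evaluates \eqn{C(u) = 1/(2 N_e(u))} at evolutionary time \code{u}
#' (generations).  Epochs are half-open, so a time exactly on an epoch
#' boundary takes the later epoch's rate.
#'
#' @param model a \code{\link{demographic_model}}.
#' @param u evolutionary time(s) in generations, non-negative.
#' @return coalescence rate(s) per generation.
#' @export
coalescence_rate <- function(model, u) {
  if (any(u < 0)) stop("evolutionary time must be non-negative")
  e <- findInterval(u, model$epoch_start)
  rate <- 1 / (2 * model$ne[e])
  g <- model$growth[e]
  ifelse(g != 0, rate * exp(g * (u - model$epoch_start[e])), rate)
}

# epoch index (1-based) containing each time u
epoch_index <- function(model, u) findInterval(u, model$epoch_start)

#' Parse an epoch specification string
#'
#' Three forms are accepted:
#' \itemize{
#'   \item explicit boundaries, e.g. \code{"400,800,1200,2000"} (or a numeric
#'     vector): epochs \code{[0,400), [400,800), ...} with a final open-ended
#'     epoch;
#'   \item a log-spaced triple \code{"A B k*1"}: \code{k} boundaries placed
#'     logarithmically from \code{A} to \code{B} generations, giving
#'     \code{k+1} epochs including \code{[0,A)} and \code{[B,Inf)};
#'   \item a merge pattern such as \code{"4*1+7*2+8*5"} applied to a base
#'     grid supplied via \code{base}: consecutive base intervals are merged
#'     in groups, PSMC-style.  The multiplicities must sum to the number of
#'     base intervals.
#' }
#'
#' @param spec character scalar (or numeric vector of boundaries).
#' @param base numeric vector of base-grid boundaries (first element 0),
#'   required for the merge-pattern form.
#' @return numeric vector of epoch start times, beginning with 0.
#' @examples
#' length(parse_epoch_spec("133 133016 31*1"))  # 32 epochs
#' parse_epoch_spec("400,800,1200")
#' @export
parse_epoch_spec <- function(spec, base = NULL) {
  if (is.numeric(spec)) {
    b <- sort(unique(as.numeric(spec)))
    if (b[1] != 0) b <- c(0, b)
    return(b)
  }
  spec <- trimws(spec)
  toks <- strsplit(spec, "[[:space:]]+")[[1]]
  if (length(toks) == 3 && !grepl("\\+", spec) && grepl("^\\d+\\*1$", toks[3])) {
    a <- as.numeric(toks[1]); b <- as.numeric(toks[2])
    k <- as.integer(sub("\\*1$", "", toks[3]))
    if (!(a > 0 && b > a && k >= 2)) stop("bad log-spaced epoch spec")
    return(c(0, exp(seq(log(a), log(b), length.out = k))))
  }
  if (grepl("\\*", spec) && grepl("\\+", spec)) {
    if (is.null(base)) stop("merge-pattern epoch specs need a base grid")
    groups <- strsplit(spec, "\\+")[[1]]
    mult <- vapply(groups, function(g) {
      p <- as.integer(strsplit(g, "\\*")[[1]])
      if (length(p) != 2) stop("bad merge-pattern term: ", g)
      p
    }, integer(2))
    counts <- rep(mult[2, ], mult[1, ])
    nint <- length(base) - 1
    if (sum(counts) != nint)
      stop("merge pattern covers ", sum(counts), " base intervals but the grid has ", nint)
    idx <- cumsum(c(1L, counts))
    # group start points plus the top of the base grid (whose tail forms the
    # final open-ended epoch)
    return(base[idx])
  }
  b <- sort(unique(as.numeric(strsplit(spec, ",")[[1]])))
  if (anyNA(b)) stop("could not parse epoch spec: ", spec)
  if (b[1] != 0) b <- c(0, b)
  b
}

#' Replace the epoch grid / rates of a model
#'
#' Helper used by the inference loop: returns a copy of \code{model} with
#' piecewise-constant coalescence rates \code{coal_rate} (per epoch of
#' \code{epoch_start}) and recombination rate \code{rho}.
#'
#' @param model a \code{coalpf_model} (supplies mu and generation time).
#' @param epoch_start new epoch start times (first 0).
#' @param coal_rate per-epoch coalescence rate; Ne is \code{1/(2*coal_rate)}.
#' @param rho new recombination rate (default: keep).
#' @return a \code{coalpf_model}.
#' @export
with_rates <- function(model, epoch_start, coal_rate, rho = model$rho) {
  demographic_model(ne = 1 / (2 * coal_rate), epoch_start = epoch_start,
                    growth = 0, rho = rho, mu = model$mu,
                    generation_time = model$generation_time)
}
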