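#' Genealogies (local trees)
#'
#' A genealogy is the rooted binary tree relating the n sampled haplotypes at
#' one genomic position: the latent state of the sequential
#' coalescent-with-recombination process.  Nodes are indexed 1..2n-1 (tips
#' 1..n at age 0, internal nodes n+1..2n-1); \code{parent} holds the parent
#' index per node (NA at the root) and \code{time} the node ages in
#' generations.  The root's branch extends to infinity: it carries no
#' recombination and contributes nothing to the total branch length, and the
#' branch count \eqn{b_u} equals 1 above the root.
#'
#' @param parent integer vector, length 2n-1; NA marks the root.
#' @param time numeric node ages (tips 0).
#' @return an object of class \code{genealogy}.
#' @export
genealogy <- function(parent, time) {
  n <- (length(parent) + 1) / 2
  if (n < 2 || n != floor(n)) stop("need 2n-1 nodes for n >= 2 tips")
  if (sum(is.na(parent)) != 1) stop("exactly one root expected")
  if (length(time) != length(parent)) stop("parent/time length mismatch")
  g <- structure(list(n = as.integer(n), parent = as.integer(parent),
                      time = as.numeric(time)), class = "genealogy")
  ok <- which(!is.na(parent))
  if (any(time[parent[ok]] <= time[ok]))
    stop("child age must be below parent age")
  g
}

#' @export
print.genealogy <- function(x, ...) {
  cat("Genealogy over", x$n, "tips; TMRCA =", format(tmrca(x)), "generations;",
      "B =", format(total_branch_length(x)), "\n")
  invisible(x)
}

# conversions to/from the 0-based arrays the compiled code uses
as_cpp_tree <- function(g) {
  p <- g$parent - 1L
  p[is.na(p)] <- -1L
  list(parent = p, time = g$time)
}
from_cpp_tree <- function(tl) {
  p <- tl$parent + 1L
  p[p == 0L] <- NA_integer_
  structure(list(n = as.integer((length(p) + 1) / 2), parent = p,
                 time = tl$time), class = "genealogy")
}

#' Sample a stationary coalescent genealogy
#'
#' Draws a genealogy from the standard coalescent under the given demography:
#' starting from n lineages at time 0, each pair of extant lineages merges at
#' the instantaneous rate \eqn{C(u)}.  This is the state distribution used to
#' initialise the particle filter at the left edge of a (chunk of) genome.
#'
#' @param model a \code{\link{demographic_model}}.
#' @param n number of tips (haplotypes), at least 2.
#' @return a \code{\link{genealogy}}.
#' @export
sample_stationary_tree <- function(model, n) {
  if (n < 2) stop("need at least two tips")
  from_cpp_tree(cpp_sample_tree(as.integer(n), as_engine_model(model)))
}

#' Total branch length of a genealogy
#'
#' \eqn{B = \int_0^{root} b_u \, du}, equivalently the sum over non-root
#' nodes of (parent age - node age).  Mutations fall on the tree at total
#' rate \eqn{\mu B} and recombinations at \eqn{\rho B} per nucleotide.
#'
#' @param g a \code{\link{genealogy}}.
#' @return branch length in generations.
#' @export
total_branch_length <- function(g) {
  ok <- !is.na(g$parent)
  sum(g$time[g$parent[ok]] - g$time[ok])
}

#' @rdname total_branch_length
#' @export
tmrca <- function(g) g$time[which(is.na(g$parent))]

# branch lengths per node (0 at root)
branch_lengths <- function(g) {
  len <- rep(0, length(g$parent))
  ok <- !is.na(g$parent)
  len[ok] <- g$time[g$parent[ok]] - g$time[ok]
  len
}

# tips below each node, as a list of integer vectors
descendant_tips <- function(g) {
  nn <- length(g$parent)
  d <- vector("list", nn)
  ord <- order(g$time)
  for (v in ord) {
    if (v <= g$n) d[[v]] <- v
    else d[[v]] <- sort(unlist(d[which(g$parent == v)]))
  }
  d
}

#' Export a genealogy in Newick format
#'
#' Branch lengths are in generations.  Intended for debugging and for
#' interchange with tree packages (\code{ape::read.tree} reads the output).
#'
#' @param g a \code{\link{genealogy}}.
#' @param digits significant digits for branch lengths.
#' @return a Newick string.
#' @export
as_newick <- function(g, digits = 8) {
  len <- branch_lengths(g)
  rec <- function(v) {
    if (v <= g$n) lab <- as.character(v)
    else {
      ch <- which(g$parent == v)
      lab <- paste0("(", rec(ch[1]), ",", rec(ch[2]), ")")
    }
    if (is.na(g$parent[v])) paste0(lab, ";")
    else paste0(lab, ":", format(len[v], digits = digits))
  }
  rec(which(is.na(g$parent)))
}

#' Convert a genealogy to an ape "phylo" tree
#'
#' @param g a \code{\link{genealogy}}.
#' @return an \code{ape::phylo} object.
#' @export
as_phylo <- function(g) ape::read.tree(text = as_newick(g))

# number of cherries (internal nodes with two tip children)
n_cherries <- function(g) {
  internal <- (g$n + 1):(2 * g$n - 1)
  sum(vapply(internal, function(v) sum(g$parent[seq_len(g$n)] == v, na.rm = TRUE) == 2,
             logical(1)))
}

# TRUE if tips a and b are siblings
is_cherry <- function(g, a, b) {
  !is.na(g$parent[a]) && g$parent[a] == g$parent[b]
}
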