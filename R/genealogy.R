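#' Simulate a coalescent genealogy
#'
#' Standard n-coalescent: with `k` active lineages the waiting time to the
#' next coalescence is exponential with rate `k(k-1)/2` per `2N` generations;
#' a uniformly random pair merges.  Under exponential growth
#' (`N(t) = N exp(-g t)` looking backwards in time) the clock is
#' deterministically time-changed, which preserves seedability.  Branch
#' lengths are in generations; use [scale_tree()] to convert to expected
#' substitutions per site.
#'
#' @param n Sample size (>= 2 tips).
#' @param N Population size in individuals (>= 1); `E[T2] = 2N` generations.
#' @param growth_rate Exponential growth rate per generation (>= 0).
#' @param seed Optional integer seed (uses the current RNG stream if `NULL`).
#' @param tip_labels Optional tip names (default `t1..tn`).
#' @return An `ape` \code{phylo} tree with attribute `units = "generations"`
#'   and `provenance = "coalescent"`; ultrametric, `n - 1` internal nodes.
#' @export
simulate_coalescent <- function(n, N = 1000, growth_rate = 0, seed = NULL,
                                tip_labels = NULL) {
  stopifnot(n >= 2, N >= 1, growth_rate >= 0)
  if (!is.null(seed)) return(.with_seed(seed,
    simulate_coalescent(n, N, growth_rate, NULL, tip_labels)))
  n <- as.integer(n)
  active <- seq_len(n)                  # ape ids: tips 1..n
  t_node <- numeric(2L * n - 1L)        # node times (generations before now)
  edge <- matrix(0L, 2L * (n - 1L), 2L)
  elen <- numeric(2L * (n - 1L))
  t_cur <- 0
  eidx <- 0L
  for (k in n:2) {
    rate <- k * (k - 1) / 2 / (2 * N)   # pair-coalescence rate at N(t)=N
    Ex <- rexp(1L)
    if (growth_rate == 0) {
      w <- Ex / rate
    } else {
      # solve int_{t_cur}^{t_cur+w} rate * e^{g s} ds = Ex
      g <- growth_rate
      w <- log(exp(g * t_cur) + g * Ex / rate) / g - t_cur
    }
    t_cur <- t_cur + w
    pick <- sample.int(k, 2L)
    a <- active[pick[1]]; b <- active[pick[2]]
    # internal ids: root (last merge) gets n+1 per ape convention
    p <- 2L * n - (n - k + 1L)
    t_node[p] <- t_cur
    edge[eidx + 1L, ] <- c(p, a); elen[eidx + 1L] <- t_cur - t_node[a]
    edge[eidx + 2L, ] <- c(p, b); elen[eidx + 2L] <- t_cur - t_node[b]
    eidx <- eidx + 2L
    active <- c(active[-pick], p)
  }
  if (is.null(tip_labels)) tip_labels <- paste0("t", seq_len(n))
  tr <- structure(list(edge = edge, edge.length = elen,
                       tip.label = tip_labels, Nnode = n - 1L),
                  class = "phylo", order = "postorder")
  tr <- ape::reorder.phylo(tr, "cladewise")
  attr(tr, "units") <- "generations"
  attr(tr, "provenance") <- "coalescent"
  tr
}

#' Scale a genealogy from generations to substitutions per site
#'
#' Multiplies every branch by `mu = theta / (4 N l)`, the per-site
#' per-generation substitution rate implied by the population substitution
#' rate `theta = 4 N mu l`.
#'
#' @param tree A \code{phylo} tree with branch lengths in generations.
#' @param theta Population substitution rate (>= 0).
#' @param N Population size used to simulate the tree.
#' @param l Number of sites (> 0).
#' @return The tree with branch lengths in expected substitutions per site.
#' @export
scale_tree <- function(tree, theta, N, l) {
  stopifnot(theta >= 0)
  if (l == 0) stop("l must be positive", call. = FALSE)
  tree$edge.length <- tree$edge.length * (theta / (4 * N * l))
  attr(tree, "units") <- "substitutions/site"
  tree
}

#' Parse a rooted Newick tree
#'
#' Branch lengths are taken as expected substitutions per site.  Polytomies
#' (including a trifurcating root) are resolved arbitrarily with zero-length
#' branches and a warning.
#'
#' @param text Newick string.
#' @return A binary rooted \code{phylo} with `provenance = "user"`.
#' @export
parse_newick <- function(text) {
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("format error: could not parse Newick", call. = FALSE)
  if (is.null(tr$edge.length)) {
    stop("format error: tree has no branch lengths", call. = FALSE)
  }
  if (!ape::is.binary(tr) || !ape::is.rooted(tr)) {
    warning("polytomies resolved arbitrarily with zero-length branches")
    tr <- ape::multi2di(tr)
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0)) {
    stop("format error: negative branch length", call. = FALSE)
  }
  attr(tr, "units") <- "substitutions/site"
  attr(tr, "provenance") <- "user"
  tr
}

#' Write a genealogy as Newick
#'
#' @param tree A \code{phylo}.
#' @param path Optional file; if `NULL` the Newick string is returned.
#' @return Newick string (invisibly when writing to file).
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

# tree height (root to tip distance); assumes ultrametric for coalescent use
.tree_height <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  max(depths[seq_along(tree$tip.label)])
}
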