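#' Draw per-site rate multipliers
#'
#' Each site is invariable with probability `p_inv` (multiplier 0); variable
#' sites draw continuous Gamma(shape = `gamma_shape`, mean 1) rates,
#' renormalised to mean exactly 1 over the variable sites.  With
#' `gamma_shape = NULL` all variable-site multipliers are exactly 1.
#'
#' @param l Number of sites.
#' @param gamma_shape Positive Gamma shape, or `NULL` for uniform rates.
#' @param p_inv Proportion of invariable sites in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return List with `multipliers` (length `l`) and `invariant_mask`.
#' @export
draw_site_rates <- function(l, gamma_shape = NULL, p_inv = 0, seed = NULL) {
  if (!is.null(gamma_shape) && gamma_shape <= 0) {
    stop("gamma_shape must be positive", call. = FALSE)
  }
  stopifnot(p_inv >= 0, p_inv < 1, l >= 1)
  if (!is.null(seed)) {
    return(.with_seed(seed, draw_site_rates(l, gamma_shape, p_inv, NULL)))
  }
  mask <- rbinom(l, 1L, p_inv) == 1L
  r <- rep(1, l)
  nv <- sum(!mask)
  if (!is.null(gamma_shape) && nv > 0L) {
    g <- rgamma(nv, shape = gamma_shape, rate = gamma_shape)
    r[!mask] <- g / mean(g)
  }
  r[mask] <- 0
  list(multipliers = r, invariant_mask = mask)
}

# eigendecomposition of a reversible generator via symmetrisation
.q_eigen <- function(Q, pi) {
  sp <- sqrt(pi)
  B <- Q * (sp %o% (1 / sp))           # diag(sp) Q diag(1/sp), symmetric
  es <- eigen((B + t(B)) / 2, symmetric = TRUE)
  V <- es$vectors / sp                 # columns of right eigenvectors of Q
  Vinv <- t(es$vectors * sp)
  list(values = es$values, V = V, Vinv = Vinv)
}

#' Simulate an alignment under an empirical substitution model
#'
#' Forward in time from root to tips: the root is drawn i.i.d. from the
#' equilibrium frequencies and each site evolves along each branch of length
#' `b` by the Markov chain with transition matrix `expm(Q b r_i)` where `r_i`
#' is the site's rate multiplier.
#'
#' @param tree \code{phylo} with branch lengths in substitutions per site.
#' @param model An `scs_empirical_model`.
#' @param l Number of sites to simulate (ignored when `rates` given).
#' @param rates Optional result of [draw_site_rates()].
#' @param seed Optional integer seed (same seed, bit-identical alignment).
#' @return An [scs_alignment] with tips in tree tip order.
#' @export
evolve_empirical <- function(tree, model, l = NULL, rates = NULL,
                             seed = NULL) {
  if (!is.null(seed)) {
    return(.with_seed(seed, evolve_empirical(tree, model, l, rates, NULL)))
  }
  if (is.null(rates)) {
    if (is.null(l)) stop("give l or rates", call. = FALSE)
    rates <- draw_site_rates(l, model$gamma_shape, model$p_inv)
  }
  r <- rates$multipliers
  l <- length(r)
  Q <- build_rate_matrix(model)
  eg <- .q_eigen(Q, model$pi)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  states <- matrix(0L, nnode, l)
  root <- ntip + 1L
  states[root, ] <- sample.int(20L, l, replace = TRUE, prob = model$pi)
  tree <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
    b <- tree$edge.length[e]
    states[chi, ] <- .evolve_branch_sites(states[par, ], b, r, eg)
  }
  rows <- vapply(seq_len(ntip),
                 function(i) paste(AA_ALPHABET20[states[i, ]], collapse = ""),
                 character(1))
  scs_alignment(tree$tip.label, rows)
}

# evolve all sites along one branch: groups sites by parent state, computes
# the transition row p_s(.) = V[s,] diag(e^{lambda b r}) Vinv per site
.evolve_branch_sites <- function(parent, b, r, eg) {
  out <- parent
  if (b == 0) return(out)
  active <- which(r > 0)
  if (!length(active)) return(out)
  Ew <- exp(outer(eg$values, b * r[active]))      # 20 x n_active
  for (s in unique(parent[active])) {
    idx <- active[parent[active] == s]
    cols <- match(idx, active)
    P <- crossprod(eg$Vinv, eg$V[s, ] * Ew[, cols, drop = FALSE])  # 20 x nidx
    P[P < 0] <- 0
    cum <- apply(P, 2, cumsum)
    tot <- cum[20, ]
    u <- runif(length(idx)) * tot
    out[idx] <- max.col(t(cum >= rep(u, each = 20)), "first")
  }
  out
}

#' Two-state fitness from folding free energy
#'
#' The fraction of molecules in the native state,
#' `f(dG) = 1 / (1 + exp(dG / T))`: 0.5 at `dG = 0`, tending to 1 for very
#' stable (`dG << 0`) and 0 for very unstable proteins.
#'
#' @param dG Folding free energy (negative = stable).
#' @param T Thermodynamic temperature (> 0).
#' @return Fitness in (0, 1).
#' @export
fitness_of <- function(dG, T) {
  if (any(T <= 0)) stop("T must be positive", call. = FALSE)
  1 / (1 + exp(dG / T))
}

#' Moran fixation probability
#'
#' Probability that a single new variant of fitness `f_new` fixes in a Moran
#' population of size `Ne` of residents with fitness `f_old`:
#' `(1 - rho) / (1 - rho^Ne)` with `rho = f_old / f_new`; `1/Ne` in the
#' neutral limit and 1 when `Ne = 1`.
#'
#' @param f_old,f_new Positive fitnesses of resident and new variant.
#' @param Ne Population size (>= 1).
#' @return Fixation probability in (0, 1].
#' @export
moran_fixation <- function(f_old, f_new, Ne) {
  if (any(f_old <= 0) || any(f_new <= 0)) {
    stop("fitnesses must be positive", call. = FALSE)
  }
  stopifnot(Ne >= 1)
  if (Ne == 1) return(rep_len(1, max(length(f_old), length(f_new))))
  rho <- f_old / f_new
  out <- ifelse(abs(1 - rho) < 1e-12, 1 / Ne, (1 - rho) / (1 - rho^Ne))
  unname(out)
}

#' Parameters of a structurally constrained substitution model
#'
#' @param kind `"neutral"` (binary viability: variants with `dG` at most
#'   `dG_threshold` are viable and equally fit) or `"fitness"` (fitness is
#'   the native-state occupancy; mutations fix by Moran dynamics in a
#'   population of size `Ne`).
#' @param T Thermodynamic temperature (> 0); taken from the stability model
#'   when `NULL`.
#' @param dG_threshold Viability boundary for the neutral model.
#' @param Ne Moran population size (>= 1).
#' @param root_mode `"structure_native"` or `"user_sequence"`.
#' @param root_sequence Root sequence when `root_mode = "user_sequence"`.
#' @param burnin_proposals Number of accepted moves used to equilibrate the
#'   root before the tree root (`NULL` = 10 L, the default; 0 disables).
#' @return An `scs_params` list.
#' @export
scs_params <- function(kind = c("neutral", "fitness"), T = NULL,
                       dG_threshold = 0, Ne = 100,
                       root_mode = c("structure_native", "user_sequence"),
                       root_sequence = NULL, burnin_proposals = NULL) {
  kind <- match.arg(kind)
  root_mode <- match.arg(root_mode)
  if (!is.null(T) && T <= 0) stop("T must be positive", call. = FALSE)
  stopifnot(Ne >= 1)
  structure(list(kind = kind, T = T, dG_threshold = dG_threshold, Ne = Ne,
                 root_mode = root_mode, root_sequence = root_sequence,
                 burnin_proposals = burnin_proposals),
            class = "scs_params")
}

#' Simulate an alignment under a structurally constrained model
#'
#' Forward simulation along the genealogy: proposal events arrive as a
#' Poisson process with per-site rate `r_i` per unit branch length (branch
#' lengths therefore calibrate the attempted mutation rate; realized
#' substitution counts are returned per branch).  Each proposal draws a
#' uniform alternative residue.  Neutral model: accept iff the mutant
#' `dG <= dG_threshold`.  Fitness model: accept with probability
#' `min(1, Ne * moran_fixation(f_old, f_new, Ne))`, the fixation probability
#' scaled so the neutral limit accepts with probability 1 (this is what makes
#' the fitness model collapse onto the neutral model at low temperature).
#'
#' @param tree \code{phylo}, branch lengths in attempted substitutions/site.
#' @param params An [scs_params].
#' @param stab An `scs_stability_model` (provides structure, potential, T).
#' @param rates Optional [draw_site_rates()] result (default: all sites 1).
#' @param seed Optional integer seed.
#' @param instrument If `TRUE`, also return all node sequences, node dG
#'   values and the per-proposal acceptance decisions.
#' @return An [scs_alignment] with attributes `realized_substitutions`
#'   (per edge) and, when instrumented, `node_seqs`, `node_dg`, `decisions`.
#' @export
evolve_scs <- function(tree, params, stab, rates = NULL, seed = NULL,
                       instrument = FALSE) {
  if (!is.null(seed)) {
    return(.with_seed(seed,
                      evolve_scs(tree, params, stab, rates, NULL, instrument)))
  }
  L <- stab$L
  root_str <- if (params$root_mode == "user_sequence") {
    if (is.null(params$root_sequence)) stop("root_sequence missing", call. = FALSE)
    params$root_sequence
  } else {
    if (is.null(stab$native_seq)) {
      stop("stability model carries no native sequence", call. = FALSE)
    }
    stab$native_seq
  }
  root_v <- .encode_seq(root_str)
  if (length(root_v) != L) stop("root sequence length != L", call. = FALSE)
  Tval <- if (is.null(params$T)) stab$T else params$T
  stab_eff <- stab
  stab_eff$T <- Tval
  root_dg <- delta_g(root_v, stab_eff)$dG
  if (params$kind == "neutral" && root_dg > params$dG_threshold) {
    stop(sprintf(paste0("root sequence violates neutral viability ",
                        "(dG = %.4f > threshold %.4f); raise dG_threshold ",
                        "to at least %.4f"),
                 root_dg, params$dG_threshold, root_dg), call. = FALSE)
  }
  r <- if (is.null(rates)) rep(1, L) else rates$multipliers
  if (all(r == 0)) stop("all sites invariable", call. = FALSE)
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  burn <- params$burnin_proposals
  if (is.null(burn)) burn <- 10L * L
  res <- evolve_scs_tree_cpp(root_v, tree$edge[, 1], tree$edge[, 2],
                             tree$edge.length, ntip + tree$Nnode, ntip + 1L,
                             r, stab_eff,
                             if (params$kind == "neutral") 0L else 1L,
                             params$dG_threshold, params$Ne,
                             burnin_accepts = as.integer(burn),
                             record_decisions = isTRUE(instrument))
  rows <- vapply(seq_len(ntip),
                 function(i) .decode_seq(res$node_seq[i, ]), character(1))
  aln <- scs_alignment(tree$tip.label, rows)
  attr(aln, "realized_substitutions") <- res$realized
  if (instrument) {
    attr(aln, "node_seqs") <- res$node_seq
    attr(aln, "node_dg") <- res$node_dg
    attr(aln, "decisions") <- res$decisions
    attr(aln, "proposals") <- data.frame(dg_old = res$prop_dg_old,
                                         dg_new = res$prop_dg_new,
                                         u = res$prop_u)
  }
  aln
}
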