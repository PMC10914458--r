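# run expr with a temporary RNG state seeded by `seed`, restoring the caller's
# stream afterwards
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

#' Bundled contact potential (synthetic, hydrophobicity-based)
#'
#' A 20x20 symmetric quasi-potential `U[a,b] = -h(a) h(b)` built from the
#' Kyte-Doolittle hydrophopathy scale rescaled to `[-1, 1]`.  Contacts between
#' hydrophobic residues are favourable (negative), mimicking the dominant
#' hydrophobic term of statistical contact potentials.  It is a synthetic
#' stand-in, not a published knowledge-based potential; any symmetric 20x20
#' matrix can be supplied wherever a potential is accepted.
#'
#' @return Object of class `scs_potential` wrapping the matrix `U`.
#' @export
default_contact_potential <- function() {
  kd <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
          I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
          R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
  h <- kd[AA_ALPHABET20] / 4.5
  contact_potential(-outer(h, h), name = "kd_product_synthetic")
}

#' Wrap a 20x20 contact-energy matrix
#'
#' @param U Symmetric numeric 20x20 matrix in [AA_ALPHABET20] order
#'   (dimensionless energies, negative = favourable).
#' @param name Label for provenance.
#' @return An `scs_potential`.
#' @export
contact_potential <- function(U, name = "custom") {
  U <- as.matrix(U)
  stopifnot(identical(dim(U), c(20L, 20L)))
  if (max(abs(U - t(U))) > 1e-12) {
    stop("contact potential must be symmetric", call. = FALSE)
  }
  dimnames(U) <- list(AA_ALPHABET20, AA_ALPHABET20)
  structure(list(U = U, name = name), class = "scs_potential")
}

#' Native contact energy of a sequence on a contact map
#'
#' Sum of `U[seq_i, seq_j]` over all contact pairs.  Gap/`X` positions are
#' only allowed via [delta_g()], which substitutes the mean potential value.
#'
#' @param seq Amino-acid string of length `cmap$L`.
#' @param cmap An `scs_contact_map`.
#' @param potential An `scs_potential`.
#' @return Scalar energy.
#' @export
native_energy <- function(seq, cmap, potential = default_contact_potential()) {
  v <- .encode_seq(seq)
  if (length(v) != cmap$L) {
    stop("sequence length ", length(v), " does not match contact map L = ",
         cmap$L, call. = FALSE)
  }
  if (nrow(cmap$pairs) == 0L) return(0)
  if (any(v[unique(as.vector(cmap$pairs))] <= 0L)) {
    stop("gap/X at a contacting position; use delta_g() for gapped sequences",
         call. = FALSE)
  }
  sum(potential$U[cbind(v[cmap$pairs[, 1]], v[cmap$pairs[, 2]])])
}

#' Generate misfolded decoy contact maps by circular-shift threading
#'
#' Decoy `k` re-threads the chain through the native contact topology by a
#' circular index shift (and, once shifts are exhausted, a direction flip),
#' discards pairs whose shifted separation falls below `s_min`, and restores
#' the native contact count by sampling uniformly among valid absent pairs.
#' All decoys share `L` and the native number of contacts.
#'
#' @param cmap Native `scs_contact_map`.
#' @param M Number of decoys (>= 2).
#' @param seed Integer seed; same seed, same ensemble.
#' @return List of `M` `scs_contact_map` objects.
#' @export
make_decoys <- function(cmap, M = 1000L, seed = 1L) {
  stopifnot(M >= 2)
  L <- cmap$L; s_min <- cmap$s_min
  npair <- nrow(cmap$pairs)
  # all admissible pairs, used for count restoration
  all_i <- rep(seq_len(L), times = L)
  all_j <- rep(seq_len(L), each = L)
  ok <- all_j - all_i >= s_min
  valid_key <- (all_i[ok] - 1L) * L + all_j[ok]
  .with_seed(seed, lapply(seq_len(M), function(k) {
    s <- 1L + (k - 1L) %% (L - 1L)
    flip <- ((k - 1L) %/% (L - 1L)) %% 2L == 1L
    i2 <- (cmap$pairs[, 1] - 1L + s) %% L + 1L
    j2 <- (cmap$pairs[, 2] - 1L + s) %% L + 1L
    if (flip) { i2 <- L + 1L - i2; j2 <- L + 1L - j2 }
    lo <- pmin(i2, j2); hi <- pmax(i2, j2)
    keep <- hi - lo >= s_min
    key <- unique((lo[keep] - 1L) * L + hi[keep])
    deficit <- npair - length(key)
    if (deficit > 0L) {
      pool <- setdiff(valid_key, key)
      key <- c(key, sample(pool, deficit))
    } else if (deficit < 0L) {
      key <- sample(key, npair)
    }
    i <- (key - 1L) %/% L + 1L
    j <- key - (i - 1L) * L
    structure(list(L = L, s_min = s_min,
                   pairs = cbind(as.integer(i), as.integer(j))),
              class = "scs_contact_map")
  }))
}

#' Random-energy-model free energy of the misfolded ensemble
#'
#' With decoy energies `E_k` (mean `Ebar`, sample variance `s2`, `M` decoys)
#' the REM estimate is `Ebar - s2/(2T) - T log M`, valid above the freezing
#' temperature `T_f = s/sqrt(2 log M)`; below `T_f` the ensemble is frozen in
#' its ground state and the free energy is held at `Ebar - s*sqrt(2 log M)`.
#'
#' @param seq Amino-acid string.
#' @param decoys List of decoy contact maps (from [make_decoys()]).
#' @param potential An `scs_potential`.
#' @param T Thermodynamic temperature (> 0, dimensionless, k_B = 1).
#' @return Scalar free energy.
#' @export
misfold_free_energy <- function(seq, decoys,
                                potential = default_contact_potential(),
                                T = 0.5) {
  if (T <= 0) stop("T must be positive", call. = FALSE)
  if (!length(decoys)) stop("decoys must be nonempty", call. = FALSE)
  E <- vapply(decoys, function(d) native_energy(seq, d, potential), numeric(1))
  .rem_free_energy(mean(E), if (length(E) > 1) var(E) else 0, length(E), T)
}

.rem_free_energy <- function(Ebar, s2, M, T) {
  lnM <- log(M)
  Tf <- sqrt(s2 / (2 * lnM))
  if (T < Tf) Ebar - sqrt(2 * s2 * lnM) else Ebar - s2 / (2 * T) - T * lnM
}

#' Assemble a stability model
#'
#' Bundles everything needed to predict the folding free energy of any
#' sequence threaded on one representative structure: native contact map,
#' contact potential, temperature, unfolding entropy per residue, misfold
#' decoy ensemble and (optionally) the alignment-column-to-residue map.
#'
#' @param cmap Native `scs_contact_map`.
#' @param potential An `scs_potential`.
#' @param T Temperature (> 0), default 0.5.
#' @param s_U Unfolding entropy per residue (> 0), default 0.065.
#' @param M Number of misfold decoys, default 1000.
#' @param seed Seed for the decoy ensemble.
#' @param native_seq Optional native sequence (used as SCS simulation root).
#' @param column_map Optional integer vector mapping alignment columns to
#'   residue indices (`NA` = unmapped column).
#' @return Object of class `scs_stability_model`.
#' @export
stability_model <- function(cmap, potential = default_contact_potential(),
                            T = 0.5, s_U = 0.065, M = 1000L, seed = 1L,
                            native_seq = NULL, column_map = NULL) {
  stopifnot(T > 0, s_U > 0, M >= 2)
  decoys <- make_decoys(cmap, M = M, seed = seed)
  # flat decoy pair arrays for the compiled kernels
  np <- vapply(decoys, function(d) nrow(d$pairs), integer(1))
  di <- unlist(lapply(decoys, function(d) d$pairs[, 1]), use.names = FALSE)
  dj <- unlist(lapply(decoys, function(d) d$pairs[, 2]), use.names = FALSE)
  dk <- rep(seq_along(decoys), times = np)
  structure(list(cmap = cmap, potential = potential, T = T, s_U = s_U,
                 M = as.integer(M), decoys = decoys,
                 decoy_i = as.integer(di), decoy_j = as.integer(dj),
                 decoy_k = as.integer(dk),
                 native_seq = native_seq, column_map = column_map,
                 L = cmap$L),
            class = "scs_stability_model")
}

#' @export
print.scs_stability_model <- function(x, ...) {
  cat(sprintf(paste0("scs_stability_model: L = %d, %d native contacts, ",
                     "%d decoys, T = %g, s_U = %g\n"),
              x$L, nrow(x$cmap$pairs), x$M, x$T, x$s_U))
  invisible(x)
}

#' Folding free energy of a sequence
#'
#' `dG = E_nat - (-T log(exp(-G_unf/T) + exp(-G_misf/T)))` where `E_nat` is
#' the native contact energy, `G_unf = -T s_U L` the unfolded-chain free
#' energy and `G_misf` the REM misfolded-ensemble free energy.  More negative
#' `dG` means more stable.  Gaps/`X` at mapped positions contribute the mean
#' potential value over the 20 amino acids.
#'
#' @param seq Amino-acid string of length `model$L` (already column-mapped).
#' @param model An `scs_stability_model`.
#' @return Object of class `scs_stability_result`: `E_nat`, `G_unf`,
#'   `G_misf`, `dG`.
#' @export
delta_g <- function(seq, model) {
  v <- if (is.character(seq)) .encode_seq(seq) else as.integer(seq)
  if (length(v) != model$L) {
    stop("sequence length ", length(v), " does not match structure L = ",
         model$L, call. = FALSE)
  }
  if (all(v <= 0L)) stop("all positions unmapped or missing", call. = FALSE)
  U <- model$potential$U
  E_nat <- contact_energy_cpp(v, model$cmap$pairs, U)
  E <- decoy_energies_cpp(v, model$decoy_i, model$decoy_j, model$decoy_k,
                          model$M, U)
  dg_from_energies(E_nat, E, model)
}

# shared tail of delta_g, reused by the incremental kernels' R-side checks
dg_from_energies <- function(E_nat, E, model) {
  T <- model$T
  G_unf <- -T * model$s_U * model$L
  G_misf <- .rem_free_energy(mean(E), if (length(E) > 1) var(E) else 0,
                             length(E), T)
  # G_non = -T*log(e^{-G_unf/T} + e^{-G_misf/T}), evaluated via log-sum-exp
  m <- min(G_unf, G_misf)
  G_non <- m - T * log(exp((m - G_unf) / T) + exp((m - G_misf) / T))
  structure(list(E_nat = E_nat, G_unf = G_unf, G_misf = G_misf,
                 dG = E_nat - G_non),
            class = "scs_stability_result")
}

#' @export
print.scs_stability_result <- function(x, ...) {
  cat(sprintf("dG = %.4f (E_nat = %.4f, G_unf = %.4f, G_misf = %.4f)\n",
              x$dG, x$E_nat, x$G_unf, x$G_misf))
  invisible(x)
}
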