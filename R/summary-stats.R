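#' Number of segregating sites
#'
#' Columns with at least two distinct canonical residues; gaps and `X` are
#' treated as missing data.
#'
#' @param aln An [scs_alignment] (n >= 2).
#' @return Integer count.
#' @export
segregating_sites <- function(aln) {
  m <- .alignment_matrix(aln)
  sum(apply(m, 2, function(col) length(unique(col[col > 0L])) >= 2L))
}

#' Moments of pooled Grantham distances
#'
#' Pools `D(a, b)` over every column and every unordered sequence pair whose
#' residues at that column are canonical and different (identical pairs are
#' excluded: the statistic measures the physicochemical size of observed
#' changes, and zero-distance self pairs would swamp it).  Returns the sample
#' mean, sd (n-1 denominator), skewness `m3/m2^(3/2)` and excess kurtosis
#' `m4/m2^2 - 3`.  Pools with fewer than two values return `(mean-or-0, 0,
#' 0, 0)` so every alignment yields a finite vector.
#'
#' @param aln An [scs_alignment].
#' @param table An `scs_grantham` table.
#' @return Named numeric vector `gr_mean`, `gr_sd`, `gr_skew`, `gr_kurt`.
#' @export
grantham_moments <- function(aln, table = grantham_table()) {
  m <- .alignment_matrix(aln)
  n <- nrow(m)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  a <- m[pairs[, 1], , drop = FALSE]
  b <- m[pairs[, 2], , drop = FALSE]
  ok <- a > 0L & b > 0L & a != b
  vals <- table$D[cbind(a[ok], b[ok])]
  if (length(vals) == 0L) {
    return(c(gr_mean = 0, gr_sd = 0, gr_skew = 0, gr_kurt = 0))
  }
  if (length(vals) == 1L) {
    return(c(gr_mean = vals, gr_sd = 0, gr_skew = 0, gr_kurt = 0))
  }
  mu <- mean(vals)
  d <- vals - mu
  m2 <- mean(d^2)
  if (m2 == 0) {
    return(c(gr_mean = mu, gr_sd = 0, gr_skew = 0, gr_kurt = 0))
  }
  c(gr_mean = mu,
    gr_sd = sd(vals),
    gr_skew = mean(d^3) / m2^1.5,
    gr_kurt = mean(d^4) / m2^2 - 3)
}

#' Folding-stability summary of an alignment
#'
#' `dG` of every sequence (already column-mapped to the structure), then the
#' sample mean and sd across sequences.
#'
#' @param aln An [scs_alignment] with `l == stab$L`.
#' @param stab An `scs_stability_model`.
#' @return Named vector `dg_mean`, `dg_sd`.
#' @export
stability_stats <- function(aln, stab) {
  g <- vapply(aln$rows, function(s) delta_g(s, stab)$dG, numeric(1))
  c(dg_mean = mean(g), dg_sd = if (length(g) > 1) sd(g) else 0)
}

#' The seven-statistic summary vector
#'
#' Fixed order: `dg_mean`, `dg_sd`, `seg_sites`, `gr_mean`, `gr_sd`,
#' `gr_skew`, `gr_kurt`.
#'
#' @param aln An [scs_alignment] mapped to the structure.
#' @param stab An `scs_stability_model`.
#' @param table An `scs_grantham` table.
#' @return Named numeric vector of length 7.
#' @export
compute_summary_vector <- function(aln, stab, table = grantham_table()) {
  c(stability_stats(aln, stab),
    seg_sites = segregating_sites(aln),
    grantham_moments(aln, table))
}

#' Mean pairwise sequence identity
#'
#' For each unordered pair: matching canonical positions divided by positions
#' where both residues are canonical; pairs with no comparable positions are
#' skipped.
#'
#' @param aln An [scs_alignment] (n >= 2).
#' @return Fraction in `[0, 1]`.
#' @export
mean_pairwise_identity <- function(aln) {
  m <- .alignment_matrix(aln)
  n <- nrow(m)
  ids <- c()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- m[i, ] > 0L & m[j, ] > 0L
    if (any(comp)) ids <- c(ids, mean(m[i, comp] == m[j, comp]))
  }
  if (!length(ids)) stop("no comparable positions in any pair", call. = FALSE)
  mean(ids)
}

#' Map alignment columns onto structure residues
#'
#' Globally aligns the alignment's consensus (majority canonical residue per
#' column) to the structure's native sequence with BLOSUM62 scoring, keeps
#' only columns matched to a residue, and reports the column-to-residue map
#' plus the dropped columns.
#'
#' @param aln Query [scs_alignment].
#' @param structure An [scs_structure].
#' @param score_floor Minimum alignment score per aligned residue below which
#'   homology is rejected.
#' @return List: `alignment` (trimmed to mapped columns), `threaded` (the
#'   alignment threaded onto all `L` structure residues, unmapped residues
#'   filled with `X` so it can be scored by [delta_g()] directly),
#'   `column_map` (integer vector over the original columns, `NA` = dropped),
#'   `dropped` (data frame of dropped columns and reasons).
#' @export
map_alignment_to_structure <- function(aln, structure, score_floor = -1) {
  cons <- .consensus_sequence(aln)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  pa <- Biostrings::pairwiseAlignment(cons, structure$native_seq,
                                      type = "global",
                                      substitutionMatrix = get("BLOSUM62"),
                                      gapOpening = 10, gapExtension = 0.5)
  if (Biostrings::score(pa) / structure$L < score_floor) {
    stop("homology error: consensus does not align to the structure; ",
         "choose a better template", call. = FALSE)
  }
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  col <- 0L; res <- 0L
  column_map <- rep(NA_integer_, aln$l)
  for (k in seq_along(pat)) {
    if (pat[k] != "-") col <- col + 1L
    if (sub[k] != "-") res <- res + 1L
    if (pat[k] != "-" && sub[k] != "-") column_map[col] <- res
  }
  keep <- which(!is.na(column_map))
  if (!length(keep)) stop("homology error: no columns map to the structure",
                          call. = FALSE)
  trimmed <- scs_alignment(aln$ids,
                           vapply(aln$rows, function(s) {
                             paste(strsplit(s, "")[[1]][keep], collapse = "")
                           }, character(1), USE.NAMES = FALSE))
  threaded <- scs_alignment(aln$ids, vapply(aln$rows, function(s) {
    out <- rep("X", structure$L)
    out[column_map[keep]] <- strsplit(s, "")[[1]][keep]
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE))
  dropped <- setdiff(seq_len(aln$l), keep)
  list(alignment = trimmed, threaded = threaded, column_map = column_map,
       dropped = data.frame(column = dropped,
                            reason = rep("no homologous residue",
                                         length(dropped))))
}

.consensus_sequence <- function(aln) {
  m <- .alignment_matrix(aln)
  paste(apply(m, 2, function(col) {
    col <- col[col > 0L]
    if (!length(col)) return("A")   # fully-missing column: placeholder
    AA_ALPHABET20[as.integer(names(which.max(table(col))))]
  }), collapse = "")
}
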