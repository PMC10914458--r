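#' Bundled empirical amino-acid substitution models
#'
#' Names accepted by [load_empirical_model()].  Matrices are the canonical
#' published versions, taken at run time from \pkg{phangorn}.
#' @export
EMPIRICAL_MODELS <- c("Blosum62", "CpRev", "Dayhoff", "DayhoffDCMUT", "HIVb",
                      "HIVw", "JTT", "JonesDCMUT", "LG", "Mtart", "Mtmam",
                      "Mtrev24", "RtRev", "VT", "WAG")

# map bundled names to phangorn object names
.PHANGORN_NAME <- c(Blosum62 = "Blosum62", CpRev = "cpREV", Dayhoff = "Dayhoff",
                    DayhoffDCMUT = "Dayhoff_DCMut", HIVb = "HIVb", HIVw = "HIVw",
                    JTT = "JTT", JonesDCMUT = "JTT_DCMut", LG = "LG",
                    Mtart = "mtArt", Mtmam = "mtmam", Mtrev24 = "mtREV24",
                    RtRev = "RtREV", VT = "VT", WAG = "WAG")

.empirical_model <- function(name, S, pi, gamma_shape = NULL, p_inv = 0) {
  dimnames(S) <- list(AA_ALPHABET20, AA_ALPHABET20)
  names(pi) <- AA_ALPHABET20
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-12))) {
    stop("format error: exchangeability matrix is not symmetric", call. = FALSE)
  }
  if (any(S < 0) || any(diag(S) != 0)) {
    stop("format error: exchangeabilities must be nonnegative with zero diagonal",
         call. = FALSE)
  }
  if (abs(sum(pi) - 1) > 1e-4) {
    stop("format error: frequencies sum to ", sum(pi), call. = FALSE)
  }
  pi <- pi / sum(pi)
  if (any(pi <= 0)) stop("format error: zero or negative frequency", call. = FALSE)
  if (!is.null(gamma_shape) && gamma_shape <= 0) {
    stop("gamma_shape must be positive", call. = FALSE)
  }
  if (p_inv < 0 || p_inv >= 1) stop("p_inv must be in [0,1)", call. = FALSE)
  structure(list(name = name, S = S, pi = pi,
                 gamma_shape = gamma_shape, p_inv = p_inv),
            class = "scs_empirical_model")
}

#' @export
print.scs_empirical_model <- function(x, ...) {
  cat(sprintf("empirical model '%s' (20x20 exchangeabilities + frequencies)\n",
              x$name))
  invisible(x)
}

# expand a 190-vector lower triangle in PAML (Dayhoff) row order into a
# symmetric 20x20 matrix in the package's alphabetical order
.expand_paml_triangle <- function(rates, freqs) {
  S <- matrix(0, 20, 20, dimnames = list(.PAML_ORDER, .PAML_ORDER))
  k <- 1L
  for (i in 2:20) for (j in 1:(i - 1L)) {
    S[i, j] <- S[j, i] <- rates[k]
    k <- k + 1L
  }
  names(freqs) <- .PAML_ORDER
  list(S = S[AA_ALPHABET20, AA_ALPHABET20], pi = freqs[AA_ALPHABET20])
}

#' Load an empirical substitution model
#'
#' @param name_or_path One of [EMPIRICAL_MODELS] (case as listed) or the path
#'   to a PAML-style `.dat` file (lower-triangle exchangeabilities followed by
#'   20 equilibrium frequencies, Dayhoff row order).
#' @param gamma_shape Optional shape of the Gamma distribution of among-site
#'   rate variation (mean fixed at 1); `NULL` disables rate variation.
#' @param p_inv Proportion of invariable sites in `[0, 1)`.
#' @return An object of class `scs_empirical_model` with fields `name`, `S`
#'   (symmetric 20x20 exchangeabilities, zero diagonal), `pi` (frequencies on
#'   the simplex), `gamma_shape`, `p_inv`.  Index order is alphabetical by
#'   one-letter code everywhere.
#' @export
load_empirical_model <- function(name_or_path, gamma_shape = NULL, p_inv = 0) {
  if (name_or_path %in% EMPIRICAL_MODELS) {
    obj <- get(paste0(".", .PHANGORN_NAME[[name_or_path]]),
               envir = environment(phangorn::pml))
    ex <- .expand_paml_triangle(obj$Q, unname(obj$bf))
    return(.empirical_model(name_or_path, ex$S, ex$pi, gamma_shape, p_inv))
  }
  if (!file.exists(name_or_path)) {
    stop("lookup error: unknown model '", name_or_path,
         "'; valid names: ", paste(EMPIRICAL_MODELS, collapse = ", "),
         call. = FALSE)
  }
  read_paml_dat(name_or_path, gamma_shape = gamma_shape, p_inv = p_inv)
}

#' Read a PAML-style .dat substitution model file
#'
#' Expects 19 lines of lower-triangle exchangeabilities followed by the 20
#' equilibrium frequencies (whitespace separated, Dayhoff row order);
#' comments after the frequencies are ignored.
#'
#' @inheritParams load_empirical_model
#' @param path Path to the `.dat` file.
#' @return An `scs_empirical_model`.
#' @export
read_paml_dat <- function(path, gamma_shape = NULL, p_inv = 0) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  vals <- suppressWarnings(as.numeric(toks))
  vals <- vals[!is.na(vals)]
  if (length(vals) < 210) {
    stop("format error: expected 190 rates + 20 frequencies in ", path,
         call. = FALSE)
  }
  ex <- .expand_paml_triangle(vals[1:190], vals[191:210])
  .empirical_model(basename(path), ex$S, ex$pi, gamma_shape, p_inv)
}

#' Write a model as a PAML-style .dat file
#'
#' Inverse of [read_paml_dat()]; numbers are printed with full precision so a
#' write-then-read round trip is exact.
#'
#' @param model An `scs_empirical_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paml_dat <- function(model, path) {
  S <- model$S[.PAML_ORDER, .PAML_ORDER]
  pi <- model$pi[.PAML_ORDER]
  lines <- vapply(2:20, function(i) {
    paste(formatC(S[i, 1:(i - 1L)], format = "g", digits = 17),
          collapse = " ")
  }, character(1))
  writeLines(c(lines, "",
               paste(formatC(pi, format = "g", digits = 17), collapse = " ")),
             path)
  invisible(path)
}

#' Build the scaled generator matrix Q of an empirical model
#'
#' `Q[i,j] = S[i,j] * pi[j]` off-diagonal, diagonal set so rows sum to zero,
#' then globally rescaled so the expected substitution rate at equilibrium,
#' `-sum_i pi_i Q_ii`, is exactly 1 (one expected substitution per site per
#' unit branch length).
#'
#' @param model An `scs_empirical_model`.
#' @return A 20x20 generator matrix.
#' @export
build_rate_matrix <- function(model) {
  Q <- model$S * rep(model$pi, each = 20)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  rate <- -sum(model$pi * diag(Q))
  Q / rate
}
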