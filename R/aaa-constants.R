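#' Canonical amino-acid alphabet
#'
#' Single-letter codes in the fixed index order used by every matrix in the
#' package: alphabetical by code (A, C, D, ..., Y).  One convention everywhere
#' avoids transposition bugs between exchangeability, Grantham and contact
#' matrices.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# PAML/phangorn row order (Dayhoff order), used when reading .dat files and
# phangorn model objects.
.PAML_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.aa_index <- function(x) {
  i <- match(x, AA_ALPHABET20)
  if (anyNA(i)) {
    stop("non-canonical amino acid symbol: ",
         paste(unique(x[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  i
}

# integer encoding of a sequence string; gaps '-' -> 0, 'X' -> -1
.encode_seq <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  out <- match(ch, AA_ALPHABET20)
  out[ch == "-"] <- 0L
  out[ch == "X"] <- -1L
  if (anyNA(out)) stop("illegal character in sequence: ",
                       paste(unique(ch[is.na(out)]), collapse = ", "),
                       call. = FALSE)
  as.integer(out)
}

.decode_seq <- function(v) {
  ch <- character(length(v))
  ch[v > 0] <- AA_ALPHABET20[v[v > 0]]
  ch[v == 0] <- "-"
  ch[v < 0] <- "X"
  paste(ch, collapse = "")
}
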