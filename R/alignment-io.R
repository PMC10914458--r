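#' Alignment container
#'
#' A multiple protein-sequence alignment: unique ids and equal-length rows
#' over the 20 canonical amino acids plus `-` (gap) and `X` (unknown).
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param rows Character vector of aligned sequences, all the same length.
#' @param require_query If `TRUE`, insist on at least two sequences (a query
#'   alignment); single-sequence objects are allowed internally.
#' @return An object of class `scs_alignment` with elements `ids`, `rows`,
#'   `n` (sequence count) and `l` (alignment length in columns).
#' @export
scs_alignment <- function(ids, rows, require_query = FALSE) {
  ids <- as.character(ids)
  rows <- toupper(as.character(rows))
  rows <- gsub(".", "-", rows, fixed = TRUE)
  if (length(ids) != length(rows)) {
    stop("ids and rows differ in length", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("sequence ids are not unique", call. = FALSE)
  ll <- nchar(rows)
  if (length(unique(ll)) != 1L) {
    stop("alignment error: unequal row lengths (",
         paste(unique(ll), collapse = ", "), ")", call. = FALSE)
  }
  if (ll[1] < 1L) stop("alignment error: zero-length rows", call. = FALSE)
  if (require_query && length(rows) < 2L) {
    stop("query error: an alignment needs at least 2 sequences", call. = FALSE)
  }
  bad <- regexpr(sprintf("[^%sX-]", paste(AA_ALPHABET20, collapse = "")), rows)
  if (any(bad > 0)) {
    r <- which(bad > 0)[1]
    stop(sprintf("format error: illegal character in row %d ('%s') column %d",
                 r, ids[r], bad[r]), call. = FALSE)
  }
  structure(list(ids = ids, rows = rows, n = length(rows), l = ll[1]),
            class = "scs_alignment")
}

#' @export
print.scs_alignment <- function(x, ...) {
  cat(sprintf("scs_alignment: %d sequences x %d columns\n", x$n, x$l))
  show <- head(seq_len(x$n), 5L)
  for (i in show) {
    cat(sprintf("  %-12s %s%s\n", x$ids[i],
                substr(x$rows[i], 1, min(50, x$l)),
                if (x$l > 50) "..." else ""))
  }
  if (x$n > 5L) cat(sprintf("  ... %d more\n", x$n - 5L))
  invisible(x)
}

# integer matrix (n x l) view; gaps 0, X -1
.alignment_matrix <- function(aln) {
  do.call(rbind, lapply(aln$rows, .encode_seq))
}

.guess_format <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("format error: empty file", call. = FALSE)
  if (startsWith(trimws(first), ">")) "fasta" else "phylip"
}

#' Read a protein alignment from FASTA or PHYLIP
#'
#' Characters are upper-cased and `.` is normalised to `-`.  Sequence order is
#' preserved.  PHYLIP input may be sequential or interleaved.
#'
#' @param path Path to an alignment file.
#' @param format `"fasta"`, `"phylip"` or `"auto"` (sniff the first line).
#' @return An [scs_alignment] with at least two sequences.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- .guess_format(path)
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    aln <- scs_alignment(names(ss), as.character(ss), require_query = TRUE)
    return(aln)
  }
  .read_phylip(path)
}

.read_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 2L || anyNA(suppressWarnings(as.integer(hdr[1:2])))) {
    stop("format error: bad PHYLIP header", call. = FALSE)
  }
  n <- as.integer(hdr[1]); l <- as.integer(hdr[2])
  body <- lines[-1]
  if (length(body) < n) stop("format error: truncated PHYLIP file", call. = FALSE)
  split1 <- function(x) {
    m <- regexpr("\\s", x)
    if (m < 0) c(x, "") else c(substr(x, 1, m - 1L),
                               gsub("\\s", "", substr(x, m + 1L, nchar(x))))
  }
  first <- t(vapply(body[seq_len(n)], split1, character(2)))
  ids <- first[, 1]; seqs <- first[, 2]
  extra <- body[-seq_len(n)]
  k <- 0L
  for (ln in extra) {           # interleaved continuation blocks
    seqs[k + 1L] <- paste0(seqs[k + 1L], gsub("\\s", "", ln))
    k <- (k + 1L) %% n
  }
  if (any(nchar(seqs) != l)) {
    stop("alignment error: PHYLIP rows do not match stated length ", l,
         call. = FALSE)
  }
  scs_alignment(ids, seqs, require_query = TRUE)
}

#' Write an alignment to FASTA or sequential PHYLIP
#'
#' @param aln An [scs_alignment].
#' @param path Output path.
#' @param format `"fasta"` or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "fasta") {
    writeLines(as.vector(rbind(paste0(">", aln$ids), aln$rows)), path)
  } else {
    writeLines(c(sprintf("%d %d", aln$n, aln$l),
                 sprintf("%-10s  %s", aln$ids, aln$rows)), path)
  }
  invisible(path)
}
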