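.AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
             MSE = "M", SEC = "C", PYL = "K")

#' Protein structure container
#'
#' @param coords List of numeric matrices (one per residue, heavy-atom rows,
#'   columns x/y/z); a single row per residue is the C-alpha fallback.
#' @param native_seq Amino-acid string, one letter per residue.
#' @param chain Chain identifier.
#' @param resno Residue numbering from the source file.
#' @return Object of class `scs_structure` with `L` residues.
#' @export
scs_structure <- function(coords, native_seq, chain = "A", resno = NULL) {
  L <- length(coords)
  if (L < 2L) stop("structure must have at least 2 residues", call. = FALSE)
  if (nchar(native_seq) != L) {
    stop("native_seq length (", nchar(native_seq),
         ") does not match residue count (", L, ")", call. = FALSE)
  }
  if (!all(vapply(coords, function(m) all(is.finite(m)), logical(1)))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  if (is.null(resno)) resno <- seq_len(L)
  structure(list(coords = coords, native_seq = toupper(native_seq),
                 chain = chain, resno = resno, L = L),
            class = "scs_structure")
}

#' @export
print.scs_structure <- function(x, ...) {
  cat(sprintf("scs_structure: %d residues, chain %s\n", x$L, x$chain))
  invisible(x)
}

#' Read a protein structure from a PDB file
#'
#' Minimal fixed-width ATOM-record reader: first model only, one chain
#' (default: first chain seen), HETATM and hydrogens ignored, altLoc other
#' than ' '/'A' skipped.
#'
#' @param path Path to a PDB file.
#' @param chain Chain id to keep, or `NULL` for the first chain encountered.
#' @return An [scs_structure].
#' @export
read_pdb <- function(path, chain = NULL) {
  lines <- readLines(path, warn = FALSE)
  end <- which(startsWith(lines, "ENDMDL"))
  if (length(end)) lines <- lines[seq_len(end[1] - 1L)]
  at <- lines[startsWith(lines, "ATOM  ")]
  if (!length(at)) stop("format error: no ATOM records in ", path, call. = FALSE)
  f <- function(a, b) trimws(substr(at, a, b))
  name <- f(13, 16); alt <- f(17, 17); resn <- f(18, 20)
  ch <- f(22, 22); resi <- f(23, 26); icode <- f(27, 27)
  keep <- alt %in% c("", "A") & !startsWith(name, "H") &
    !grepl("^[0-9]H", name) & resn %in% names(.AA3TO1)
  if (is.null(chain)) chain <- ch[keep][1]
  keep <- keep & ch == chain
  if (!any(keep)) stop("no residues found for chain ", chain, call. = FALSE)
  at <- at[keep]; name <- name[keep]; resn <- resn[keep]
  resi <- resi[keep]; icode <- icode[keep]
  xyz <- cbind(as.numeric(substr(at, 31, 38)),
               as.numeric(substr(at, 39, 46)),
               as.numeric(substr(at, 47, 54)))
  key <- paste(resi, icode)
  ord <- !duplicated(key)
  coords <- split.data.frame(xyz, factor(key, levels = key[ord]))
  seq1 <- paste(.AA3TO1[resn[ord]], collapse = "")
  scs_structure(lapply(coords, as.matrix), seq1, chain = chain,
                resno = as.integer(resi[ord]))
}

#' Write a C-alpha trace as a PDB file
#'
#' One ATOM record per residue using the first coordinate row of each; enough
#' for round-tripping synthetic fixture structures.
#'
#' @param structure An [scs_structure].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  aa1 <- strsplit(structure$native_seq, "")[[1]]
  to3 <- setNames(names(.AA3TO1)[1:20], unname(.AA3TO1[1:20]))
  lines <- vapply(seq_len(structure$L), function(i) {
    p <- structure$coords[[i]][1, ]
    sprintf("ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, to3[[aa1[i]]], structure$chain, structure$resno[i],
            p[1], p[2], p[3])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Build a residue contact map
#'
#' Residues `i`, `j` are in contact when `|i - j| >= s_min` and the minimum
#' heavy-atom inter-residue distance is at most `cutoff` Angstroms.
#'
#' @param structure An [scs_structure].
#' @param cutoff Distance cutoff in Angstroms (default 4.5).
#' @param s_min Minimum sequence separation (default 3).
#' @return Object of class `scs_contact_map`: `L`, `s_min` and `pairs`, a
#'   two-column integer matrix with `i < j`.
#' @export
build_contact_map <- function(structure, cutoff = 4.5, s_min = 3L) {
  stopifnot(cutoff > 0, s_min >= 1)
  L <- structure$L
  if (L < 2L) stop("structure must have at least 2 residues", call. = FALSE)
  cent <- t(vapply(structure$coords, colMeans, numeric(3)))
  rad <- vapply(structure$coords, function(m) {
    sqrt(max(rowSums((m - rep(colMeans(m), each = nrow(m)))^2)))
  }, numeric(1))
  pairs <- matrix(0L, 0L, 2L)
  for (i in seq_len(L - s_min)) {
    js <- (i + s_min):L
    # bounding-sphere prefilter before the exact atom-atom scan
    dc <- sqrt(colSums((t(cent[js, , drop = FALSE]) - cent[i, ])^2))
    js <- js[dc <= cutoff + rad[i] + rad[js]]
    for (j in js) {
      a <- structure$coords[[i]]; b <- structure$coords[[j]]
      d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
      if (min(d2) <= cutoff^2) pairs <- rbind(pairs, c(i, j))
    }
  }
  structure(list(L = L, s_min = as.integer(s_min), pairs = pairs),
            class = "scs_contact_map")
}

#' @export
print.scs_contact_map <- function(x, ...) {
  cat(sprintf("scs_contact_map: L = %d, %d contacts (s_min = %d)\n",
              x$L, nrow(x$pairs), x$s_min))
  invisible(x)
}
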