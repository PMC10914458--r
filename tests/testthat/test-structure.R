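two_residue_structure <- function(d) {
  scs_structure(list(matrix(c(0, 0, 0), 1), matrix(c(d, 0, 0), 1)), "AC")
}

test_that("build_contact_map applies cutoff and separation rules", {
  cm <- build_contact_map(two_residue_structure(3.0), cutoff = 4.5, s_min = 1)
  expect_equal(nrow(cm$pairs), 1L)
  cm2 <- build_contact_map(two_residue_structure(50), cutoff = 4.5, s_min = 1)
  expect_equal(nrow(cm2$pairs), 0L)
  # s_min excludes the sequential neighbour pair
  cm3 <- build_contact_map(two_residue_structure(3.0), cutoff = 4.5, s_min = 2)
  expect_equal(nrow(cm3$pairs), 0L)
})

test_that("build_contact_map equals an all-pairs brute-force scan", {
  withr::with_seed(3, {
    coords <- lapply(1:10, function(i) {
      matrix(rnorm(3 * sample(1:4, 1), sd = 4), ncol = 3)
    })
  })
  st <- scs_structure(coords, "ACDEFGHIKL")
  cm <- build_contact_map(st, cutoff = 6, s_min = 2)
  brute <- NULL
  for (i in 1:9) for (j in (i + 1):10) {
    if (j - i < 2) next
    mind <- Inf
    for (a in seq_len(nrow(coords[[i]]))) for (b in seq_len(nrow(coords[[j]]))) {
      mind <- min(mind, sqrt(sum((coords[[i]][a, ] - coords[[j]][b, ])^2)))
    }
    if (mind <= 6) brute <- rbind(brute, c(i, j))
  }
  expect_equal(cm$pairs, brute)
})

test_that("PDB reader parses fixed-width records, skips HETATM/other chains", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HEADER    TEST",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.400   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       4.100   1.000   0.000  1.00  0.00           C",
    "HETATM    4  O   HOH A  90      99.000  99.000  99.000  1.00  0.00           O",
    "ATOM      5  CA  TRP B   1      50.000   0.000   0.000  1.00  0.00           C",
    "ATOM      6  CA  LEU B   2      54.000   0.000   0.000  1.00  0.00           C",
    "END"), pdb)
  st <- read_pdb(pdb)                 # first chain = A
  expect_equal(st$native_seq, "AG")
  expect_equal(nrow(st$coords[[1]]), 2L)   # N + CA
  stB <- read_pdb(pdb, chain = "B")
  expect_equal(stB$native_seq, "WL")
  expect_equal(stB$coords[[1]][1, 1], 50)
})

test_that("write_pdb/read_pdb round-trips a C-alpha fixture", {
  fx <- small_fixture()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(fx$structure, f)
  back <- read_pdb(f)
  expect_equal(back$native_seq, fx$structure$native_seq)
  expect_equal(back$L, fx$structure$L)
  d <- max(abs(do.call(rbind, back$coords) - do.call(rbind, fx$structure$coords)))
  expect_lt(d, 1e-3)                  # PDB format has 3 decimals
})

test_that("native_energy matches the brute-force double loop", {
  U <- default_contact_potential()
  cm_empty <- structure(list(L = 5L, s_min = 1L,
                             pairs = matrix(0L, 0, 2)),
                        class = "scs_contact_map")
  expect_equal(native_energy("ACDEF", cm_empty, U), 0)
  cm1 <- structure(list(L = 2L, s_min = 1L,
                        pairs = matrix(c(1L, 2L), 1)),
                   class = "scs_contact_map")
  expect_equal(native_energy("AC", cm1, U), U$U["A", "C"])

  stab <- small_stab()
  withr::with_seed(11, {
    for (rep in 1:100) {
      s <- random_seq(stab$L)
      v <- match(strsplit(s, "")[[1]], AA_ALPHABET20)
      terms <- numeric(nrow(stab$cmap$pairs))
      for (k in seq_len(nrow(stab$cmap$pairs))) {
        terms[k] <- U$U[v[stab$cmap$pairs[k, 1]], v[stab$cmap$pairs[k, 2]]]
      }
      expect_identical(native_energy(s, stab$cmap, U), sum(terms))
    }
  })
})

test_that("make_decoys preserves counts, avoids the native map, is seeded", {
  stab <- small_stab()
  cm <- stab$cmap
  d1 <- make_decoys(cm, M = 10, seed = 3)
  d2 <- make_decoys(cm, M = 10, seed = 3)
  expect_identical(d1, d2)
  native_key <- sort((cm$pairs[, 1] - 1) * cm$L + cm$pairs[, 2])
  for (d in d1) {
    expect_equal(nrow(d$pairs), nrow(cm$pairs))
    expect_true(all(d$pairs[, 2] - d$pairs[, 1] >= cm$s_min))
    expect_false(identical(sort((d$pairs[, 1] - 1) * cm$L + d$pairs[, 2]),
                           native_key))
  }
})

test_that("misfold_free_energy implements the clamped REM", {
  U <- default_contact_potential()
  # identical decoys => sigma = 0 => G = Ebar - T log M at any T
  cm1 <- structure(list(L = 6L, s_min = 3L, pairs = matrix(c(1L, 5L), 1)),
                   class = "scs_contact_map")
  decs <- rep(list(cm1), 10)
  g <- misfold_free_energy("ACDEFG", decs, U, T = 1)
  expect_equal(g, U$U["A", "F"] - log(10), tolerance = 1e-12)

  # random instance vs an independent formula evaluation
  stab <- small_stab()
  withr::with_seed(4, s <- random_seq(stab$L))
  E <- vapply(stab$decoys, function(d) native_energy(s, d, U), numeric(1))
  Ebar <- mean(E); s2 <- var(E); M <- length(E)
  Tf <- sqrt(s2 / (2 * log(M)))
  for (T in c(Tf * 0.5, Tf * 1.5, 5)) {
    want <- if (T < Tf) Ebar - sqrt(2 * s2 * log(M))
            else Ebar - s2 / (2 * T) - T * log(M)
    expect_equal(misfold_free_energy(s, stab$decoys, U, T), want,
                 tolerance = 1e-9)
  }
  # clamp engages below Tf and G is non-increasing in T overall
  Ts <- seq(Tf / 4, 4 * Tf, length.out = 40)
  gs <- vapply(Ts, function(T) misfold_free_energy(s, stab$decoys, U, T),
               numeric(1))
  expect_true(all(diff(gs) <= 1e-9))
  expect_equal(misfold_free_energy(s, stab$decoys, U, Tf / 4),
               Ebar - sqrt(2 * s2 * log(M)))
  expect_error(misfold_free_energy(s, stab$decoys, U, T = 0), "positive")
})

test_that("delta_g closed form, determinism and decoy-order invariance", {
  stab <- small_stab()
  # zero potential: dG = T log(exp(s_U L) + M)
  z <- stab
  z$potential <- contact_potential(matrix(0, 20, 20))
  withr::with_seed(5, s <- random_seq(stab$L))
  r <- delta_g(s, z)
  expect_equal(r$E_nat, 0)
  expect_equal(r$G_misf, -z$T * log(z$M))
  expect_equal(r$dG, z$T * log(exp(z$s_U * z$L) + z$M), tolerance = 1e-9)
  expect_gt(r$dG, 0)

  # permuting the decoy ensemble leaves the result unchanged
  perm <- stab
  withr::with_seed(6, p <- sample(stab$M))
  perm$decoy_k <- match(stab$decoy_k, p)
  r1 <- delta_g(s, stab)
  r2 <- delta_g(s, perm)
  expect_equal(r1$dG, r2$dG, tolerance = 1e-12)
  expect_identical(delta_g(s, stab), delta_g(s, stab))

  # dG satisfies its defining identity
  lhs <- r1$dG
  rhs <- r1$E_nat + stab$T * log(exp(-r1$G_unf / stab$T) +
                                 exp(-r1$G_misf / stab$T))
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("adding a favourable native contact decreases dG", {
  stab <- small_stab()
  withr::with_seed(8, s <- random_seq(stab$L))
  base <- delta_g(s, stab)$dG
  # add one strongly favourable contact to the native map only
  # find an absent admissible pair whose potential term is favourable, then
  # add it to the native map only (potential and decoys untouched)
  v <- scsabc:::.encode_seq(s)
  native_key <- (stab$cmap$pairs[, 1] - 1) * stab$L + stab$cmap$pairs[, 2]
  U <- stab$potential$U
  ij <- NULL
  for (i in seq_len(stab$L)) {
    for (j in seq_len(stab$L)) {
      if (j - i >= stab$cmap$s_min &&
          !((i - 1) * stab$L + j) %in% native_key &&
          U[v[i], v[j]] < -0.1) {
        ij <- c(i, j); break
      }
    }
    if (!is.null(ij)) break
  }
  expect_false(is.null(ij))
  aug <- stab
  aug$cmap$pairs <- rbind(stab$cmap$pairs, ij)
  base2 <- delta_g(s, aug)$dG
  expect_lt(base2, base)
})

test_that("map_alignment_to_structure recovers known correspondences", {
  fx <- small_fixture()
  nat <- fx$structure$native_seq
  aln <- scs_alignment(c("a", "b"), c(nat, nat))
  mp <- map_alignment_to_structure(aln, fx$structure)
  expect_equal(mp$column_map, seq_len(nchar(nat)))
  expect_equal(nrow(mp$dropped), 0L)

  # 5 extra N-terminal columns are dropped
  aln2 <- scs_alignment(c("a", "b"), paste0("WWWWW", c(nat, nat)))
  mp2 <- map_alignment_to_structure(aln2, fx$structure)
  expect_equal(sort(mp2$dropped$column), 1:5)
  expect_equal(mp2$alignment$l, nchar(nat))

  # structure missing a known internal block: those columns must drop
  keep <- setdiff(seq_len(fx$structure$L), 11:18)
  sub <- scs_structure(fx$structure$coords[keep],
                       paste(strsplit(nat, "")[[1]][keep], collapse = ""))
  mp3 <- map_alignment_to_structure(aln, sub)
  # exactly 8 columns drop and every mapped column lands on the residue with
  # the same amino acid (equal-score gap placements at block edges are
  # acceptable, so the assertion is on correctness, not on one optimum)
  expect_equal(sum(is.na(mp3$column_map)), 8L)
  mapped <- which(!is.na(mp3$column_map))
  natv <- strsplit(nat, "")[[1]]
  subv <- strsplit(sub$native_seq, "")[[1]]
  expect_true(all(natv[mapped] == subv[mp3$column_map[mapped]]))
  expect_true(all(diff(mp3$column_map[mapped]) > 0))   # monotone injection
})
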