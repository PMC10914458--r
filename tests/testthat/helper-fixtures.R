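# shared fixtures, built once per test run and cached
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# small, fast stability model on a 30-residue snake chain (60 decoys)
small_stab <- function() {
  cached("small_stab", {
    fx <- generate_fixture(seed = 7, L = 30, n = 4, M = 60, greedy_sweeps = 1)
    fx$stab
  })
}

small_fixture <- function() {
  cached("small_fixture",
         generate_fixture(seed = 7, L = 30, n = 6, M = 60, greedy_sweeps = 1))
}

# the scaled-down validation fixture used by the acceptance tests
accept_fixture <- function() {
  cached("accept_fixture", generate_fixture(seed = 42, L = 60, n = 12,
                                            M = 1000))
}

# random simulation table with continuous statistics (no signal unless asked)
random_sim_table <- function(n_per_model, labels = c("A", "B", "C"),
                             shift = 0) {
  n <- n_per_model * length(labels)
  stats <- matrix(rnorm(n * 7), n, 7)
  model <- rep(labels, each = n_per_model)
  for (i in seq_along(labels)) {
    stats[model == labels[i], ] <-
      stats[model == labels[i], ] + shift * (i - 1)
  }
  colnames(stats) <- c("dg_mean", "dg_sd", "seg_sites", "gr_mean", "gr_sd",
                       "gr_skew", "gr_kurt")
  simulation_table(model, runif(n, 0, 100), stats)
}

random_alignment <- function(n, l, gap_frac = 0) {
  rows <- vapply(seq_len(n), function(i) {
    ch <- sample(AA_ALPHABET20, l, replace = TRUE)
    if (gap_frac > 0) {
      g <- runif(l) < gap_frac
      ch[g] <- "-"
    }
    paste(ch, collapse = "")
  }, character(1))
  scs_alignment(paste0("s", seq_len(n)), rows)
}

random_seq <- function(l) paste(sample(AA_ALPHABET20, l, TRUE), collapse = "")
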