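#' Model specifications for a comparison run
#'
#' @param name Bundled empirical model name or path to a PAML `.dat` file.
#' @param gamma_shape,p_inv Among-site rate variation for the empirical model.
#' @return A model-spec list consumed by [run_pipeline()].
#' @export
model_empirical <- function(name, gamma_shape = NULL, p_inv = 0) {
  list(kind = "empirical", label = name,
       model = load_empirical_model(name, gamma_shape, p_inv))
}

#' @rdname model_empirical
#' @param label Row label in the simulation table (default `"Neutral"`).
#' @param ... Passed to [scs_params()].
#' @export
model_neutral <- function(label = "Neutral", ...) {
  list(kind = "scs", label = label, params = scs_params("neutral", ...))
}

#' @rdname model_empirical
#' @export
model_fitness <- function(label = "Fitness", ...) {
  list(kind = "scs", label = label, params = scs_params("fitness", ...))
}

#' Run configuration
#'
#' @param models List of model specs ([model_empirical()], [model_neutral()],
#'   [model_fitness()]); at least two.
#' @param stab An `scs_stability_model` (required; also used for the
#'   stability statistics of empirical-model simulations so query and
#'   simulations are summarised identically).
#' @param n_tips Sample size for coalescent histories.
#' @param N Population size, default 1000.
#' @param growth_rate Exponential growth rate per generation.
#' @param theta_prior `c(low, high)` of the uniform prior on
#'   `theta = 4 N mu l`, default `c(0, 500)`.
#' @param user_tree Optional \code{phylo} in substitutions/site; when given,
#'   every simulation reuses it (coalescent mode redraws a tree per
#'   simulation).
#' @param n_sims_per_model Simulations per model (default 10000, the scale
#'   used for real analyses; tests use smaller values).
#' @param abc An `scs_abc_config`.
#' @param seed Master seed; per-simulation substreams are derived from it so
#'   results do not depend on the worker count.
#' @param workers Parallel workers (forked; 1 = serial).
#' @return An `scs_run_config`.
#' @export
run_config <- function(models, stab, n_tips, N = 1000, growth_rate = 0,
                       theta_prior = c(0, 500), user_tree = NULL,
                       n_sims_per_model = 10000L,
                       abc = abc_config("rejection", 0.005),
                       seed = 1L, workers = 1L) {
  stopifnot(length(models) >= 2, n_sims_per_model >= 100,
            theta_prior[1] >= 0, theta_prior[1] < theta_prior[2])
  labs <- vapply(models, `[[`, character(1), "label")
  if (anyDuplicated(labs)) stop("duplicate model labels", call. = FALSE)
  structure(list(models = models, stab = stab, n_tips = n_tips, N = N,
                 growth_rate = growth_rate, theta_prior = theta_prior,
                 user_tree = user_tree,
                 n_sims_per_model = as.integer(n_sims_per_model),
                 abc = abc, seed = as.integer(seed),
                 workers = as.integer(workers)),
            class = "scs_run_config")
}

# deterministic per-simulation seed substream (kept below 2^31)
.sim_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 16807) %%
               2147483629) + 1L
}

# one simulation: draw theta, tree, evolve, summarise
.simulate_one <- function(spec, cfg, index, gr_table) {
  seed <- .sim_seed(cfg$seed, index)
  .with_seed(seed, {
    theta <- runif(1, cfg$theta_prior[1], cfg$theta_prior[2])
    l <- cfg$stab$L
    tree <- if (is.null(cfg$user_tree)) {
      scale_tree(simulate_coalescent(cfg$n_tips, cfg$N, cfg$growth_rate),
                 theta, cfg$N, l)
    } else {
      # user tree: identical history for all simulations, lengths already in
      # substitutions/site; the theta draw is recorded but has no effect
      cfg$user_tree
    }
    aln <- if (spec$kind == "empirical") {
      evolve_empirical(tree, spec$model, l = l)
    } else {
      evolve_scs(tree, spec$params, cfg$stab)
    }
    c(theta = theta, compute_summary_vector(aln, cfg$stab, gr_table))
  })
}

#' Simulate the training table for a configuration
#'
#' Equal numbers of simulations per model; per-simulation seeds derive from
#' the master seed, so the result is identical for any worker count.
#'
#' @param cfg An `scs_run_config`.
#' @param n_per_model Override of `cfg$n_sims_per_model` (used by pilots).
#' @return A `scs_sim_table`.
#' @export
simulate_table <- function(cfg, n_per_model = NULL) {
  n <- if (is.null(n_per_model)) cfg$n_sims_per_model else as.integer(n_per_model)
  gr <- grantham_table()
  jobs <- expand.grid(model = seq_along(cfg$models), rep = seq_len(n))
  jobs <- jobs[order(jobs$model, jobs$rep), ]
  run1 <- function(j) {
    spec <- cfg$models[[jobs$model[j]]]
    .simulate_one(spec, cfg, index = (jobs$model[j] - 1L) * n + jobs$rep[j],
                  gr_table = gr)
  }
  res <- if (cfg$workers > 1L) {
    parallel::mclapply(seq_len(nrow(jobs)), run1, mc.cores = cfg$workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(nrow(jobs)), run1)
  }
  M <- do.call(rbind, res)
  labs <- vapply(cfg$models, `[[`, character(1), "label")
  simulation_table(labs[jobs$model], M[, "theta"],
                   M[, .STAT_NAMES, drop = FALSE])
}

#' Run the whole model-selection pipeline
#'
#' Read/trim happens upstream (see [map_alignment_to_structure()]); this
#' function simulates the training table, summarises the query, estimates
#' posterior model probabilities, and reports goodness of fit.
#'
#' @param cfg An `scs_run_config`.
#' @param query An [scs_alignment] already mapped to the structure
#'   (`query$l == cfg$stab$L`).
#' @param out_dir Optional directory for TSV artifacts and a JSON manifest.
#' @return List: `posterior` (`scs_posterior`), `observed`, `table`,
#'   `gof`, `best_model`, `manifest`.
#' @export
run_pipeline <- function(cfg, query, out_dir = NULL) {
  if (query$l != cfg$stab$L) {
    stop("query alignment is not mapped to the structure (l = ", query$l,
         ", L = ", cfg$stab$L, "); run map_alignment_to_structure() first",
         call. = FALSE)
  }
  gr <- grantham_table()
  observed <- compute_summary_vector(query, cfg$stab, gr)
  table <- simulate_table(cfg)
  posterior <- .abc_estimate(observed, table, cfg$abc)
  gof <- goodness_of_fit(observed, table, cfg$abc)
  best <- names(posterior$probabilities)[which.max(posterior$probabilities)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("scsabc")),
    seed = cfg$seed, n_sims_per_model = cfg$n_sims_per_model,
    models = vapply(cfg$models, `[[`, character(1), "label"),
    abc_method = cfg$abc$method, tolerance = cfg$abc$tolerance,
    theta_prior = cfg$theta_prior, N = cfg$N, n_tips = cfg$n_tips,
    workers = cfg$workers)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(data.frame(model = names(posterior$probabilities),
                           posterior = unname(posterior$probabilities)),
                file.path(out_dir, "posterior.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(as.data.frame(table), file.path(out_dir, "simulations.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(posterior = posterior, observed = observed, table = table, gof = gof,
       best_model = best, manifest = manifest)
}

#' Pilot-calibrate the theta prior against sequence identity
#'
#' Runs pilot simulations across the prior range (using the first SCS model
#' if present, otherwise the first model) and reports the achieved range of
#' mean pairwise identity; warns when the query identity falls outside it.
#'
#' @param cfg An `scs_run_config`.
#' @param query Optional mapped query alignment (enables the warning).
#' @param pilot_sims Number of pilot simulations (>= 50).
#' @return List `identity_range`, `identities`, `thetas`,
#'   `query_identity` (or `NA`), `within`.
#' @export
calibrate_prior <- function(cfg, query = NULL, pilot_sims = 50L) {
  stopifnot(pilot_sims >= 50)
  scs_idx <- which(vapply(cfg$models, `[[`, character(1), "kind") == "scs")
  spec <- cfg$models[[if (length(scs_idx)) scs_idx[1] else 1L]]
  gr <- grantham_table()
  ids <- numeric(pilot_sims)
  thetas <- numeric(pilot_sims)
  for (i in seq_len(pilot_sims)) {
    seed <- .sim_seed(cfg$seed + 7L, i)
    res <- .with_seed(seed, {
      # stratified theta over the prior range for even coverage
      theta <- cfg$theta_prior[1] +
        (i - 0.5) / pilot_sims * diff(cfg$theta_prior)
      tree <- scale_tree(simulate_coalescent(cfg$n_tips, cfg$N,
                                             cfg$growth_rate),
                         theta, cfg$N, cfg$stab$L)
      aln <- if (spec$kind == "empirical") {
        evolve_empirical(tree, spec$model, l = cfg$stab$L)
      } else {
        evolve_scs(tree, spec$params, cfg$stab)
      }
      c(theta, mean_pairwise_identity(aln))
    })
    thetas[i] <- res[1]; ids[i] <- res[2]
  }
  rng <- range(ids)
  qid <- if (is.null(query)) NA_real_ else mean_pairwise_identity(query)
  within <- if (is.na(qid)) NA else qid >= rng[1] && qid <= rng[2]
  if (isFALSE(within)) {
    warning(sprintf(paste0("query identity %.3f outside the pilot identity ",
                           "range [%.3f, %.3f]; adjust the theta prior"),
                    qid, rng[1], rng[2]))
  }
  list(identity_range = rng, identities = ids, thetas = thetas,
       query_identity = qid, within = within)
}
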