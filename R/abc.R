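.STAT_NAMES <- c("dg_mean", "dg_sd", "seg_sites", "gr_mean", "gr_sd",
                 "gr_skew", "gr_kurt")

#' Assemble a simulation table
#'
#' @param model Character vector of model labels (one per simulation).
#' @param theta Numeric vector of theta draws.
#' @param stats Numeric matrix with the 7 summary statistics per row.
#' @return A `scs_sim_table` data frame; per-model counts must be equal and
#'   at least two distinct labels are required.
#' @export
simulation_table <- function(model, theta, stats) {
  stats <- as.matrix(stats)
  colnames(stats) <- .STAT_NAMES
  stopifnot(length(model) == nrow(stats), length(theta) == nrow(stats))
  tab <- data.frame(model = as.character(model), theta = theta, stats,
                    stringsAsFactors = FALSE)
  counts <- table(tab$model)
  if (length(counts) < 2L) {
    stop("need at least 2 distinct model labels", call. = FALSE)
  }
  if (length(unique(counts)) != 1L) {
    stop("per-model simulation counts must be equal (got ",
         paste(counts, collapse = ", "), ")", call. = FALSE)
  }
  if (!all(is.finite(as.matrix(tab[, .STAT_NAMES])))) {
    stop("non-finite summary statistics in table", call. = FALSE)
  }
  class(tab) <- c("scs_sim_table", "data.frame")
  tab
}

#' ABC configuration
#'
#' @param method `"rejection"`, `"mnlogistic"` or `"neuralnet"`.
#' @param tolerance Fraction of simulations retained, in (0, 1].
#' @param seed Integer seed used by the stochastic methods.
#' @return An `scs_abc_config`.
#' @export
abc_config <- function(method = c("rejection", "mnlogistic", "neuralnet"),
                       tolerance = 0.005, seed = 1L) {
  method <- match.arg(method)
  stopifnot(tolerance > 0, tolerance <= 1)
  structure(list(method = method, tolerance = tolerance,
                 seed = as.integer(seed)),
            class = "scs_abc_config")
}

#' MAD-standardize a simulation table and observed vector
#'
#' Each statistic is divided by its median absolute deviation
#' (`median(|x - median(x)|)`, no consistency constant) across all
#' simulations; statistics with zero MAD are dropped with a warning and the
#' same transform is applied to the observed vector.
#'
#' @param table A `scs_sim_table`.
#' @param observed Named summary vector (7 statistics).
#' @return List `table` (matrix of standardized stats), `observed`,
#'   `kept` (names of retained statistics), `mad` (the divisors).
#' @export
standardize <- function(table, observed) {
  X <- as.matrix(table[, .STAT_NAMES])
  mads <- apply(X, 2, function(x) median(abs(x - median(x))))
  keep <- mads > 0
  if (!any(keep)) stop("all summary statistics are degenerate", call. = FALSE)
  if (any(!keep)) {
    warning("dropping degenerate statistic(s): ",
            paste(.STAT_NAMES[!keep], collapse = ", "))
  }
  obs <- observed[.STAT_NAMES]
  list(table = sweep(X[, keep, drop = FALSE], 2, mads[keep], "/"),
       observed = obs[keep] / mads[keep],
       kept = .STAT_NAMES[keep], mad = mads[keep])
}

.retained <- function(observed, table, tolerance) {
  st <- standardize(table, observed)
  d <- sqrt(colSums((t(st$table) - st$observed)^2))
  k <- ceiling(tolerance * nrow(st$table))
  ord <- order(d, seq_along(d))      # ties broken by row index
  idx <- ord[seq_len(k)]
  list(idx = idx, d = d, st = st, k = k)
}

.posterior_result <- function(probs, retained_indices, distances) {
  probs <- probs / sum(probs)
  structure(list(probabilities = probs, retained_indices = retained_indices,
                 distances = distances),
            class = "scs_posterior")
}

#' @export
print.scs_posterior <- function(x, ...) {
  cat("posterior model probabilities:\n")
  p <- sort(x$probabilities, decreasing = TRUE)
  for (m in names(p)) cat(sprintf("  %-12s %.4f\n", m, p[[m]]))
  invisible(x)
}

#' Rejection ABC model choice
#'
#' Euclidean distance on MAD-standardized statistics; the
#' `ceil(tolerance * nrow)` closest simulations are retained (ties broken by
#' row index) and each model's posterior probability is its share of the
#' retained set.
#'
#' @param observed Named 7-statistic summary vector of the query.
#' @param table A `scs_sim_table`.
#' @param config An `scs_abc_config`.
#' @return An `scs_posterior`: `probabilities` (named, sums to 1),
#'   `retained_indices`, `distances`.
#' @export
abc_rejection <- function(observed, table, config = abc_config("rejection")) {
  r <- .retained(observed, table, config$tolerance)
  labs <- sort(unique(table$model))
  p <- vapply(labs, function(m) mean(table$model[r$idx] == m), numeric(1))
  .posterior_result(setNames(p, labs), r$idx, r$d)
}

.check_regression_feasible <- function(k, nmods) {
  if (k < 10L * nmods) {
    stop("convergence error: only ", k, " retained simulations for ", nmods,
         " models; regression/neural-network methods need at least ",
         10L * nmods, " - increase the tolerance", call. = FALSE)
  }
}

.epanechnikov <- function(d) {
  dmax <- max(d)
  if (dmax == 0) return(rep(1, length(d)))
  pmax(1 - (d / dmax)^2, 1e-8)
}

#' Multinomial-logistic regression ABC model choice
#'
#' Fits a weighted multinomial logistic regression (softmax regression with a
#' tiny ridge penalty for identifiability, solved by full-batch Adam on the
#' convex objective) of model label on the standardized statistics over the
#' retained set, rows weighted by the Epanechnikov kernel of their distance,
#' and evaluates it at the observed vector.  Probabilities are clipped to
#' `[1e-12, 1]` and renormalised.
#'
#' @inheritParams abc_rejection
#' @return An `scs_posterior`.
#' @export
abc_mnlogistic <- function(observed, table,
                           config = abc_config("mnlogistic", 0.05)) {
  r <- .retained(observed, table, config$tolerance)
  labs <- sort(unique(table$model))
  ylab <- table$model[r$idx]
  .check_regression_feasible(r$k, length(labs))
  if (length(unique(ylab)) == 1L) {
    p <- setNames(as.numeric(labs == ylab[1]), labs)
    return(.posterior_result(pmax(p, 1e-12), r$idx, r$d))
  }
  sc <- .center_scale(r$st$table[r$idx, , drop = FALSE], r$st$observed)
  present <- sort(unique(ylab))
  Y <- outer(ylab, present, "==") * 1
  w <- .epanechnikov(r$d[r$idx])
  fit <- .fit_softmax(sc$X, Y, w)
  if (!fit$converged) {
    stop("convergence error: multinomial regression did not converge; ",
         "increase the tolerance", call. = FALSE)
  }
  pr <- .predict_softmax(fit, sc$xobs)
  p <- setNames(rep(1e-12, length(labs)), labs)
  p[present] <- pmax(pmin(pr, 1), 1e-12)
  .posterior_result(p, r$idx, r$d)
}

.center_scale <- function(X, xobs) {
  X <- scale(X)
  ctr <- attr(X, "scaled:center")
  scl <- attr(X, "scaled:scale")
  scl[scl == 0] <- 1
  X[is.na(X)] <- 0
  xo <- (xobs - ctr) / scl
  xo[!is.finite(xo)] <- 0
  list(X = X, xobs = xo)
}

# weighted softmax regression with a small ridge penalty; the objective is
# convex, so damped Newton with the exact Hessian converges in a few steps
.fit_softmax <- function(X, Y, w, iters = 60L, ridge = 0.01) {
  n <- nrow(X); C <- ncol(Y)
  Xb <- cbind(1, X)
  p <- ncol(Xb)
  B <- matrix(0, p, C)
  wn <- w / sum(w)
  pen <- ridge * diag(rep(c(1e-4, rep(1, p - 1)), C))  # light on intercepts
  loss <- function(B) {
    Z <- Xb %*% B
    Z <- Z - apply(Z, 1, max)
    lse <- log(rowSums(exp(Z)))
    -sum(wn * (rowSums(Y * Z) - lse)) +
      0.5 * ridge * sum(B[-1, ]^2) + 0.5 * ridge * 1e-4 * sum(B[1, ]^2)
  }
  gnorm <- Inf
  for (it in seq_len(iters)) {
    Z <- Xb %*% B
    Z <- Z - apply(Z, 1, max)
    P <- exp(Z); P <- P / rowSums(P)
    G <- t(Xb) %*% ((P - Y) * wn)
    G <- G + ridge * rbind(1e-4 * B[1, , drop = FALSE],
                           B[-1, , drop = FALSE])
    gnorm <- max(abs(G))
    if (gnorm < 1e-10) break
    H <- matrix(0, p * C, p * C)
    for (cc in seq_len(C)) for (dd in seq_len(C)) {
      v <- wn * ((cc == dd) * P[, cc] - P[, cc] * P[, dd])
      H[(cc - 1) * p + seq_len(p), (dd - 1) * p + seq_len(p)] <-
        crossprod(Xb, Xb * v)
    }
    H <- H + pen + 1e-10 * diag(p * C)
    step <- matrix(solve(H, as.vector(G)), p, C)
    f0 <- loss(B)
    lam <- 1
    repeat {
      Bn <- B - lam * step
      if (loss(Bn) <= f0 + 1e-12 || lam < 1e-6) break
      lam <- lam / 2
    }
    B <- Bn
  }
  list(B = B, converged = is.finite(gnorm) && gnorm < 1e-5)
}

.predict_softmax <- function(fit, x) {
  z <- drop(crossprod(fit$B, c(1, x)))
  z <- z - max(z)
  exp(z) / sum(exp(z))
}

# single-hidden-layer softmax classifier trained by full-batch Adam with a
# small weight decay (keeps noise-only fits near the uniform prediction);
# deterministic given the RNG stream at entry
.fit_mlp <- function(X, Y, w, hidden = 5L, iters = 400L, lr = 0.05,
                     decay = 0.05) {
  p <- ncol(X); C <- ncol(Y); n <- nrow(X)
  th <- list(W1 = matrix(rnorm(hidden * p, sd = 0.5), hidden, p),
             b1 = rnorm(hidden, sd = 0.1),
             W2 = matrix(rnorm(C * hidden, sd = 0.5), C, hidden),
             b2 = rnorm(C, sd = 0.1))
  mom <- lapply(th, function(x) x * 0)
  vel <- mom
  wn <- w / sum(w)
  b1 <- 0.9; b2a <- 0.999; eps <- 1e-8
  for (it in seq_len(iters)) {
    H <- tanh(X %*% t(th$W1) + rep(th$b1, each = n))      # n x hidden
    Z <- H %*% t(th$W2) + rep(th$b2, each = n)            # n x C
    Z <- Z - apply(Z, 1, max)
    P <- exp(Z); P <- P / rowSums(P)
    dZ <- (P - Y) * wn                                     # n x C
    g <- list(W2 = t(dZ) %*% H + decay * th$W2, b2 = colSums(dZ),
              W1 = t((dZ %*% th$W2) * (1 - H^2)) %*% X + decay * th$W1,
              b1 = colSums((dZ %*% th$W2) * (1 - H^2)))
    for (nm in names(th)) {
      mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * g[[nm]]
      vel[[nm]] <- b2a * vel[[nm]] + (1 - b2a) * g[[nm]]^2
      th[[nm]] <- th[[nm]] - lr * (mom[[nm]] / (1 - b1^it)) /
        (sqrt(vel[[nm]] / (1 - b2a^it)) + eps)
    }
  }
  th
}

.predict_mlp <- function(th, x) {
  h <- tanh(th$W1 %*% x + th$b1)
  z <- drop(th$W2 %*% h + th$b2)
  z <- z - max(z)
  exp(z) / sum(exp(z))
}

#' Neural-network ABC model choice
#'
#' Ensemble of 10 single-hidden-layer (5 tanh units) softmax classifiers
#' trained on the Epanechnikov-weighted retained set from random
#' initialisations seeded from `config$seed`; class probabilities at the
#' observed vector are averaged and renormalised.
#'
#' @inheritParams abc_rejection
#' @param ensemble Number of networks (default 10).
#' @return An `scs_posterior`.
#' @export
abc_neuralnet <- function(observed, table,
                          config = abc_config("neuralnet", 0.05),
                          ensemble = 10L) {
  r <- .retained(observed, table, config$tolerance)
  labs <- sort(unique(table$model))
  ylab <- table$model[r$idx]
  .check_regression_feasible(r$k, length(labs))
  if (length(unique(ylab)) == 1L) {
    p <- setNames(as.numeric(labs == ylab[1]), labs)
    return(.posterior_result(pmax(p, 1e-12), r$idx, r$d))
  }
  sc <- .center_scale(r$st$table[r$idx, , drop = FALSE], r$st$observed)
  present <- sort(unique(ylab))
  Y <- outer(ylab, present, "==") * 1
  w <- .epanechnikov(r$d[r$idx])
  preds <- .with_seed(config$seed, {
    lapply(seq_len(ensemble), function(e) {
      th <- .fit_mlp(sc$X, Y, w)
      .predict_mlp(th, sc$xobs)
    })
  })
  pm <- Reduce("+", preds) / length(preds)
  p <- setNames(rep(1e-12, length(labs)), labs)
  p[present] <- pmax(pm, 1e-12)
  .posterior_result(p, r$idx, r$d)
}

.abc_estimate <- function(observed, table, config) {
  switch(config$method,
         rejection = abc_rejection(observed, table, config),
         mnlogistic = abc_mnlogistic(observed, table, config),
         neuralnet = abc_neuralnet(observed, table, config))
}

#' Leave-one-out cross-validation of model selection
#'
#' For each model, `n_eval` table rows are drawn without replacement and used
#' as pseudo-observed data; each is estimated against the table minus itself.
#' Records the selected model (argmax posterior; ties go to the first label
#' alphabetically) and the posterior probability of the true model.
#'
#' @param table A `scs_sim_table`.
#' @param config An `scs_abc_config`.
#' @param n_eval Pseudo-observed draws per model (default 100).
#' @param seed Seed for the draws.
#' @return An `scs_confusion`: `counts` (true x selected),
#'   `mean_true_posterior` (per true model), `accuracy`.
#' @export
cross_validate <- function(table, config, n_eval = 100L, seed = 1L) {
  labs <- sort(unique(table$model))
  per <- sum(table$model == labs[1])
  stopifnot(n_eval <= per)
  counts <- matrix(0L, length(labs), length(labs),
                   dimnames = list(true = labs, selected = labs))
  post_true <- setNames(numeric(length(labs)), labs)
  .with_seed(seed, {
    for (m in labs) {
      rows <- sample(which(table$model == m), n_eval)
      for (i in rows) {
        obs <- unlist(table[i, .STAT_NAMES])
        sub <- table[-i, , drop = FALSE]
        class(sub) <- class(table)
        res <- .abc_estimate(obs, sub, config)
        sel <- names(res$probabilities)[which.max(res$probabilities)]
        counts[m, sel] <- counts[m, sel] + 1L
        post_true[m] <- post_true[m] + res$probabilities[[m]]
      }
    }
  })
  structure(list(counts = counts, mean_true_posterior = post_true / n_eval,
                 accuracy = sum(diag(counts)) / sum(counts),
                 n_eval = n_eval),
            class = "scs_confusion")
}

#' @export
print.scs_confusion <- function(x, ...) {
  cat("cross-validation confusion matrix (rows = true model):\n")
  print(x$counts)
  cat(sprintf("overall accuracy: %.3f\n", x$accuracy))
  cat("mean posterior of true model:\n")
  print(round(x$mean_true_posterior, 3))
  invisible(x)
}

#' Goodness of fit of each model to the observed data
#'
#' Per model: the distribution of distances from the observed vector to that
#' model's retained simulations (rejection at `config$tolerance` within the
#' model), and per statistic a flag for whether the observed value lies
#' within the `[1%, 99%]` quantile envelope of the model's retained
#' simulations.
#'
#' @inheritParams abc_rejection
#' @return An `scs_gof`: `distances` (list per model), `envelope` (logical
#'   matrix model x statistic).
#' @export
goodness_of_fit <- function(observed, table,
                            config = abc_config("rejection", 0.005)) {
  st <- standardize(table, observed)
  labs <- sort(unique(table$model))
  obs <- observed[.STAT_NAMES]
  distances <- list()
  env <- matrix(NA, length(labs), length(.STAT_NAMES),
                dimnames = list(labs, .STAT_NAMES))
  for (m in labs) {
    rows <- which(table$model == m)
    d <- sqrt(colSums((t(st$table[rows, , drop = FALSE]) - st$observed)^2))
    k <- max(1L, ceiling(config$tolerance * length(rows)))
    keep <- rows[order(d, seq_along(d))[seq_len(k)]]
    distances[[m]] <- sort(d)[seq_len(k)]
    for (s in .STAT_NAMES) {
      q <- quantile(table[keep, s], c(0.01, 0.99), names = FALSE, type = 7)
      env[m, s] <- obs[[s]] >= q[1] && obs[[s]] <= q[2]
    }
  }
  structure(list(distances = distances, envelope = env), class = "scs_gof")
}

#' @export
print.scs_gof <- function(x, ...) {
  cat("goodness of fit; minimum retained distance per model:\n")
  for (m in names(x$distances)) {
    cat(sprintf("  %-12s min %.4f median %.4f\n", m, min(x$distances[[m]]),
                median(x$distances[[m]])))
  }
  cat("observed within [1%,99%] envelope:\n")
  print(x$envelope)
  invisible(x)
}
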