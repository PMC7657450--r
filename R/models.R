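#' Standardize columns of a feature table
#'
#' Centers and scales (n-1 denominator) the named columns to mean 0, sd 1
#' within each level of `scope` (per-study by default), storing the
#' transform in `attr(, "standardize")` for inversion.
#'
#' @param table a data.frame (e.g. a `feature_table`).
#' @param columns character vector of columns to standardize.
#' @param scope column naming the grouping within which to standardize, or
#'   `NULL` for global.
#' @return The table with standardized columns.
#' @export
standardize <- function(table,
                        columns = c("log_shares", "rating", "roi_mean",
                                    "expression_r"),
                        scope = "study") {
  groups <- if (is.null(scope)) rep(1L, nrow(table)) else table[[scope]]
  params <- list()
  for (cl in columns) {
    for (gl in unique(groups)) {
      sel <- groups == gl
      x <- table[[cl]][sel]
      m <- mean(x, na.rm = TRUE); s <- stats::sd(x, na.rm = TRUE)
      if (!is.finite(s) || s == 0) {
        stop(sprintf("column '%s' has zero variance within scope '%s'",
                     cl, gl))
      }
      table[[cl]][sel] <- (x - m) / s
      params[[paste(cl, gl, sep = "|")]] <- c(mean = m, sd = s)
    }
  }
  attr(table, "standardize") <- params
  table
}

#' Invert a standardization
#'
#' @param table a table previously returned by [standardize()].
#' @param columns columns to restore.
#' @param scope same grouping column used for standardization.
#' @return The table on the original scale.
#' @export
destandardize <- function(table, columns, scope = "study") {
  params <- attr(table, "standardize")
  if (is.null(params)) stop("table carries no standardization attributes")
  groups <- if (is.null(scope)) rep(1L, nrow(table)) else table[[scope]]
  for (cl in columns) {
    for (gl in unique(groups)) {
      pr <- params[[paste(cl, gl, sep = "|")]]
      sel <- groups == gl
      table[[cl]][sel] <- table[[cl]][sel] * pr["sd"] + pr["mean"]
    }
  }
  table
}

#' Specification of a Bayesian sharing model
#'
#' Fixed settings mirror the reference analysis: normal(0,1) priors on
#' coefficients, half-normal(0,1) on standard deviations, LKJ(1) on the
#' group correlation; 4 chains of 1000 iterations with the first 500
#' discarded.
#'
#' @param predictors subset of `c("rating", "roi_mean", "expression_r")`
#'   (at least one; any numeric column of the table is accepted).
#' @param outcome outcome column (default `log_shares`).
#' @param hierarchical if `TRUE`, per-participant varying intercepts and
#'   slopes for all predictors; if `FALSE`, a single-level model.
#' @param chains,iter,warmup MCMC settings.
#' @param seed base seed; chain c uses `seed + c`.
#' @return A `model_spec` list.
#' @export
model_spec <- function(predictors, outcome = "log_shares",
                       hierarchical = TRUE, chains = 4L, iter = 1000L,
                       warmup = 500L, seed = 1L) {
  stopifnot(length(predictors) >= 1, chains >= 2, iter > warmup)
  structure(list(predictors = predictors, outcome = outcome,
                 hierarchical = hierarchical, chains = as.integer(chains),
                 iter = as.integer(iter), warmup = as.integer(warmup),
                 seed = as.integer(seed)),
            class = "model_spec")
}

## fingerprint of the modelled observations (outcome vector and grouping,
## in order) used to refuse LOO comparisons across different data; the
## design is deliberately excluded so nested models on the same rows match
data_fingerprint <- function(y, X, g = NULL) {
  v <- c(length(y), round(sum(y), 8), round(sum(y^2), 8),
         round(sum(y * seq_along(y)), 8),
         if (!is.null(g)) c(length(unique(g)), sum(g * seq_along(g))))
  paste(format(v, digits = 12), collapse = "|")
}

chain_array <- function(chains_list) {
  ## list of S x P matrices -> S x chains x P array
  S <- nrow(chains_list[[1]]); P <- ncol(chains_list[[1]])
  arr <- array(NA_real_, c(S, length(chains_list), P),
               dimnames = list(NULL, NULL, colnames(chains_list[[1]])))
  for (c in seq_along(chains_list)) arr[, c, ] <- chains_list[[c]]
  arr
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) PSRF `sqrt(((n-1)/n * W + B/n) / W)` with `W` the
#' mean within-chain variance and `B` the between-chain variance of chain
#' means times `n`.
#'
#' @param draws matrix of draws with one column per chain (or a list of
#'   equal-length numeric vectors).
#' @return The PSRF as a single number.
#' @export
gelman_rubin <- function(draws) {
  if (is.list(draws)) draws <- do.call(cbind, draws)
  draws <- as.matrix(draws)
  m <- ncol(draws); n <- nrow(draws)
  if (m < 2) stop("need at least 2 chains")
  if (n < 10) stop("need at least 10 draws per chain")
  W <- mean(apply(draws, 2, stats::var))
  B <- n * stats::var(colMeans(draws))
  sqrt(((n - 1) / n * W + B / n) / W)
}

split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  h <- floor(n / 2)
  halves <- do.call(cbind, lapply(seq_len(ncol(draws)), function(c) {
    cbind(draws[seq_len(h), c], draws[(n - h + 1):n, c])
  }))
  gelman_rubin(halves)
}

run_chains <- function(sampler, spec) {
  lapply(seq_len(spec$chains), function(ch) {
    set.seed(spec$seed + ch)
    sampler(spec$iter, spec$warmup)
  })
}

assemble_fit <- function(chains, spec, y, X, g, n_group, table) {
  ## chains: list of lists with matrices beta (S x p), sigma (S), opt tau/u
  p <- ncol(X)
  nm <- c(colnames(X), "sigma")
  mono <- lapply(chains, function(ch) {
    m <- cbind(ch$beta, ch$sigma)
    colnames(m) <- nm
    if (!is.null(ch$tau)) {
      tn <- paste0("tau_", colnames(X))
      colnames(ch$tau) <- tn
      m <- cbind(m, ch$tau)
    }
    m
  })
  arr <- chain_array(mono)
  params <- dimnames(arr)[[3]]
  rhat <- vapply(params, function(pp) gelman_rubin(arr[, , pp]), 0)
  srhat <- vapply(params, function(pp) split_rhat(arr[, , pp]), 0)
  draws <- do.call(rbind, mono)
  u <- if (!is.null(chains[[1]]$u)) do.call(rbind, lapply(chains, `[[`, "u"))
  fit <- structure(list(
    draws = draws, u = u, n_group = n_group, spec = spec,
    y = y, X = X, g = g, rhat = rhat, split_rhat = srhat,
    data_hash = data_fingerprint(y, X, g),
    n_draws = nrow(draws)), class = "model_fit")
  fit$loglik <- pointwise_loglik(fit)
  fit$summary <- coef_summary(fit)
  fit
}

coef_summary <- function(fit) {
  terms <- c(colnames(fit$X), "sigma")
  do.call(rbind, lapply(terms, function(tm) {
    d <- fit$draws[, tm]
    data.frame(term = tm, mean = mean(d),
               lower = unname(stats::quantile(d, 0.025)),
               upper = unname(stats::quantile(d, 0.975)),
               rhat = unname(fit$rhat[tm]))
  }))
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit: %s%s, %d draws>\n",
              paste(x$spec$predictors, collapse = " + "),
              if (x$spec$hierarchical) " | participant" else "",
              x$n_draws))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

build_model_matrices <- function(table, spec) {
  if ("flagged" %in% names(table) && any(table$flagged)) {
    message(sprintf("dropping %d flagged trial(s) from the model",
                    sum(table$flagged)))
    table <- table[!table$flagged, , drop = FALSE]
  }
  keep <- stats::complete.cases(table[, c(spec$outcome, spec$predictors)])
  table <- table[keep, , drop = FALSE]
  y <- table[[spec$outcome]]
  X <- cbind(intercept = 1,
             as.matrix(table[, spec$predictors, drop = FALSE]))
  list(y = y, X = X, table = table)
}

#' Fit a hierarchical within-person sharing model
#'
#' Gaussian likelihood with person-varying intercept and slopes:
#' `y_pa = x' beta + x' u_p + eps`, `u_p ~ MVN(0, diag(tau) Omega diag(tau))`,
#' priors normal(0,1) on `beta`, half-normal(0,1) on `tau` and the residual
#' sd, LKJ(1) on `Omega`. Sampled by blocked Gibbs (non-centred
#' parameterisation; Metropolis steps for the correlation). Convergence is
#' checked with the classic Gelman-Rubin PSRF on all monitored parameters
#' against the 0.95-1.05 band; on violation the iteration count is
#' doubled once, then the fit fails loudly.
#'
#' @param table a `feature_table` (standardize first for standardized
#'   effect sizes).
#' @param spec a [model_spec()] with `hierarchical = TRUE`.
#' @param group column defining the grouping (default `participant`).
#' @return A `model_fit` with draws, coefficient summary, R-hat, pointwise
#'   log-likelihood and (lazily) Bayesian R-squared.
#' @export
fit_hierarchical <- function(table, spec, group = "participant") {
  stopifnot(inherits(spec, "model_spec"), spec$hierarchical)
  mm <- build_model_matrices(table, spec)
  gfac <- factor(mm$table[[group]])
  if (nlevels(gfac) < 2) stop("need at least 2 participants")
  if (min(tabulate(gfac)) < 2) stop("every participant needs >= 2 trials")
  g0 <- as.integer(gfac) - 1L
  n_group <- nlevels(gfac)
  fit_once <- function(sp) {
    chains <- run_chains(function(iter, warmup) {
      gibbs_hier_cpp(mm$y, mm$X, mm$X, g0, n_group, iter, warmup, 0.12)
    }, sp)
    assemble_fit(chains, sp, mm$y, mm$X, g0, n_group, mm$table)
  }
  fit <- fit_once(spec)
  if (any(fit$rhat < 0.95 | fit$rhat > 1.05)) {
    spec2 <- spec; spec2$iter <- 2L * spec$iter; spec2$warmup <- 2L * spec$warmup
    fit <- fit_once(spec2)
    if (any(fit$rhat < 0.95 | fit$rhat > 1.05)) {
      bad <- names(fit$rhat)[fit$rhat < 0.95 | fit$rhat > 1.05]
      stop(sprintf("non-convergence after doubling iterations (R-hat: %s)",
                   paste(sprintf("%s=%.3f", bad, fit$rhat[bad]),
                         collapse = ", ")))
    }
  }
  fit
}

#' Fit a single-level article-average sharing model
#'
#' Aggregates each predictor by article (mean over participants) unless the
#' table already has one row per article, then fits a Gaussian regression
#' with the same priors on coefficients and residual sd.
#'
#' @param table a `feature_table` (trial-level; aggregated internally) or an
#'   article-level table with unique `article_id`.
#' @param spec a [model_spec()] with `hierarchical = FALSE`.
#' @param aggregate if `TRUE` (default) average predictors by article and
#'   re-standardize the averaged columns across articles, so coefficients are
#'   standardized effects at the level of article-to-article variation.
#' @return A `model_fit`.
#' @export
fit_article_level <- function(table, spec, aggregate = TRUE) {
  stopifnot(inherits(spec, "model_spec"), !spec$hierarchical)
  if (aggregate) {
    table <- aggregate_by_article(table, c(spec$predictors, spec$outcome))
    table <- standardize(table, c(spec$predictors, spec$outcome),
                         scope = NULL)
  } else if (anyDuplicated(table$article_id)) {
    stop("duplicate article rows in an article-level table")
  }
  if (nrow(table) < 8) stop("need at least 8 articles")
  if (nrow(table) < length(spec$predictors) + 2) {
    stop("fewer articles than predictors + 2")
  }
  mm <- build_model_matrices(table, spec)
  fit_once <- function(sp) {
    chains <- run_chains(function(iter, warmup) {
      gibbs_lm_cpp(mm$y, mm$X, iter, warmup)
    }, sp)
    assemble_fit(chains, sp, mm$y, mm$X, NULL, 0L, mm$table)
  }
  fit <- fit_once(spec)
  if (any(fit$rhat < 0.95 | fit$rhat > 1.05)) {
    spec2 <- spec; spec2$iter <- 2L * spec$iter; spec2$warmup <- 2L * spec$warmup
    fit <- fit_once(spec2)
  }
  fit
}

#' Average a feature table by article
#'
#' @param table trial-level table with `article_id`.
#' @param columns numeric columns to average.
#' @return One row per article.
#' @export
aggregate_by_article <- function(table, columns) {
  if ("flagged" %in% names(table)) table <- table[!table$flagged, ]
  agg <- stats::aggregate(table[, columns, drop = FALSE],
                          by = list(article_id = table$article_id), mean)
  agg[order(agg$article_id), , drop = FALSE]
}

linear_predictor <- function(fit) {
  ## S x N matrix of draw-wise predicted means, including group effects
  eta <- fit$draws[, colnames(fit$X), drop = FALSE] %*% t(fit$X)
  if (!is.null(fit$u)) {
    K <- ncol(fit$X); S <- fit$n_draws; N <- length(fit$y)
    ## fit$u rows are vectorised n_group x K matrices (column-major)
    for (k in seq_len(K)) {
      uk <- fit$u[, (k - 1L) * fit$n_group + fit$g + 1L, drop = FALSE]
      eta <- eta + uk * matrix(fit$X[, k], S, N, byrow = TRUE)
    }
  }
  eta
}

#' Pointwise log-likelihood matrix
#'
#' `log N(y_i | yhat_si, sigma_s)` for every posterior draw `s` and
#' observation `i`, with the linear predictor including group effects for
#' hierarchical fits.
#'
#' @param fit a `model_fit`.
#' @return An `S x N` matrix.
#' @export
pointwise_loglik <- function(fit) {
  eta <- linear_predictor(fit)
  sig <- fit$draws[, "sigma"]
  ll <- stats::dnorm(matrix(fit$y, nrow(eta), ncol(eta), byrow = TRUE),
                     eta, sig, log = TRUE)
  ll
}

#' Bayesian R-squared
#'
#' Per posterior draw `s`: `R2_s = V(yhat_s) / (V(yhat_s) + sigma_s^2)`
#' where `yhat_s` is the draw's linear predictor (group effects included)
#' and `sigma_s^2` the draw's residual variance.
#'
#' @param fit a `model_fit`.
#' @return List with `draws` (vector), `median`, `lower`, `upper` (95% CI).
#' @export
bayes_r2 <- function(fit) {
  if (!"sigma" %in% colnames(fit$draws)) stop("fit has no residual sd draws")
  eta <- linear_predictor(fit)
  vfit <- apply(eta, 1, stats::var)
  r2 <- vfit / (vfit + fit$draws[, "sigma"]^2)
  list(draws = r2, median = stats::median(r2),
       lower = unname(stats::quantile(r2, 0.025)),
       upper = unname(stats::quantile(r2, 0.975)))
}
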