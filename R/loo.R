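## Generalized Pareto fit by the profile-likelihood quadrature of
## Zhang & Stephens (2009), as used for Pareto-smoothed importance sampling.
## x are exceedances over the threshold (sorted ascending). Returns shape k
## and scale sigma.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_bs <- 3
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior_bs * xstar)
  prof <- vapply(theta, function(th) {
    ## profile log-likelihood in the Zhang-Stephens parameterisation
    kz <- -mean(log1p(-th * x))
    n * (log(th / kz) + kz - 1)
  }, 0)
  w <- 1 / vapply(jj, function(j) sum(exp(prof - prof[j])), 0)
  theta_hat <- sum(theta * w)
  ## report the modern tail index xi (positive = heavy tail) and scale
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

#' Pareto-smoothed importance-sampling LOO
#'
#' Approximate leave-one-out cross-validation from posterior draws. For
#' each observation the raw importance ratios are proportional to the
#' reciprocal likelihood; the `M = min(ceil(0.2 S), ceil(3 sqrt(S)))`
#' largest log-ratios are replaced by expected order statistics of a
#' generalized Pareto distribution fitted to that tail, weights are
#' truncated at the largest raw ratio, and
#' `elpd_i = log(sum(w_s lik_s) / sum(w_s))`. The Pareto shape `k` is
#' reported per observation, with a warning above 0.7.
#'
#' @param loglik `S x N` pointwise log-likelihood matrix (draws by
#'   observations), or a `model_fit`.
#' @return A `loo_result`: list with `elpd_loo`, `se`, `looic = -2 *
#'   elpd_loo`, `pointwise` (elpd_i), `pareto_k`.
#' @export
psis_loo <- function(loglik) {
  if (inherits(loglik, "model_fit")) loglik <- loglik$loglik
  loglik <- as.matrix(loglik)
  if (any(!is.finite(loglik))) stop("non-finite log-likelihood entries")
  S <- nrow(loglik); N <- ncol(loglik)
  if (S < 400) stop("need at least 400 posterior draws")
  M <- min(ceiling(0.2 * S), ceiling(3 * sqrt(S)))
  elpd <- numeric(N); pk <- numeric(N)
  for (i in seq_len(N)) {
    ll <- loglik[, i]
    lr <- -ll                      # log raw importance ratios
    lr <- lr - max(lr)
    ord <- order(lr)
    tail_idx <- ord[(S - M + 1):S]
    cutpoint <- lr[ord[S - M]]     # threshold: largest non-tail log-ratio
    exceed <- exp(lr[tail_idx]) - exp(cutpoint)
    if (stats::sd(exceed) == 0) {
      pk[i] <- -Inf
      lw <- lr
    } else {
      fitgp <- gpd_fit(exceed)
      pk[i] <- fitgp$k
      pfit <- (seq_len(M) - 0.5) / M
      repl <- log(exp(cutpoint) + qgpd(pfit, fitgp$k, fitgp$sigma))
      lw <- lr
      lw[tail_idx[order(lr[tail_idx])]] <- repl
      lw <- pmin(lw, max(lr))      # truncate at the largest raw ratio
    }
    ## elpd_i = log( sum w*lik / sum w )
    elpd[i] <- logsumexp(lw + ll) - logsumexp(lw)
  }
  if (any(pk > 0.7)) {
    warning(sprintf("%d observation(s) with Pareto k > 0.7; PSIS estimate %s",
                    sum(pk > 0.7), "may be unreliable"))
  }
  elpd_loo <- sum(elpd)
  se <- sqrt(N * stats::var(elpd))
  structure(list(elpd_loo = elpd_loo, se = se, looic = -2 * elpd_loo,
                 looic_se = 2 * se, pointwise = elpd, pareto_k = pk),
            class = "loo_result")
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("<loo: elpd_loo = %.2f (SE %.2f), looic = %.2f>\n",
              x$elpd_loo, x$se, x$looic))
  invisible(x)
}

#' Compare two fits by LOO information criterion
#'
#' Pointwise elpd differences between fits of the same observations (checked
#' via a data fingerprint): `dLOOIC = -2 * sum(elpd_a,i - elpd_b,i)` with
#' `SE = 2 * sqrt(N * var(elpd_a,i - elpd_b,i))`. Negative values favour
#' `fit_a`.
#'
#' @param fit_a,fit_b `model_fit` objects on identical data.
#' @return List with `delta_looic`, `se`, `delta_elpd`, per-observation
#'   differences.
#' @export
compare_loo <- function(fit_a, fit_b) {
  if (!identical(fit_a$data_hash, fit_b$data_hash)) {
    stop("fits were not computed on the same observations")
  }
  la <- psis_loo(fit_a$loglik)
  lb <- psis_loo(fit_b$loglik)
  d <- la$pointwise - lb$pointwise
  delta_elpd <- sum(d)
  se <- 2 * sqrt(length(d) * stats::var(d))
  list(delta_looic = -2 * delta_elpd, se = se, delta_elpd = delta_elpd,
       pointwise = d, loo_a = la, loo_b = lb)
}

#' Exact leave-one-out by refitting (oracle for small single-level fits)
#'
#' Refits the model N times, each time holding out one observation, and
#' evaluates the log posterior-predictive density of the held-out point.
#' Quadratic in the data size; intended for validating [psis_loo()] on
#' small problems.
#'
#' @param table article-level table (one row per observation).
#' @param spec a [model_spec()] with `hierarchical = FALSE`.
#' @return List with `elpd_loo` and `pointwise`.
#' @export
exact_loo_refit <- function(table, spec) {
  stopifnot(!spec$hierarchical)
  n <- nrow(table)
  pw <- numeric(n)
  for (i in seq_len(n)) {
    fit_i <- fit_article_level(table[-i, , drop = FALSE], spec,
                               aggregate = FALSE)
    Xi <- c(intercept = 1,
            unlist(table[i, spec$predictors, drop = TRUE]))
    eta <- as.vector(fit_i$draws[, colnames(fit_i$X), drop = FALSE] %*% Xi)
    ll <- stats::dnorm(table[[spec$outcome]][i], eta,
                       fit_i$draws[, "sigma"], log = TRUE)
    pw[i] <- logsumexp(ll) - log(length(ll))
  }
  list(elpd_loo = sum(pw), pointwise = pw)
}
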