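#' Fit a finite mixture of linear regressions by EM
#'
#' Models `y ~ Normal(intercept_k + slope_k * x, residual_sd_k^2)` with `k`
#' components and mixing weights, the working model for one CpG whose beta
#' values are diluted towards a shared normal state by (1 - purity). The EM
#' loop alternates posterior membership probabilities (E-step) with weighted
#' least-squares line fits, weight and residual-SD updates per component
#' (M-step). Components whose mixing weight falls below `min_weight` are
#' dropped and EM continues with fewer components, so the returned number of
#' components may be smaller than requested — this is what makes spurious
#' tiny populations vanish.
#'
#' Initialization is a random hard partition of the samples drawn from the
#' seeded generator, followed by one M-step; the same `(y, x, k, seed)`
#' therefore always returns the identical fit. The residual SD is floored at
#' `sd_floor` so zero-variance populations cannot blow up the likelihood.
#' Final components are relabelled in order of increasing intercept, which
#' makes labels comparable across restarts.
#'
#' @param y Numeric response vector (beta values), finite.
#' @param x Numeric covariate vector (typically 1 - purity), finite; must
#'   have nonzero variance unless `k == 1`.
#' @param k Number of components to start from, 1–3.
#' @param seed Integer seed for the random initial partition.
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param min_weight Components below this mixing weight are dropped.
#' @param sd_floor Lower bound for every residual SD.
#' @return An object of class `mixreg_fit`: a list with `components` (tibble
#'   of weight, intercept, slope, residual_sd per component), the n-by-K
#'   `responsibilities` matrix, hard `labels`, `log_likelihood`, `bic`,
#'   `n_params`, `converged`, `n_iter`, `seed`, and the per-iteration
#'   `ll_history` (restarted after a component drop).
#' @seealso [select_model()] for BIC-based choice of the component count.
#' @examples
#' x <- runif(60, 0.1, 0.8)
#' y <- 0.1 + 0.8 * x + rnorm(60, 0, 0.02)
#' fit_em(y, x, k = 1, seed = 1)
#' @export
fit_em <- function(y, x, k, seed = 1L, max_iter = 200L, tol = 1e-6,
                   min_weight = 0.05, sd_floor = 1e-4) {
  n <- length(y)
  if (length(x) != n) stop("y and x must have equal length")
  if (!all(is.finite(y)) || !all(is.finite(x))) stop("y and x must be finite")
  if (k < 1 || k > 3) stop("k must be between 1 and 3")
  if (n < 3 * k) stop(sprintf("need at least %d samples for k = %d", 3 * k, k))
  if (k > 1 && stats::var(x) == 0) stop("x has zero variance; only k = 1 is identifiable")

  if (k == 1L) {
    comp <- wls_line(y, x, rep(1, n))
    s <- max(sqrt(mean((y - comp[1] - comp[2] * x)^2)), sd_floor)
    ll <- sum(dnorm(y, comp[1] + comp[2] * x, s, log = TRUE))
    return(new_mixreg_fit(
      weights = 1, intercepts = comp[1], slopes = comp[2], sds = s,
      resp = matrix(1, n, 1), ll = ll, n = n, converged = TRUE,
      n_iter = 0L, seed = as.integer(seed), ll_history = ll
    ))
  }

  lab0 <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  resp <- matrix(0, n, k)
  resp[cbind(seq_len(n), lab0)] <- 1
  par <- mstep(y, x, resp, sd_floor)

  ll_prev <- -Inf
  ll_history <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    es <- estep(y, x, par)
    ll <- es$ll
    ll_history <- c(ll_history, ll)

    w <- colMeans(es$resp)
    if (any(w < min_weight) && length(w) > 1L) {
      keep <- w >= min_weight
      if (!any(keep)) keep <- seq_along(w) == which.max(w)
      resp <- es$resp[, keep, drop = FALSE]
      resp <- resp / rowSums(resp)
      par <- mstep(y, x, resp, sd_floor)
      # the model changed: likelihood comparisons restart
      ll_prev <- -Inf
      ll_history <- numeric(0)
      if (ncol(resp) == 1L) break
      next
    }

    if (is.finite(ll_prev) && abs(ll - ll_prev) <= tol * (abs(ll_prev) + tol)) {
      converged <- TRUE
      par <- mstep(y, x, es$resp, sd_floor)
      break
    }
    ll_prev <- ll
    par <- mstep(y, x, es$resp, sd_floor)
  }

  es <- estep(y, x, par) # final consistent E-step
  ord <- order(par$intercepts)
  new_mixreg_fit(
    weights = par$weights[ord], intercepts = par$intercepts[ord],
    slopes = par$slopes[ord], sds = par$sds[ord],
    resp = es$resp[, ord, drop = FALSE], ll = es$ll, n = n,
    converged = converged || ncol(es$resp) == 1L, n_iter = iter,
    seed = as.integer(seed), ll_history = ll_history
  )
}

# E-step: log-sum-exp over component log densities
estep <- function(y, x, par) {
  k <- length(par$weights)
  ld <- vapply(seq_len(k), function(j) {
    log(par$weights[j]) +
      dnorm(y, par$intercepts[j] + par$slopes[j] * x, par$sds[j], log = TRUE)
  }, numeric(length(y)))
  ld <- matrix(ld, nrow = length(y))
  m <- do.call(pmax, c(as.data.frame(ld), list(na.rm = FALSE)))
  lse <- m + log(rowSums(exp(ld - m)))
  list(resp = exp(ld - lse), ll = sum(lse))
}

# M-step: per-component weighted least squares, weight and floored SD update
mstep <- function(y, x, resp, sd_floor) {
  k <- ncol(resp)
  weights <- colMeans(resp)
  intercepts <- slopes <- sds <- numeric(k)
  for (j in seq_len(k)) {
    w <- resp[, j]
    ab <- wls_line(y, x, w)
    intercepts[j] <- ab[1]
    slopes[j] <- ab[2]
    r <- y - ab[1] - ab[2] * x
    sds[j] <- max(sqrt(sum(w * r^2) / sum(w)), sd_floor)
  }
  list(weights = weights, intercepts = intercepts, slopes = slopes, sds = sds)
}

# closed-form weighted least squares line; degenerate x collapses to the
# weighted mean (slope 0)
wls_line <- function(y, x, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  sxx <- sum(w * (x - mx)^2)
  if (sxx < 1e-12) return(c(my, 0))
  b <- sum(w * (x - mx) * (y - my)) / sxx
  c(my - b * mx, b)
}

new_mixreg_fit <- function(weights, intercepts, slopes, sds, resp, ll, n,
                           converged, n_iter, seed, ll_history) {
  k <- length(weights)
  np <- mixreg_n_params(k)
  structure(list(
    components = tibble::tibble(
      component = seq_len(k),
      weight = as.numeric(weights / sum(weights)),
      intercept = as.numeric(intercepts),
      slope = as.numeric(slopes),
      residual_sd = as.numeric(sds)
    ),
    responsibilities = resp,
    labels = max.col(resp, ties.method = "first"),
    log_likelihood = ll,
    bic = bic(ll, np, n),
    n_params = np,
    n_obs = n,
    converged = converged,
    n_iter = n_iter,
    seed = seed,
    ll_history = ll_history
  ), class = "mixreg_fit")
}

mixreg_n_params <- function(k) as.integer(3L * k + (k - 1L))

#' Bayesian Information Criterion
#'
#' `-2 * log_likelihood + n_params * log(n)`; for a K-component mixture of
#' regressions the parameter count is `3K + (K - 1)` (intercept, slope and
#' residual SD per component plus K - 1 free mixing weights).
#'
#' @param log_likelihood Maximized log-likelihood of the fit.
#' @param n_params Number of free parameters.
#' @param n Number of observations, at least 1.
#' @return The BIC value (smaller is better).
#' @examples
#' bic(-100, 5, 100) # 200 + 5 * log(100)
#' @export
bic <- function(log_likelihood, n_params, n) {
  stopifnot(n >= 1, n_params >= 1)
  -2 * log_likelihood + n_params * log(n)
}

#' Select the number of mixture components by BIC
#'
#' For each component count `k` in `1..k_max`, runs `nrep` EM fits from
#' distinct deterministic sub-seeds, keeps the best log-likelihood per `k`,
#' and returns the candidate minimizing BIC. Ties (within 1e-9) go to the
#' smaller component count. `k = 1` is deterministic, so it is fitted once.
#' A `k` whose fits all error (e.g. too few samples) is skipped; fits that
#' ran out of iterations still compete with their achieved likelihood.
#'
#' @inheritParams fit_em
#' @param k_max Largest component count to consider (1–3).
#' @param nrep Number of random restarts per component count.
#' @return The winning `mixreg_fit`.
#' @examples
#' x <- runif(80, 0.1, 0.8)
#' y <- ifelse(seq_len(80) %% 2 == 0, 0.05 + 0.9 * x, 0.9 + rnorm(80, 0, 0.01))
#' select_model(y, x, seed = 7)$components
#' @export
select_model <- function(y, x, k_max = 3L, nrep = 3L, seed = 1L,
                         max_iter = 200L, tol = 1e-6, min_weight = 0.05,
                         sd_floor = 1e-4) {
  stopifnot(k_max >= 1, k_max <= 3, nrep >= 1)
  best <- NULL
  for (k in seq_len(k_max)) {
    reps <- if (k == 1L) 1L else nrep
    best_k <- NULL
    for (r in seq_len(reps)) {
      f <- tryCatch(
        fit_em(y, x, k, seed = subseed(seed, k, r), max_iter = max_iter,
               tol = tol, min_weight = min_weight, sd_floor = sd_floor),
        error = function(e) NULL
      )
      if (is.null(f)) next
      if (is.null(best_k) || f$log_likelihood > best_k$log_likelihood) best_k <- f
    }
    if (is.null(best_k)) next
    if (is.null(best) || best_k$bic < best$bic - 1e-9) best <- best_k
  }
  if (is.null(best)) stop("no component count could be fitted")
  best
}

#' @export
print.mixreg_fit <- function(x, ...) {
  k <- nrow(x$components)
  cat(sprintf(
    "Mixture of %d linear regression%s (n = %d)\n", k,
    if (k == 1) "" else "s", x$n_obs
  ))
  print(x$components)
  cat(sprintf(
    "logLik %.3f | BIC %.3f | %s in %d iteration%s\n",
    x$log_likelihood, x$bic,
    if (x$converged) "converged" else "not converged",
    x$n_iter, if (x$n_iter == 1) "" else "s"
  ))
  invisible(x)
}

#' Tidy a mixture-of-regressions fit
#'
#' @param x A `mixreg_fit`.
#' @param ... Unused.
#' @return A tibble with one row per component: weight, intercept, slope and
#'   residual SD.
#' @exportS3Method generics::tidy
tidy.mixreg_fit <- function(x, ...) x$components

#' One-row summary of a mixture-of-regressions fit
#'
#' @param x A `mixreg_fit`.
#' @param ... Unused.
#' @return A one-row tibble: component count, log-likelihood, BIC, parameter
#'   count, iterations and convergence flag.
#' @exportS3Method generics::glance
glance.mixreg_fit <- function(x, ...) {
  tibble::tibble(
    k = nrow(x$components),
    log_likelihood = x$log_likelihood,
    bic = x$bic,
    n_params = x$n_params,
    n_obs = x$n_obs,
    n_iter = x$n_iter,
    converged = x$converged
  )
}
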