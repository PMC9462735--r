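#' Purity-adjust a single CpG
#'
#' The full per-CpG correction: (1) a small amount of seeded Gaussian noise
#' (`N(0, noise_sd^2)`, default SD 0.005) is added to a working copy of the
#' beta values to stop zero-variance populations from dominating model
#' selection — the noisy copy is used only for population discovery; (2)
#' [select_model()] is run on the noisy betas against `1 - purity` to find up
#' to `k_max` sample populations; (3) each population is refitted by ordinary
#' least squares on the ORIGINAL betas, once against `1 - purity` (intercept =
#' pure-tumor methylation state) and once against purity (intercept = inferred
#' normal state); (4) residuals of each fit are added back to its intercept,
#' preserving within-population variation; (5) values outside `[0, 1]` are
#' clamped to 0 and 1.
#'
#' Populations left with fewer than 3 members after hard assignment cannot
#' support a line fit and are merged into the population with the nearest
#' mixture intercept before detrending. Samples with missing beta are
#' excluded from all fits and emitted as `NA`.
#'
#' @param beta Numeric vector of beta values in `[0, 1]` (may contain `NA`),
#'   at least 10 non-missing.
#' @param purity Per-sample tumor purity in `(0, 1]`, same length as `beta`
#'   (or named and matching `names(beta)`).
#' @param seed Integer seed controlling the discovery noise and EM restarts.
#' @param noise_sd SD of the Gaussian noise used for population discovery
#'   only; 0 disables it.
#' @param k_max,nrep,max_iter,tol,min_weight Passed to [select_model()].
#' @return An object of class `cpg_adjustment`: per-sample `tumor_beta` and
#'   `normal_beta` (clamped), their pre-clamp versions `tumor_pre` /
#'   `normal_pre`, population `labels`, `k_selected`, per-population
#'   `tumor_fit` and `normal_fit` tibbles (intercept, slope, n), the winning
#'   `mixreg_fit` (`fit`), and the `seed`.
#' @examples
#' p <- runif(60, 0.2, 0.9)
#' b <- 0.2 + 0.5 * (1 - p) + rnorm(60, 0, 0.01)
#' adj <- adjust_cpg(pmin(pmax(b, 0), 1), p, seed = 11)
#' mean(adj$tumor_beta) # close to the pure-tumor state 0.2
#' @export
adjust_cpg <- function(beta, purity, seed = 1L, noise_sd = 0.005,
                       k_max = 3L, nrep = 3L, max_iter = 200L, tol = 1e-6,
                       min_weight = 0.05) {
  purity <- align_purity(purity, names(beta), length(beta))
  check_beta_range(beta)
  check_purity_range(purity)

  ok <- !is.na(beta)
  if (sum(ok) < 10) stop("need at least 10 non-missing beta values")
  b <- beta[ok]
  p <- purity[ok]
  x <- 1 - p

  noisy <- if (noise_sd > 0) {
    b + withr::with_seed(seed, rnorm(length(b), 0, noise_sd))
  } else b
  fit <- select_model(noisy, x, k_max = k_max, nrep = nrep,
                      seed = mix31(seed + 1), max_iter = max_iter, tol = tol,
                      min_weight = min_weight)
  lab <- merge_tiny_populations(fit$labels, fit$components$intercept, min_n = 3L)

  n_all <- length(beta)
  tumor_pre <- normal_pre <- rep(NA_real_, n_all)
  labels <- rep(NA_integer_, n_all)
  pops <- sort(unique(lab))
  tfit <- nfit <- vector("list", length(pops))
  for (i in seq_along(pops)) {
    sel <- lab == pops[i]
    t_ab <- wls_line(b[sel], x[sel], rep(1, sum(sel)))
    n_ab <- wls_line(b[sel], p[sel], rep(1, sum(sel)))
    idx <- which(ok)[sel]
    tumor_pre[idx] <- t_ab[1] + (b[sel] - t_ab[1] - t_ab[2] * x[sel])
    normal_pre[idx] <- n_ab[1] + (b[sel] - n_ab[1] - n_ab[2] * p[sel])
    labels[idx] <- i
    tfit[[i]] <- c(intercept = t_ab[1], slope = t_ab[2], n = sum(sel))
    nfit[[i]] <- c(intercept = n_ab[1], slope = n_ab[2], n = sum(sel))
  }

  structure(list(
    tumor_beta = clamp01(tumor_pre),
    normal_beta = clamp01(normal_pre),
    tumor_pre = tumor_pre,
    normal_pre = normal_pre,
    labels = labels,
    k_selected = length(pops),
    tumor_fit = fit_table(tfit),
    normal_fit = fit_table(nfit),
    fit = fit,
    beta = beta,
    purity = purity,
    seed = as.integer(seed)
  ), class = "cpg_adjustment")
}

fit_table <- function(lst) {
  tibble::tibble(
    population = seq_along(lst),
    intercept = vapply(lst, `[[`, numeric(1), "intercept"),
    slope = vapply(lst, `[[`, numeric(1), "slope"),
    n = as.integer(vapply(lst, `[[`, numeric(1), "n"))
  )
}

# merge populations with < min_n members into the one with the closest
# mixture intercept (tiny groups cannot support OLS)
merge_tiny_populations <- function(labels, intercepts, min_n = 3L) {
  repeat {
    counts <- tabulate(labels, nbins = length(intercepts))
    present <- which(counts > 0)
    if (length(present) <= 1L) return(labels)
    tiny <- present[counts[present] < min_n]
    if (length(tiny) == 0L) return(labels)
    donor <- tiny[which.min(counts[tiny])]
    others <- setdiff(present, donor)
    target <- others[which.min(abs(intercepts[others] - intercepts[donor]))]
    labels[labels == donor] <- target
  }
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Single-population purity detrending
#'
#' The comparison baseline that treats the whole cohort as one population
#' (no mixture discovery, no discovery noise): one OLS fit of beta on
#' `1 - purity` whose intercept is the pure-tumor state, one on purity whose
#' intercept is the inferred normal state, residuals re-added, clamped to
#' `[0, 1]`. Equivalent to [adjust_cpg()] whenever model selection returns a
#' single population.
#'
#' @inheritParams adjust_cpg
#' @return A list with `tumor` and `normal` per-sample vectors.
#' @export
single_population_adjust <- function(beta, purity) {
  purity <- align_purity(purity, names(beta), length(beta))
  check_beta_range(beta)
  check_purity_range(purity)
  ok <- !is.na(beta)
  if (sum(ok) < 10) stop("need at least 10 non-missing beta values")
  b <- beta[ok]
  p <- purity[ok]
  t_ab <- wls_line(b, 1 - p, rep(1, length(b)))
  n_ab <- wls_line(b, p, rep(1, length(b)))
  tumor <- normal <- rep(NA_real_, length(beta))
  tumor[ok] <- t_ab[1] + (b - t_ab[1] - t_ab[2] * (1 - p))
  normal[ok] <- n_ab[1] + (b - n_ab[1] - n_ab[2] * p)
  list(tumor = clamp01(tumor), normal = clamp01(normal))
}

#' Purity-adjust a whole beta matrix
#'
#' Applies [adjust_cpg()] to every row of a CpGs-by-samples beta matrix.
#' Each CpG gets its own seed from [derive_cpg_seed()], so output is
#' bit-identical for any `n_workers` and any scheduling order. A CpG whose
#' fit fails is emitted unadjusted with a failure flag in the fit summary;
#' the run never aborts mid-matrix.
#'
#' @param betas Numeric matrix, CpGs as rows and samples as columns, entries
#'   in `[0, 1]` or `NA`, with unique row and column names.
#' @param purity Named per-sample purity vector in `(0, 1]` covering every
#'   column of `betas` (or unnamed of matching length).
#' @param global_seed Integer master seed.
#' @param n_workers Number of forked workers (1 = serial).
#' @inheritParams adjust_cpg
#' @return An object of class `beta_adjustment`: `tumor` and `normal`
#'   matrices with the input's dimnames, an integer `populations` label
#'   matrix, and a per-CpG `fit_summary` tibble (cpg_id, seed, failed,
#'   k_selected, log-likelihood, BIC, convergence, per-population intercepts
#'   and slopes as comma-separated audit strings, and any error message).
#' @examples
#' sim <- simulate_cohort(n_samples = 40, n_cpgs = 5, seed = 3)
#' res <- adjust_matrix(sim$observed, sim$purity, global_seed = 3)
#' res$fit_summary
#' @export
adjust_matrix <- function(betas, purity, global_seed = 1L, n_workers = 1L,
                          noise_sd = 0.005, k_max = 3L, nrep = 3L,
                          max_iter = 200L, tol = 1e-6, min_weight = 0.05) {
  check_beta_matrix(betas)
  purity <- align_purity(purity, colnames(betas), ncol(betas))
  check_purity_range(purity)

  run_row <- function(i) {
    s <- derive_cpg_seed(global_seed, i - 1L)
    tryCatch({
      adj <- adjust_cpg(betas[i, ], purity, seed = s, noise_sd = noise_sd,
                        k_max = k_max, nrep = nrep, max_iter = max_iter,
                        tol = tol, min_weight = min_weight)
      list(ok = TRUE, seed = s, adj = adj)
    }, error = function(e) {
      list(ok = FALSE, seed = s, message = conditionMessage(e))
    })
  }

  rows <- seq_len(nrow(betas))
  res <- if (n_workers > 1L) {
    parallel::mclapply(rows, run_row, mc.cores = n_workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(rows, run_row)
  }

  n_cpg <- nrow(betas)
  tumor <- normal <- betas
  populations <- matrix(NA_integer_, n_cpg, ncol(betas),
                        dimnames = dimnames(betas))
  summ <- vector("list", n_cpg)
  for (i in rows) {
    r <- res[[i]]
    id <- rownames(betas)[i]
    if (r$ok) {
      a <- r$adj
      tumor[i, ] <- a$tumor_beta
      normal[i, ] <- a$normal_beta
      populations[i, ] <- a$labels
      summ[[i]] <- tibble::tibble(
        cpg_id = id, seed = r$seed, failed = FALSE,
        k_selected = a$k_selected,
        log_likelihood = a$fit$log_likelihood, bic = a$fit$bic,
        converged = a$fit$converged,
        tumor_intercepts = paste(signif(a$tumor_fit$intercept, 6), collapse = ","),
        tumor_slopes = paste(signif(a$tumor_fit$slope, 6), collapse = ","),
        normal_intercepts = paste(signif(a$normal_fit$intercept, 6), collapse = ","),
        pop_sizes = paste(a$tumor_fit$n, collapse = ","),
        message = NA_character_
      )
    } else {
      summ[[i]] <- tibble::tibble(
        cpg_id = id, seed = r$seed, failed = TRUE,
        k_selected = NA_integer_, log_likelihood = NA_real_, bic = NA_real_,
        converged = NA, tumor_intercepts = NA_character_,
        tumor_slopes = NA_character_, normal_intercepts = NA_character_,
        pop_sizes = NA_character_, message = r$message
      )
    }
  }

  structure(list(
    tumor = tumor,
    normal = normal,
    populations = populations,
    fit_summary = dplyr::bind_rows(summ),
    global_seed = as.integer(global_seed),
    noise_sd = noise_sd
  ), class = "beta_adjustment")
}

#' @export
print.beta_adjustment <- function(x, ...) {
  ks <- table(factor(x$fit_summary$k_selected, levels = 1:3))
  cat(sprintf(
    "Purity-adjusted beta matrix: %d CpGs x %d samples (seed %d)\n",
    nrow(x$tumor), ncol(x$tumor), x$global_seed
  ))
  cat(sprintf("populations selected: K=1: %d, K=2: %d, K=3: %d; failed: %d\n",
              ks[1], ks[2], ks[3], sum(x$fit_summary$failed)))
  invisible(x)
}

#' @export
print.cpg_adjustment <- function(x, ...) {
  cat(sprintf("CpG adjustment: %d samples, %d population%s (seed %d)\n",
              length(x$beta), x$k_selected,
              if (x$k_selected == 1) "" else "s", x$seed))
  print(dplyr::left_join(
    dplyr::rename(x$tumor_fit, tumor_intercept = "intercept",
                  tumor_slope = "slope"),
    dplyr::select(dplyr::rename(x$normal_fit,
                                normal_intercept = "intercept"),
                  "population", "normal_intercept"),
    by = "population"
  ))
  invisible(x)
}

#' Plot a per-CpG adjustment
#'
#' Scatter of beta against 1 - purity coloured by discovered population,
#' with the per-population tumor line fits; the intercept at `1 - purity = 0`
#' is the pure-tumor state and the value at 1 is the inferred normal state.
#'
#' @param object A `cpg_adjustment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cpg_adjustment <- function(object, ...) {
  df <- tibble::tibble(
    x = 1 - object$purity,
    beta = object$beta,
    population = factor(object$labels)
  )
  fits <- object$tumor_fit
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$beta,
                                   colour = .data$population)) +
    ggplot2::geom_point(alpha = 0.7, na.rm = TRUE) +
    ggplot2::geom_abline(
      data = fits,
      ggplot2::aes(intercept = .data$intercept, slope = .data$slope,
                   colour = factor(.data$population))
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "1 - tumor purity", y = "beta value",
                  colour = "population") +
    ggplot2::theme_minimal()
}

# ---- shared validation helpers ----

align_purity <- function(purity, sample_ids, n) {
  if (!is.null(names(purity)) && !is.null(sample_ids)) {
    missing <- setdiff(sample_ids, names(purity))
    if (length(missing) > 0) {
      stop("samples missing from purity table: ",
           paste(missing, collapse = ", "))
    }
    purity <- purity[sample_ids]
  }
  if (length(purity) != n) stop("purity length does not match sample count")
  unname(purity)
}

check_purity_range <- function(purity) {
  if (any(!is.finite(purity)) || any(purity <= 0) || any(purity > 1)) {
    stop("purity values must lie in (0, 1]")
  }
  invisible(purity)
}

check_beta_range <- function(beta) {
  v <- beta[!is.na(beta)]
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
    stop("beta values must lie in [0, 1]")
  }
  invisible(beta)
}

check_beta_matrix <- function(betas) {
  if (!is.matrix(betas) || !is.numeric(betas)) {
    stop("betas must be a numeric matrix (CpGs x samples)")
  }
  if (is.null(rownames(betas)) || anyDuplicated(rownames(betas))) {
    stop("betas must have unique row names (CpG ids)")
  }
  if (is.null(colnames(betas)) || anyDuplicated(colnames(betas))) {
    stop("betas must have unique column names (sample ids)")
  }
  check_beta_range(betas)
}
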