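#' Hierarchical clustering split of samples
#'
#' Agglomerative hierarchical clustering of samples (columns) using
#' 1 - Pearson correlation of their CpG profiles as the distance and Ward's
#' linkage, with the tree cut into `n_clusters` groups — the standard
#' methylation subtype clustering recipe. Constant sample profiles make the
#' Pearson distance undefined; such columns are jittered by a deterministic
#' 1e-9 ramp with a warning.
#'
#' @param betas Numeric matrix, CpGs as rows and samples as columns.
#' @param n_clusters Number of groups to cut the tree into.
#' @return Integer cluster labels named by sample id.
#' @export
hierarchical_split <- function(betas, n_clusters = 2L) {
  stopifnot(is.matrix(betas), ncol(betas) >= n_clusters)
  const <- apply(betas, 2, function(v) sd(v, na.rm = TRUE) == 0 || all(is.na(v)))
  if (any(const)) {
    warning(sprintf("%d constant sample profile(s) jittered by 1e-9", sum(const)))
    ramp <- 1e-9 * seq_len(nrow(betas))
    betas[, const] <- betas[, const, drop = FALSE] + ramp
  }
  d <- stats::as.dist(1 - cor(betas, use = "pairwise.complete.obs"))
  hc <- hclust(d, method = "ward.D2")
  cutree(hc, k = n_clusters)
}

#' Evaluate a binary clustering split against known labels
#'
#' Compares a two-group clustering with binary truth labels (e.g. the
#' top-level tree split vs Basal / non-Basal subtype). Cluster indices are
#' arbitrary, so both cluster-to-class mappings are evaluated and the one
#' maximizing accuracy is reported; accuracy is therefore always at least
#' 0.5. Sensitivity and specificity treat `positive` as the class of
#' interest.
#'
#' @param cluster_labels Two-valued cluster assignment per sample.
#' @param truth_labels Two-valued true class per sample, same length/order.
#' @param positive The truth level counted as positive (default: last level,
#'   e.g. "Basal" in a Basal / non-Basal contrast sorted alphabetically).
#' @return An object of class `split_metrics`: accuracy, sensitivity,
#'   specificity, the 2x2 `confusion` matrix (clusters mapped to classes),
#'   and the `mapping` used.
#' @examples
#' split_metrics(c(1, 1, 2, 2), c("B", "B", "A", "A"), positive = "B")
#' @export
split_metrics <- function(cluster_labels, truth_labels, positive = NULL) {
  cl <- factor(cluster_labels)
  tr <- factor(truth_labels)
  if (nlevels(cl) != 2 || nlevels(tr) != 2) {
    stop("split_metrics requires exactly two clusters and two classes")
  }
  if (length(cl) != length(tr)) stop("label vectors differ in length")
  if (is.null(positive)) positive <- levels(tr)[2]
  if (!positive %in% levels(tr)) stop("positive class not found in truth labels")
  negative <- setdiff(levels(tr), positive)

  best <- NULL
  for (map in list(setNames(c(positive, negative), levels(cl)),
                   setNames(c(negative, positive), levels(cl)))) {
    pred <- factor(unname(map[as.character(cl)]), levels = c(negative, positive))
    acc <- mean(pred == tr)
    if (is.null(best) || acc > best$accuracy) {
      tp <- sum(pred == positive & tr == positive)
      fn <- sum(pred == negative & tr == positive)
      fp <- sum(pred == positive & tr == negative)
      tn <- sum(pred == negative & tr == negative)
      best <- list(
        accuracy = acc,
        sensitivity = tp / (tp + fn),
        specificity = tn / (tn + fp),
        confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                           dimnames = list(predicted = c(positive, negative),
                                           truth = c(positive, negative))),
        mapping = map
      )
    }
  }
  structure(best, class = "split_metrics")
}

#' @export
print.split_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.3f | sensitivity %.3f | specificity %.3f\n",
              x$accuracy, x$sensitivity, x$specificity))
  print(x$confusion)
  invisible(x)
}

#' Dichotomize beta values
#'
#' The baseline preprocessing that thresholds betas to binary methylation
#' calls: 1 if beta is strictly greater than `threshold`, else 0. `NA`
#' propagates.
#'
#' @param betas Numeric matrix or vector of beta values.
#' @param threshold Strict cut point, default 0.3.
#' @return Binary matrix/vector of the same shape.
#' @export
dichotomize <- function(betas, threshold = 0.3) {
  out <- (betas > threshold) * 1
  out
}

#' Correlate inferred normal profiles to a reference normal
#'
#' Per-sample Pearson correlation across CpGs between each inferred normal
#' profile and a reference per-CpG mean methylation (e.g. the average of
#' bona fide normal tissue samples). Used to validate that the extrapolated
#' normal background recapitulates real normal methylomes.
#'
#' @param inferred_normal Numeric matrix, CpGs as rows and samples as
#'   columns, with CpG row names.
#' @param reference_mean Named (or aligned) per-CpG reference vector; names,
#'   if present, must match the matrix row names as a set.
#' @return A tibble with `sample` and `r`, carrying the cohort summary as
#'   attributes `median_r` (median of per-sample r) and `mean_vs_mean_r`
#'   (r between the row-mean inferred profile and the reference).
#' @export
correlation_to_reference <- function(inferred_normal, reference_mean) {
  stopifnot(is.matrix(inferred_normal), nrow(inferred_normal) >= 3)
  if (!is.null(names(reference_mean))) {
    if (!setequal(names(reference_mean), rownames(inferred_normal))) {
      stop("CpG sets of inferred matrix and reference do not match")
    }
    reference_mean <- reference_mean[rownames(inferred_normal)]
  } else if (length(reference_mean) != nrow(inferred_normal)) {
    stop("reference length does not match number of CpGs")
  }
  r <- apply(inferred_normal, 2, cor, y = reference_mean,
             use = "pairwise.complete.obs")
  out <- tibble::tibble(sample = colnames(inferred_normal), r = unname(r))
  attr(out, "median_r") <- median(r, na.rm = TRUE)
  attr(out, "mean_vs_mean_r") <- cor(rowMeans(inferred_normal, na.rm = TRUE),
                                     reference_mean,
                                     use = "pairwise.complete.obs")
  out
}

#' Trimodal binning of methylation values
#'
#' Bins per-CpG values into hypomethylated, intermediate (the hemimethylated
#' X-inactivation state in the X-chromosome application) and hypermethylated
#' categories by two cut points. The expected X-promoter beta distribution
#' in females is trimodal with peaks near 0, 0.5 and 1.
#'
#' @param values Numeric vector in `[0, 1]`.
#' @param cut_low,cut_high Cut points with `0 < cut_low < cut_high < 1`;
#'   values below `cut_low` are "hypo", values at or above `cut_high` are
#'   "hyper", the rest "intermediate".
#' @return A list with `labels` (factor hypo/intermediate/hyper) and
#'   `fractions` (named proportions over non-missing values).
#' @export
trimodal_bins <- function(values, cut_low = 0.25, cut_high = 0.75) {
  if (!(cut_low > 0 && cut_high < 1 && cut_low < cut_high)) {
    stop("cuts must satisfy 0 < cut_low < cut_high < 1")
  }
  lab <- cut(values, breaks = c(-Inf, cut_low, cut_high, Inf),
             labels = c("hypo", "intermediate", "hyper"), right = FALSE)
  # boundary convention: exactly cut_low is intermediate, exactly cut_high is hyper
  list(labels = lab,
       fractions = prop.table(table(lab)))
}

#' Bin-level concordance of two binned vectors
#'
#' Fraction of positions assigned to the same trimodal bin in both vectors.
#'
#' @param a,b Numeric vectors of equal length.
#' @inheritParams trimodal_bins
#' @return A single fraction in `[0, 1]`.
#' @export
bin_concordance <- function(a, b, cut_low = 0.25, cut_high = 0.75) {
  stopifnot(length(a) == length(b))
  la <- trimodal_bins(a, cut_low, cut_high)$labels
  lb <- trimodal_bins(b, cut_low, cut_high)$labels
  mean(la == lb, na.rm = TRUE)
}

# best-mapping agreement between two label vectors with at most 3 levels;
# labels are arbitrary so all injective mappings from b-labels to a-labels
# (plus unmatched levels) are enumerated
label_concordance <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  la <- sort(unique(a)); lb <- sort(unique(b))
  if (length(lb) > length(la)) { tmp <- a; a <- b; b <- tmp
    tmp <- la; la <- lb; lb <- tmp }
  perms <- all_permutations(seq_along(la))
  best <- 0
  for (p in perms) {
    map <- setNames(la[p][seq_along(lb)], lb)
    best <- max(best, mean(unname(map[as.character(b)]) == a))
  }
  best
}

all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_permutations(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

#' Robustness of beta adjustment to noisy purity estimates
#'
#' Quantifies how the correction degrades as purity estimates deteriorate.
#' A baseline adjustment is computed with the given purity, then for every
#' noise level `s` in `grid` and every replicate the purity vector is
#' perturbed with `N(0, s^2)` noise ([perturb_purity()]), the adjustment is
#' re-run, and four similarities with the unperturbed run are recorded:
#'
#' * `pop_concordance` — mean per-CpG concordance of population calls after
#'   optimal label matching,
#' * `sample_cor` — median per-sample Pearson correlation of adjusted betas,
#' * `normal_cor` — median per-sample correlation of inferred normal
#'   profiles to the reference mean (default: the baseline's per-CpG mean
#'   inferred normal),
#' * `beta_shift` — mean absolute difference between adjusted and input
#'   betas, i.e. the magnitude of the correction itself.
#'
#' @inheritParams adjust_matrix
#' @param grid Noise SDs to test, e.g. `noise_grid(0.01, 0.19, 0.02)`.
#' @param n_reps Replicates per noise level.
#' @param reference_mean Optional per-CpG reference normal means.
#' @param ... Passed on to [adjust_matrix()].
#' @return An object of class `perturbation_decay`: `per_rep` tibble
#'   (s, rep, the four metrics) and `summary` tibble (per s: median and
#'   empirical 95% interval of each metric).
#' @export
perturbation_decay <- function(betas, purity, grid, n_reps = 5L,
                               global_seed = 1L, n_workers = 1L,
                               reference_mean = NULL, ...) {
  if (length(grid) == 0) stop("grid must be non-empty")
  base <- adjust_matrix(betas, purity, global_seed = global_seed,
                        n_workers = n_workers, ...)
  if (is.null(reference_mean)) {
    reference_mean <- rowMeans(base$normal, na.rm = TRUE)
  }

  rows <- list()
  for (si in seq_along(grid)) {
    s <- grid[si]
    for (rep in seq_len(n_reps)) {
      pseed <- mix31(mix31(global_seed + 131 * si) + rep)
      p2 <- perturb_purity(purity, s, seed = pseed)
      run <- adjust_matrix(betas, p2, global_seed = global_seed,
                           n_workers = n_workers, ...)
      conc <- vapply(seq_len(nrow(betas)), function(i) {
        label_concordance(base$populations[i, ], run$populations[i, ])
      }, numeric(1))
      scor <- vapply(seq_len(ncol(betas)), function(j) {
        cor(base$tumor[, j], run$tumor[, j], use = "pairwise.complete.obs")
      }, numeric(1))
      ncor <- vapply(seq_len(ncol(betas)), function(j) {
        cor(run$normal[, j], reference_mean, use = "pairwise.complete.obs")
      }, numeric(1))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        s = s, rep = rep,
        pop_concordance = mean(conc, na.rm = TRUE),
        sample_cor = median(scor, na.rm = TRUE),
        normal_cor = median(ncor, na.rm = TRUE),
        beta_shift = mean(abs(run$tumor - betas), na.rm = TRUE),
        n_failed = sum(run$fit_summary$failed)
      )
    }
  }
  per_rep <- dplyr::bind_rows(rows)
  summary <- per_rep |>
    tidyr::pivot_longer(c("pop_concordance", "sample_cor", "normal_cor",
                          "beta_shift"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$s, .data$metric) |>
    dplyr::summarise(
      median = median(.data$value, na.rm = TRUE),
      lower = quantile(.data$value, 0.025, na.rm = TRUE, names = FALSE),
      upper = quantile(.data$value, 0.975, na.rm = TRUE, names = FALSE),
      .groups = "drop"
    )
  structure(list(per_rep = per_rep, summary = summary,
                 grid = grid, n_reps = n_reps),
            class = "perturbation_decay")
}

#' @export
print.perturbation_decay <- function(x, ...) {
  cat(sprintf("Purity perturbation decay: %d noise levels x %d replicates\n",
              length(x$grid), x$n_reps))
  print(x$summary)
  invisible(x)
}

#' Plot perturbation-decay curves
#'
#' Median metric per noise level with the empirical 95% band.
#'
#' @param object A `perturbation_decay` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.perturbation_decay <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$s, y = .data$median,
                               colour = .data$metric, fill = .data$metric)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "purity noise SD (s)", y = "metric value") +
    ggplot2::theme_minimal()
}
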