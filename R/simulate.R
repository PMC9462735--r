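#' Simulate a synthetic tumor methylation cohort
#'
#' Generates cohorts with exactly the statistical structure the correction
#' assumes: at each CpG, every sample belongs to one of K latent tumor
#' populations (K drawn from `k_probs`), each population has a pure-tumor
#' methylation state, all populations at a CpG share one normal-background
#' state, and the observed beta is the purity-weighted mixture
#' `purity * tumor_state + (1 - purity) * normal_state` plus Gaussian
#' measurement noise, clamped to `[0, 1]`. When K > 1 the tumor states drawn
#' for a CpG are distinct levels separated by at least 0.2, mirroring the
#' well-separated populations (e.g. hyper- vs unmethylated promoters) the
#' method is designed to resolve.
#'
#' Defaults mirror a purity-confounded breast-cancer-like cohort: 630
#' samples, purity uniform on (0.2, 0.95), measurement noise SD 0.03, tumor
#' states on \{0, 0.5, 1\} and normal states on \{0, 0.3, 0.7\}.
#'
#' @param n_samples Number of samples (at least 20).
#' @param n_cpgs Number of CpGs.
#' @param k_probs Probabilities for K = 1, 2, 3 latent populations; must sum
#'   to 1.
#' @param purity_range Lower/upper bound of the uniform purity distribution
#'   (within (0, 1]).
#' @param noise_sd SD of the Gaussian measurement noise (>= 0).
#' @param state_levels Allowed pure-tumor beta levels.
#' @param normal_levels Allowed normal-background beta levels.
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @return An object of class `synthetic_cohort`: `observed` beta matrix
#'   (CpGs x samples), named `purity` vector, `true_tumor_states` (n_cpgs x 3
#'   matrix, NA beyond the CpG's K), `true_normal_states`, `true_labels`
#'   (CpGs x samples), `true_k`, and `params`.
#' @examples
#' sim <- simulate_cohort(n_samples = 40, n_cpgs = 10, seed = 1)
#' range(sim$observed)
#' @export
simulate_cohort <- function(n_samples = 630L, n_cpgs = 500L,
                            k_probs = c(0.4, 0.4, 0.2),
                            purity_range = c(0.2, 0.95), noise_sd = 0.03,
                            state_levels = c(0, 0.5, 1),
                            normal_levels = c(0, 0.3, 0.7), seed = 1L) {
  stopifnot(n_samples >= 20, n_cpgs >= 1, noise_sd >= 0)
  if (length(k_probs) != 3 || any(k_probs < 0) ||
      abs(sum(k_probs) - 1) > 1e-8) {
    stop("k_probs must be 3 non-negative probabilities summing to 1")
  }
  if (purity_range[1] <= 0 || purity_range[2] > 1 ||
      purity_range[1] > purity_range[2]) {
    stop("purity_range must lie within (0, 1]")
  }
  k_possible <- max(which(k_probs > 0))
  if (length(state_levels) < k_possible) {
    stop("state_levels has too few levels for the requested k distribution")
  }

  withr::with_seed(seed, {
    sample_ids <- sprintf("s%04d", seq_len(n_samples))
    cpg_ids <- sprintf("cg%07d", seq_len(n_cpgs))
    purity <- setNames(runif(n_samples, purity_range[1], purity_range[2]),
                       sample_ids)

    true_k <- sample(1:3, n_cpgs, replace = TRUE, prob = k_probs)
    true_tumor <- matrix(NA_real_, n_cpgs, 3)
    true_normal <- numeric(n_cpgs)
    labels <- matrix(NA_integer_, n_cpgs, n_samples,
                     dimnames = list(cpg_ids, sample_ids))
    observed <- matrix(NA_real_, n_cpgs, n_samples,
                       dimnames = list(cpg_ids, sample_ids))

    for (i in seq_len(n_cpgs)) {
      k <- true_k[i]
      states <- draw_separated_states(state_levels, k, min_sep = 0.2)
      true_tumor[i, seq_len(k)] <- states
      true_normal[i] <- pick(normal_levels)
      lab <- sample(seq_len(k), n_samples, replace = TRUE)
      # guarantee every population is represented
      lab[seq_len(k)] <- seq_len(k)
      labels[i, ] <- lab
      mu <- purity * states[lab] + (1 - purity) * true_normal[i]
      observed[i, ] <- clamp01(mu + rnorm(n_samples, 0, noise_sd))
    }

    structure(list(
      observed = observed,
      purity = purity,
      true_tumor_states = true_tumor,
      true_normal_states = true_normal,
      true_labels = labels,
      true_k = true_k,
      params = list(n_samples = n_samples, n_cpgs = n_cpgs,
                    k_probs = k_probs, purity_range = purity_range,
                    noise_sd = noise_sd, state_levels = state_levels,
                    normal_levels = normal_levels, seed = as.integer(seed))
    ), class = "synthetic_cohort")
  })
}

# length-safe sampling (sample() treats a scalar as 1:n)
pick <- function(v, k = 1L) v[sample.int(length(v), k)]

# draw k tumor states pairwise separated by >= min_sep
draw_separated_states <- function(levels, k, min_sep = 0.2) {
  if (k == 1) return(pick(levels))
  repeat {
    s <- pick(levels, k)
    if (min(dist(s)) >= min_sep) return(sort(s))
  }
}

#' Simulate a two-subtype cohort for clustering evaluation
#'
#' Like [simulate_cohort()] but samples carry a global binary subtype (e.g.
#' Basal vs non-Basal). A fraction `frac_informative` of CpGs are
#' subtype-linked: they have two tumor populations whose membership equals
#' the subtype, so the subtype signal is real but diluted by purity in the
#' observed betas. Remaining CpGs behave as in [simulate_cohort()] with
#' subtype-independent populations.
#'
#' @inheritParams simulate_cohort
#' @param frac_informative Fraction of CpGs whose populations follow the
#'   subtype.
#' @param subtype_prob Probability a sample belongs to the positive subtype.
#' @return A `synthetic_cohort` with an extra named `subtype` factor
#'   (levels "A", "B") and logical `informative` per CpG.
#' @export
simulate_subtype_cohort <- function(n_samples = 200L, n_cpgs = 700L,
                                    frac_informative = 0.3,
                                    subtype_prob = 0.5,
                                    k_probs = c(0.6, 0.4, 0),
                                    purity_range = c(0.2, 0.95),
                                    noise_sd = 0.03,
                                    state_levels = c(0, 0.5, 1),
                                    normal_levels = c(0, 0.3, 0.7),
                                    seed = 1L) {
  stopifnot(frac_informative >= 0, frac_informative <= 1)
  base <- simulate_cohort(n_samples, n_cpgs, k_probs, purity_range, noise_sd,
                          state_levels, normal_levels, seed = seed)
  withr::with_seed(mix31(seed + 17), {
    subtype <- factor(ifelse(runif(n_samples) < subtype_prob, "A", "B"),
                      levels = c("A", "B"))
    # ensure both subtypes occur
    subtype[1] <- "A"
    subtype[2] <- "B"
    names(subtype) <- colnames(base$observed)
    informative <- runif(n_cpgs) < frac_informative
    purity <- base$purity
    for (i in which(informative)) {
      states <- draw_separated_states(state_levels, 2, min_sep = 0.2)
      base$true_k[i] <- 2L
      base$true_tumor_states[i, ] <- c(states, NA)
      lab <- as.integer(subtype)
      base$true_labels[i, ] <- lab
      mu <- purity * states[lab] + (1 - purity) * base$true_normal_states[i]
      base$observed[i, ] <- clamp01(mu + rnorm(n_samples, 0, noise_sd))
    }
    base$subtype <- subtype
    base$informative <- informative
    base$params$frac_informative <- frac_informative
    base
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic methylation cohort: %d CpGs x %d samples (seed %d)\n",
    nrow(x$observed), ncol(x$observed), x$params$seed
  ))
  cat(sprintf("K distribution: %s; noise SD %.3f; purity in [%.2f, %.2f]\n",
              paste(table(factor(x$true_k, 1:3)), collapse = "/"),
              x$params$noise_sd, x$params$purity_range[1],
              x$params$purity_range[2]))
  invisible(x)
}

#' Perturb purity estimates with Gaussian noise
#'
#' Adds seeded `N(0, s^2)` noise to every purity value and clips the result
#' to `[0.01, 1]` so perturbed values remain valid purities. Used for the
#' robustness experiments quantifying how beta correction degrades as the
#' purity estimate deteriorates.
#'
#' @param purity Named or unnamed purity vector in `(0, 1]`.
#' @param s Noise SD (>= 0); 0 returns the input unchanged.
#' @param seed Integer seed.
#' @return A purity vector with the same names.
#' @export
perturb_purity <- function(purity, s, seed = 1L) {
  stopifnot(s >= 0)
  if (s == 0) return(purity)
  shifted <- purity + withr::with_seed(seed, rnorm(length(purity), 0, s))
  pmin(pmax(shifted, 0.01), 1)
}

#' Inclusive arithmetic grid of noise levels
#'
#' @param s_min,s_max Grid bounds, `s_min <= s_max`.
#' @param step Positive increment.
#' @return Numeric vector `s_min, s_min + step, ...` up to `s_max`
#'   (inclusive, tolerant of floating-point drift).
#' @examples
#' noise_grid(0.01, 0.19, 0.02) # the 10-point purity perturbation grid
#' @export
noise_grid <- function(s_min, s_max, step) {
  if (step <= 0) stop("step must be positive")
  if (s_min > s_max) stop("s_min must not exceed s_max")
  seq(s_min, s_max + step * 1e-9, by = step)
}
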