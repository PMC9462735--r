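# fixture builders shared across test files

# two latent tumor states (0 and 0.9), shared normal background, the
# well-separated geometry the mixture model is designed to resolve
make_two_pop <- function(n = 200, states = c(0, 0.9), normal = 0,
                         sd = 0.03, seed = 2024) {
  withr::with_seed(seed, {
    x <- runif(n, 0.1, 0.8) # x = 1 - purity
    lab <- rep(seq_along(states), length.out = n)
    y <- states[lab] + (normal - states[lab]) * x + rnorm(n, 0, sd)
    list(y = y, x = x, lab = lab, states = states, normal = normal)
  })
}

# single CpG fixture: beta = purity * state + (1 - purity) * normal + noise
make_cpg <- function(n = 100, state = 0.2, normal = 0.7, sd = 0,
                     purity_range = c(0.2, 0.9), seed = 1) {
  withr::with_seed(seed, {
    p <- runif(n, purity_range[1], purity_range[2])
    b <- p * state + (1 - p) * normal + rnorm(n, 0, sd)
    list(beta = pmin(pmax(b, 0), 1), purity = p, state = state,
         normal = normal)
  })
}

# promoter-hypermethylation-like two-population single CpG: one population
# methylated in the tumor compartment (state near 1), one unmethylated
# (state 0), shared low normal background
make_brca1_like <- function(n = 235, states = c(0, 1), normal = 0.1,
                            sd = 0.03, seed = 42) {
  withr::with_seed(seed, {
    p <- runif(n, 0.2, 0.9)
    lab <- rep(seq_along(states), length.out = n)
    b <- p * states[lab] + (1 - p) * normal + rnorm(n, 0, sd)
    list(beta = pmin(pmax(b, 0), 1), purity = p, lab = lab,
         states = states, normal = normal)
  })
}

# closed-form OLS detrending oracle for the single-population path,
# independent of the package's fitting code
ols_detrend_oracle <- function(beta, purity) {
  x <- 1 - purity
  ft <- stats::lm(beta ~ x)
  fn <- stats::lm(beta ~ purity)
  list(
    tumor = pmin(pmax(unname(coef(ft)[1] + resid(ft)), 0), 1),
    normal = pmin(pmax(unname(coef(fn)[1] + resid(fn)), 0), 1)
  )
}

# best-permutation agreement between two label vectors (independent
# re-implementation used as test oracle for label matching)
perm_accuracy <- function(a, b) {
  la <- unique(a)
  perms <- if (length(la) == 1) list(la) else {
    out <- list()
    rec <- function(v, acc) {
      if (length(v) == 0) out[[length(out) + 1]] <<- acc
      else for (i in seq_along(v)) rec(v[-i], c(acc, v[i]))
    }
    rec(la, c())
    out
  }
  best <- 0
  for (p in perms) {
    map <- stats::setNames(p, la)
    best <- max(best, mean(map[as.character(a)] == b))
  }
  best
}
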