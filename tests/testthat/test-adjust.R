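test_that("a noiseless single-population line is detrended exactly", {
  # beta = 0.2 + 0.5 * (1 - purity): tumor state 0.2, normal state 0.7
  d <- make_cpg(n = 100, state = 0.2, normal = 0.7, sd = 0)
  adj <- adjust_cpg(d$beta, d$purity, seed = 1)
  expect_equal(adj$k_selected, 1L)
  expect_true(all(abs(adj$tumor_beta - 0.2) < 1e-2))
  expect_true(all(abs(adj$normal_beta - 0.7) < 1e-2))
})

test_that("promoter-hypermethylation-like two populations are resolved", {
  d <- make_brca1_like(n = 235, states = c(0, 1), normal = 0.1, sd = 0.03)
  adj <- adjust_cpg(d$beta, d$purity, seed = 9)
  expect_equal(adj$k_selected, 2L)
  expect_gte(perm_accuracy(adj$labels, d$lab), 0.95)
  # purified tumor betas bimodal near {0, 1}
  expect_true(all(adj$tumor_beta < 0.25 | adj$tumor_beta > 0.75))
  # inferred normal recovers the shared background state
  expect_lt(abs(mean(adj$normal_beta) - d$normal), 0.05)
})

test_that("outputs are clamped to [0, 1] on extreme fixtures", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      n <- 60
      p <- runif(n, 0.2, 0.95)
      b <- pmin(pmax(runif(n), 0), 1)
    })
    adj <- adjust_cpg(b, p, seed = seed)
    expect_gte(min(adj$tumor_beta), 0)
    expect_lte(max(adj$tumor_beta), 1)
    expect_gte(min(adj$normal_beta), 0)
    expect_lte(max(adj$normal_beta), 1)
  }
})

test_that("pre-clamp normal minus tumor equals the fitted slope per population", {
  d <- make_brca1_like(n = 120, sd = 0.05)
  adj <- adjust_cpg(d$beta, d$purity, seed = 3)
  for (pop in unique(adj$labels)) {
    sel <- adj$labels == pop
    diffs <- adj$normal_pre[sel] - adj$tumor_pre[sel]
    slope <- adj$tumor_fit$slope[adj$tumor_fit$population == pop]
    expect_true(all(abs(diffs - slope) < 1e-10))
    # tumor intercept equals normal-line prediction at purity = 1
    nf <- adj$normal_fit[adj$normal_fit$population == pop, ]
    expect_equal(adj$tumor_fit$intercept[adj$tumor_fit$population == pop],
                 nf$intercept + nf$slope, tolerance = 1e-10)
  }
})

test_that("residuals re-added agree between the tumor and normal fits", {
  d <- make_cpg(n = 80, state = 0.3, normal = 0.6, sd = 0.04)
  adj <- adjust_cpg(d$beta, d$purity, seed = 5)
  for (pop in unique(adj$labels)) {
    sel <- adj$labels == pop
    rt <- adj$tumor_pre[sel] -
      adj$tumor_fit$intercept[adj$tumor_fit$population == pop]
    rn <- adj$normal_pre[sel] -
      adj$normal_fit$intercept[adj$normal_fit$population == pop]
    expect_true(all(abs(rt - rn) < 1e-10))
  }
})

test_that("swapping the regression covariate swaps tumor and normal outputs", {
  d <- make_cpg(n = 80, state = 0.25, normal = 0.65, sd = 0.03)
  a <- single_population_adjust(d$beta, d$purity)
  # feeding 1 - purity as if it were purity exchanges the two extrapolations
  b <- single_population_adjust(d$beta, 1 - d$purity)
  expect_equal(a$tumor, b$normal, tolerance = 1e-12)
  expect_equal(a$normal, b$tumor, tolerance = 1e-12)
})

test_that("single_population_adjust matches adjust_cpg when one population is selected", {
  d <- make_cpg(n = 100, state = 0.2, normal = 0.6, sd = 0.03)
  adj <- adjust_cpg(d$beta, d$purity, seed = 2)
  expect_equal(adj$k_selected, 1L)
  base <- single_population_adjust(d$beta, d$purity)
  expect_equal(adj$tumor_beta, base$tumor, tolerance = 1e-12)
  expect_equal(adj$normal_beta, base$normal, tolerance = 1e-12)
})

test_that("single-population baseline leaves two-population structure confounded", {
  d <- make_brca1_like(n = 200, states = c(0, 1), normal = 0.1, sd = 0.03)
  multi <- adjust_cpg(d$beta, d$purity, seed = 4)
  single <- single_population_adjust(d$beta, d$purity)
  sep_multi <- abs(diff(tapply(multi$tumor_beta, d$lab, mean)))
  sep_single <- abs(diff(tapply(single$tumor, d$lab, mean)))
  expect_gt(sep_multi, sep_single)
})

test_that("zero-slope input passes through the baseline unchanged", {
  withr::with_seed(1, {
    p <- runif(50, 0.2, 0.9)
    b <- rep(0.4, 50)
  })
  out <- single_population_adjust(b, p)
  expect_equal(out$tumor, b, tolerance = 1e-12)
  expect_equal(out$normal, b, tolerance = 1e-12)
})

test_that("missing betas are excluded from fits and stay missing in outputs", {
  d <- make_cpg(n = 60, state = 0.2, normal = 0.7, sd = 0.02)
  b <- d$beta
  b[c(3, 17)] <- NA
  adj <- adjust_cpg(b, d$purity, seed = 6)
  expect_true(all(is.na(adj$tumor_beta[c(3, 17)])))
  expect_true(all(is.na(adj$normal_beta[c(3, 17)])))
  expect_true(all(!is.na(adj$tumor_beta[-c(3, 17)])))
  # the fit ignores the missing entries entirely
  ref <- adjust_cpg(b[-c(3, 17)], d$purity[-c(3, 17)], seed = 6)
  expect_equal(adj$tumor_beta[-c(3, 17)], ref$tumor_beta, tolerance = 1e-12)
})

test_that("tiny populations are merged before detrending", {
  lab <- c(rep(1L, 20), rep(2L, 2), rep(3L, 10))
  merged <- purebeta:::merge_tiny_populations(lab, c(0.0, 0.1, 0.9))
  expect_true(all(merged[21:22] == 1L)) # nearest intercept is population 1
  expect_true(all(table(merged) >= 3))
  # every population large enough is untouched
  expect_identical(purebeta:::merge_tiny_populations(lab[-(21:22)],
                                                     c(0.0, 0.1, 0.9)),
                   lab[-(21:22)])
})

test_that("adjust_cpg validates inputs", {
  expect_error(adjust_cpg(runif(5), runif(5, 0.2, 1)), "at least 10")
  expect_error(adjust_cpg(c(runif(19), 1.2), runif(20, 0.2, 1)), "\\[0, 1\\]")
  expect_error(adjust_cpg(runif(20), c(runif(19, 0.2, 1), 0)), "purity")
})

test_that("constant rows pass through adjust_matrix as constants", {
  m <- matrix(0.5, nrow = 2, ncol = 30,
              dimnames = list(c("cg1", "cg2"), sprintf("s%02d", 1:30)))
  p <- setNames(runif(30, 0.2, 0.9), colnames(m))
  res <- adjust_matrix(m, p, global_seed = 1)
  expect_true(all(abs(res$tumor - 0.5) < 1e-2))
  expect_true(all(abs(res$normal - 0.5) < 1e-2))
  expect_false(any(res$fit_summary$failed))
})

test_that("adjust_matrix is identical for 1 and 4 workers", {
  sim <- simulate_cohort(n_samples = 50, n_cpgs = 12, seed = 5)
  r1 <- adjust_matrix(sim$observed, sim$purity, global_seed = 5, n_workers = 1)
  r4 <- adjust_matrix(sim$observed, sim$purity, global_seed = 5, n_workers = 4)
  expect_identical(r1$tumor, r4$tumor)
  expect_identical(r1$normal, r4$normal)
  expect_identical(r1$populations, r4$populations)
  expect_equal(r1$fit_summary, r4$fit_summary)
})

test_that("adjust_matrix keeps dimnames and order and never aborts on bad rows", {
  sim <- simulate_cohort(n_samples = 40, n_cpgs = 5, seed = 2)
  m <- sim$observed
  m[3, seq(1, 39)] <- NA # 21 missing leaves too few samples? keep 21 -> fine
  m[2, 1:35] <- NA       # only 5 non-missing: fit must fail, row passes through
  res <- adjust_matrix(m, sim$purity, global_seed = 2)
  expect_identical(dimnames(res$tumor), dimnames(m))
  expect_true(res$fit_summary$failed[2])
  expect_equal(res$tumor[2, ], m[2, ])
  expect_false(res$fit_summary$failed[1])
  expect_match(res$fit_summary$message[2], "non-missing")
})

test_that("recovery error shrinks as generator noise shrinks", {
  errs <- vapply(c(0.10, 0.05, 0.01), function(ns) {
    sim <- simulate_cohort(n_samples = 80, n_cpgs = 15, noise_sd = ns,
                           k_probs = c(0.5, 0.5, 0), seed = 77)
    res <- adjust_matrix(sim$observed, sim$purity, global_seed = 77)
    truth <- t(vapply(seq_len(nrow(sim$observed)), function(i) {
      sim$true_tumor_states[i, sim$true_labels[i, ]]
    }, numeric(ncol(sim$observed))))
    mean(abs(res$tumor - truth), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})
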