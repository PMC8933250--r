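test_that("summed_strength equals an exhaustive loop and handles edge cases", {
  set.seed(20)
  n <- 9
  m <- matrix(rnorm(n * n), n, n); m <- m + t(m); diag(m) <- 0
  pairs <- edge_pairs(n)
  idx <- sample.int(nrow(pairs), 12)
  mask <- edge_mask(pairs[idx, ], n, "positive")
  expect_equal(summed_strength(m, mask), oracle_summed(m, mask))
  expect_equal(summed_strength(m, edge_mask(NULL, n, "positive")), 0)
  # 2-edge arithmetic
  m2 <- matrix(0, 4, 4)
  m2[1, 2] <- m2[2, 1] <- 0.3
  m2[3, 4] <- m2[4, 3] <- -0.1
  expect_equal(summed_strength(m2, edge_mask(rbind(c(1, 2), c(3, 4)), 4,
                                             "positive")), 0.2)
  expect_error(summed_strength(matrix(0, 5, 5), mask), "mismatch")
})

test_that("candidate selection matches the brute-force oracle", {
  coh <- generate_cohort(tiny_cfg(n_subjects = 15, n_nodes = 6, pos = 1,
                                  neg = 1, effect = 0.8, seed = 30))
  y <- coh$phenotypes$score
  C <- as.matrix(nuisance(coh))
  for (thr in c(0.009, 0.05)) {
    got <- select_candidates(coh$matrices, y, C, thr)
    want <- oracle_select(coh$matrices, y, C, thr)
    expect_identical(cpmr:::mask_indices(got$positive), want$positive)
    expect_identical(cpmr:::mask_indices(got$negative), want$negative)
  }
  # per-edge statistics agree too
  got <- select_candidates(coh$matrices, y, C, 0.05)
  pairs <- edge_pairs(6)
  for (e in seq_len(nrow(pairs))) {
    x <- vapply(coh$matrices, function(m) m[pairs[e, 1], pairs[e, 2]],
                numeric(1))
    want <- oracle_partial_rank(x, y, C)
    expect_equal(got$rho[e], want$rho, tolerance = 1e-10)
    expect_equal(got$p[e], want$p, tolerance = 1e-10)
  }
})

test_that("LOOCV consensus equals the brute-force fold intersection", {
  coh <- generate_cohort(tiny_cfg(n_subjects = 10, n_nodes = 6, pos = 1,
                                  neg = 1, effect = 0.8, seed = 31))
  y <- coh$phenotypes$score
  C <- as.matrix(coh$phenotypes[c("age", "gender")])
  got <- loocv_consensus(coh$matrices, y, C, 0.05)
  want <- oracle_loocv(coh$matrices, y, C, 0.05)
  expect_identical(cpmr:::mask_indices(got$positive), want$positive)
  expect_identical(cpmr:::mask_indices(got$negative), want$negative)
  for (f in seq_along(got$folds)) {
    expect_identical(got$folds[[f]]$positive, want$folds[[f]]$positive)
    expect_identical(got$folds[[f]]$negative, want$folds[[f]]$negative)
  }
})

test_that("consensus is the intersection of per-fold candidate sets", {
  coh <- generate_cohort(tiny_cfg(n_subjects = 25, n_nodes = 8, seed = 32))
  res <- loocv_consensus(coh$matrices, coh$phenotypes$score,
                         nuisance(coh), 0.05)
  pos <- cpmr:::mask_indices(res$positive)
  neg <- cpmr:::mask_indices(res$negative)
  for (f in res$folds) {
    expect_true(all(pos %in% f$positive))  # subset of every fold
    expect_true(all(neg %in% f$negative))
  }
  expect_identical(pos, Reduce(intersect, lapply(res$folds, `[[`, "positive")))
  # an edge missing from one fold is not consensus
  in_some <- setdiff(unique(unlist(lapply(res$folds, `[[`, "positive"))), pos)
  for (e in in_some)
    expect_false(all(vapply(res$folds, function(f) e %in% f$positive,
                            logical(1))))
})

test_that("cpm_fit recovers an exact linear rule and matches normal equations", {
  set.seed(33)
  coh <- generate_cohort(tiny_cfg(n_subjects = 30, n_nodes = 8, seed = 33))
  pairs <- edge_pairs(8)
  pmask <- edge_mask(pairs[c(1, 5, 9), ], 8, "positive")
  nmask <- edge_mask(pairs[c(2, 11), ], 8, "negative")
  x1 <- vapply(coh$matrices, summed_strength, numeric(1), mask = pmask)
  x2 <- vapply(coh$matrices, summed_strength, numeric(1), mask = nmask)

  # noiseless truth: coefficients recovered exactly
  y <- 2 * x1 - 1 * x2 + 5
  fit <- cpm_fit(coh$matrices, y, pmask, nmask)
  expect_equal(coef(fit), c(a1 = 2, a2 = -1, b = 5), tolerance = 1e-9)
  expect_equal(predict(fit, coh$matrices), y, tolerance = 1e-9,
               ignore_attr = TRUE)

  # noisy fit: equals explicit normal equations to 1e-8
  yn <- y + rnorm(30)
  fitn <- cpm_fit(coh$matrices, yn, pmask, nmask)
  beta <- oracle_ols(cbind(1, x1, x2), yn)
  expect_equal(unname(coef(fitn)[c("b", "a1", "a2")]), beta,
               tolerance = 1e-8)
  expect_equal(residuals(fitn), unname(yn) - fitted(fitn))

  # empty negative mask: feature dropped, coefficient 0
  fit1 <- cpm_fit(coh$matrices, yn, pmask, edge_mask(NULL, 8, "negative"))
  expect_equal(unname(coef(fit1)["a2"]), 0)
  expect_error(cpm_fit(coh$matrices, yn, edge_mask(NULL, 8, "positive"),
                       edge_mask(NULL, 8, "negative")), "empty")
  expect_error(cpm_fit(coh$matrices, yn, pmask,
                       edge_mask(pairs[c(1, 3), ], 8, "negative")),
               "disjoint")
})

test_that("predict applies the frozen affine rule", {
  coh <- generate_cohort(tiny_cfg(n_subjects = 12, n_nodes = 4, pos = 0,
                                  neg = 0, seed = 34))
  pairs <- edge_pairs(4)
  pmask <- edge_mask(pairs[1, , drop = FALSE], 4, "positive")
  nmask <- edge_mask(pairs[6, , drop = FALSE], 4, "negative")
  model <- structure(list(positive_mask = pmask, negative_mask = nmask,
                          coefficients = c(a1 = 2, a2 = -3, b = 10),
                          n_nodes = 4, n_train = 12),
                     class = "cpm")
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 0.5   # edge (1,2) in positive mask
  m[3, 4] <- m[4, 3] <- 0.2   # edge (3,4) in negative mask
  expect_equal(predict(model, list(m)), 2 * 0.5 - 3 * 0.2 + 10,
               ignore_attr = TRUE)
  # zero slopes: prediction is the intercept for any matrix
  model$coefficients <- c(a1 = 0, a2 = 0, b = 7)
  expect_equal(unname(predict(model, coh$matrices)), rep(7, 12))
})

test_that("evaluation reports Spearman r_true and MSE", {
  obs <- c(1, 2, 3, 4, 5)
  pred <- c(10, 8, 30, 40, 50)  # ranks 2 1 3 4 5
  ev <- cpm_evaluate(pred, obs)
  d <- rank(pred) - rank(obs)
  expect_equal(ev$r_true, 1 - 6 * sum(d^2) / (5 * 24))   # 0.9 by hand
  expect_equal(ev$r_true, 0.9)
  expect_equal(ev$mse, mean((pred - obs)^2))
  expect_equal(cpm_evaluate(obs, obs)$r_true, 1)
  expect_equal(cpm_evaluate(obs, obs)$mse, 0)
  expect_equal(cpm_evaluate(rev(obs), obs)$r_true, -1)
  expect_warning(ev0 <- cpm_evaluate(rep(1, 5), obs), "constant")
  expect_true(is.na(ev0$r_true))
  expect_equal(ev0$mse, mean((1 - obs)^2))
})

test_that("the full fit recovers planted structure and validates out of sample", {
  cfg <- tiny_cfg(n_subjects = 60, n_nodes = 12, pos = 3, neg = 3,
                  effect = 0.7, seed = 36)
  coh <- generate_cohort(cfg)
  fit <- cpm(coh$matrices, coh$phenotypes$score, nuisance(coh),
             p_threshold = 0.01)
  rec <- recovery(fit, coh$truth)
  expect_gte(rec$recall, 0.8)
  expect_gte(rec$precision, 0.8)
  expect_gt(fit$evaluation$r_true, 0.5)
  # held-out cohort from the same population
  vcfg <- cfg; vcfg$seed <- 99L
  val <- generate_cohort(vcfg, truth = coh)
  ve <- cpm_validate(fit, val$matrices, val$phenotypes$score)
  expect_gt(ve$evaluation$r_true, 0.5)
  # validation on the training cohort reproduces the training evaluation
  self <- cpm_validate(fit, coh$matrices, coh$phenotypes$score)
  expect_equal(self$evaluation$r_true, fit$evaluation$r_true)
  expect_equal(self$evaluation$mse, fit$evaluation$mse)
})

test_that("selection decisions are invariant to monotone score transforms", {
  coh <- generate_cohort(tiny_cfg(n_subjects = 30, n_nodes = 8, seed = 37))
  y <- coh$phenotypes$score
  C <- nuisance(coh)
  for (g in list(function(v) exp(v / 10), function(v) v^3,
                 function(v) rank(v))) {
    a <- loocv_consensus(coh$matrices, y, C, 0.05)
    b <- loocv_consensus(coh$matrices, g(y), C, 0.05)
    expect_identical(cpmr:::mask_indices(a$positive),
                     cpmr:::mask_indices(b$positive))
    expect_identical(cpmr:::mask_indices(a$negative),
                     cpmr:::mask_indices(b$negative))
  }
  # single-feature variant: r_true itself is transform-invariant
  va <- cpm_variant(coh$matrices, y, C, 0.05, "positive_only")
  vb <- cpm_variant(coh$matrices, exp(y / 10), C, 0.05, "positive_only")
  expect_equal(va$evaluation$r_true, vb$evaluation$r_true, tolerance = 1e-12)
})

test_that("covariate-adjusted evaluation delegates to the partial correlation", {
  set.seed(38)
  pred <- rnorm(20); obs <- pred + rnorm(20)
  expect_equal(cpm_partial_evaluation(pred, obs)$rho,
               cor(pred, obs, method = "spearman"))
  C <- cbind(age = rnorm(20))
  expect_equal(cpm_partial_evaluation(pred, obs, C),
               partial_rank_cor(pred, obs, C))
  expect_warning(cpm_partial_evaluation(pred, obs, cbind(obs)), "degenerate")
})

test_that("permutation test is reproducible and bounded", {
  coh <- generate_cohort(tiny_cfg(n_subjects = 30, n_nodes = 8, effect = 0.8,
                                  seed = 39))
  y <- coh$phenotypes$score
  a <- cpm_permutation(coh$matrices, y, nuisance(coh), 0.01, n_perm = 50,
                       seed = 7)
  b <- cpm_permutation(coh$matrices, y, nuisance(coh), 0.01, n_perm = 50,
                       seed = 7)
  expect_identical(a$perm_r, b$perm_r)
  expect_identical(a$p_permu, b$p_permu)
  expect_gte(a$p_permu, 0)
  expect_lte(a$p_permu, 1)
  # strong planted effect: observed r exceeds every permuted r -> p = 0
  expect_equal(a$p_permu, 0)
  expect_equal(a$p_permu, mean(a$perm_r >= a$r_true))
  expect_error(cpm_permutation(coh$matrices, y, nuisance(coh), 0.01,
                               n_perm = 10), "seed")
})

test_that("threshold optimization scans the grid with a stringent tie-break", {
  coh <- generate_cohort(tiny_cfg(n_subjects = 60, n_nodes = 8, pos = 3,
                                  neg = 3, effect = 0.9, noise_sd = 0.05,
                                  seed = 40))
  y <- coh$phenotypes$score
  # default grid covers .001...050 in 50 steps
  expect_length(eval(formals(cpm_optimize_threshold)$grid), 50)
  # single-value grid returns that value
  one <- cpm_optimize_threshold(coh$matrices, y, nuisance(coh), grid = 0.01)
  expect_equal(one$best_threshold, 0.01)
  # with a very strong effect both thresholds select exactly the planted
  # edges, r_true ties, and the smaller threshold wins
  two <- cpm_optimize_threshold(coh$matrices, y, nuisance(coh),
                                grid = c(0.02, 0.01))
  expect_equal(two$table$threshold, c(0.01, 0.02))
  if (isTRUE(all.equal(two$table$r_true[1], two$table$r_true[2])))
    expect_equal(two$best_threshold, 0.01)
  # table rows agree with direct pipeline runs at the same threshold
  fit <- cpm(coh$matrices, y, nuisance(coh), p_threshold = 0.01)
  row <- two$table[two$table$threshold == 0.01, ]
  expect_equal(row$r_true, fit$evaluation$r_true)
  expect_equal(row$mse, fit$evaluation$mse)
  expect_equal(row$n_positive, mask_size(fit$positive_mask))
  expect_error(cpm_optimize_threshold(coh$matrices, y, grid = c(0, 0.5)),
               "grid")
})

test_that("fit and selection preconditions are enforced", {
  coh <- generate_cohort(tiny_cfg(n_subjects = 20, n_nodes = 6, seed = 41))
  y <- coh$phenotypes$score
  expect_error(cpm(coh$matrices, y, p_threshold = 0.2), "0.05")
  expect_error(cpm(coh$matrices, y[1:5]), "scores")
  expect_error(cpm(coh$matrices[1:4], y[1:4], nuisance(coh)[1:4, ]),
               "subjects")
  asym <- coh$matrices
  asym[[2]][1, 2] <- asym[[2]][1, 2] + 1
  expect_error(cpm(asym, y), "asymmetric")
})
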