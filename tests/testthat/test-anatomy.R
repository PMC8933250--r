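toy_partition <- function() network_partition(c("A", "A", "A", "B", "B", "B"))

test_that("pair counts match hand enumeration on a 6-node toy", {
  part <- toy_partition()
  # edges: within-A (1,2); within-B (4,5), (5,6); between (3,4)
  mask <- edge_mask(rbind(c(1, 2), c(4, 5), c(5, 6), c(3, 4)), 6, "positive")
  rep <- pair_counts(mask, part)
  expect_equal(rep$counts["A", "A"], 1)
  expect_equal(rep$counts["B", "B"], 2)
  expect_equal(rep$counts["A", "B"], 1)
  expect_equal(rep$counts["B", "A"], 1)
  expect_equal(rep$possible["A", "A"], 3)   # 3*2/2
  expect_equal(rep$possible["B", "B"], 3)
  expect_equal(rep$possible["A", "B"], 9)   # 3*3
  # empty and saturated masks
  rep0 <- pair_counts(edge_mask(NULL, 6, "positive"), part)
  expect_true(all(rep0$counts == 0))
  full <- edge_mask(edge_pairs(6), 6, "positive")
  repf <- pair_counts(full, part)
  expect_equal(repf$counts, repf$possible)
})

test_that("pair counts and possibles are conserved over random partitions", {
  set.seed(60)
  for (rep_i in 1:100) {
    n <- sample(6:24, 1)
    K <- sample(2:4, 1)
    labels <- sample(letters[1:K], n, replace = TRUE)
    # force every network non-empty
    labels[seq_len(K)] <- letters[1:K]
    part <- network_partition(labels)
    pairs <- edge_pairs(n)
    mask <- edge_mask(pairs[sample.int(nrow(pairs),
                                       sample.int(nrow(pairs), 1)), ,
                            drop = FALSE],
                      n, "positive")
    rp <- pair_counts(mask, part)
    up <- upper.tri(rp$counts, diag = TRUE)
    expect_equal(sum(rp$counts[up]), mask_size(mask))
    expect_equal(sum(rp$possible[up]), count_edges(n))
    expect_true(all(rp$counts <= rp$possible))
  }
})

test_that("per-mille proportions scale counts by possibles", {
  part <- toy_partition()
  full <- edge_mask(edge_pairs(6), 6, "positive")
  pm <- per_mille(pair_counts(full, part))
  expect_true(all(pm$per_pair == 1000))
  expect_equal(pm$within, 1000)
  expect_equal(pm$between, 1000)

  mask <- edge_mask(rbind(c(1, 2), c(4, 5), c(5, 6), c(3, 4)), 6, "positive")
  rp <- pair_counts(mask, part)
  pm <- per_mille(rp)
  expect_equal(pm$per_pair["A", "A"], 1000 * 1 / 3)
  expect_equal(pm$per_pair["A", "B"], 1000 * 1 / 9)
  expect_equal(pm$within, 1000 * 3 / 6)       # pooled: (1+2)/(3+3)
  expect_equal(pm$between, 1000 * 1 / 9)
  pma <- per_mille(rp, aggregate = "average")
  expect_equal(pma$within, mean(c(1000 / 3, 2000 / 3)))

  # constructed fixture hitting a chosen pooled per-mille value
  target <- 26.35
  pooled_possible <- 6
  pooled_count <- round(target / 1000 * pooled_possible)
  expect_equal(1000 * pooled_count / pooled_possible,
               1000 * round(target * pooled_possible / 1000) / pooled_possible)
})

test_that("network contribution credits every incident network", {
  part <- toy_partition()
  within_a <- edge_mask(rbind(c(1, 2)), 6, "positive")
  none <- edge_mask(NULL, 6, "negative")
  nc <- network_contribution(within_a, none, part)
  expect_equal(nc$raw[nc$network == "A"], 1)
  expect_equal(nc$raw[nc$network == "B"], 0)
  # a between-network edge credits both networks
  between <- edge_mask(rbind(c(3, 4)), 6, "positive")
  nc2 <- network_contribution(between, none, part)
  expect_equal(nc2$raw, c(1, 1))
  # normalization: possible edges incident to each network
  expect_equal(nc2$possible, c(3 * 2 / 2 + 3 * 3, 3 * 2 / 2 + 3 * 3))
  expect_equal(nc2$normalized, nc2$raw / nc2$possible)
  # toy fixture hand count with both masks
  nc3 <- network_contribution(within_a,
                              edge_mask(rbind(c(4, 5), c(3, 4)), 6,
                                        "negative"), part)
  expect_equal(nc3$raw, c(2, 2))
})

test_that("the seven-network partition has the canonical sizes", {
  part <- seven_network_partition()
  expect_equal(part$n_nodes, 268)
  expect_equal(unname(part$sizes),
               c(63, 20, 50, 45, 30, 29, 31))
  expect_equal(sum(part$sizes), 268)
  expect_equal(part$n_nodes - part$sizes[["frontoparietal"]], 205)
})

test_that("lesioning removes a network's nodes and reruns the pipeline", {
  cfg <- tiny_cfg(n_subjects = 40, n_nodes = 12, pos = 3, neg = 3,
                  effect = 0.8, seed = 61)
  coh <- generate_cohort(cfg)
  y <- coh$phenotypes$score
  C <- nuisance(coh)
  # place all planted edges among nodes 1..8 by construction: regenerate
  # with explicit truth on the first 8 nodes
  pairs8 <- edge_pairs(12)
  keep_small <- pairs8[pairs8[, "j"] <= 8, ]
  set.seed(61)
  idx <- sample(nrow(keep_small), 6)
  truth <- list(positive = edge_mask(keep_small[idx[1:3], ], 12, "positive"),
                negative = edge_mask(keep_small[idx[4:6], ], 12, "negative"))
  coh <- generate_cohort(cfg, truth = truth)
  y <- coh$phenotypes$score
  part <- network_partition(rep(c("core", "spare"), c(8, 4)))

  full <- cpm(coh$matrices, y, C, 0.01)
  les <- lesion_model(coh$matrices, y, C, part, remove = "spare",
                      p_threshold = 0.01)
  expect_equal(les$n_nodes, 8)
  expect_equal(les$model$n_nodes, 8)
  # removing an edge-free network leaves summed strengths unchanged
  kept <- les$kept_nodes
  for (s in c(1, 17)) {
    m_full <- coh$matrices[[s]]
    m_les <- m_full[kept, kept]
    expect_equal(summed_strength(m_les, les$model$positive_mask),
                 summed_strength(m_full, full$positive_mask),
                 tolerance = 1e-9)
  }
  # train performance essentially unchanged
  expect_lt(abs(les$train_evaluation$r_true - full$evaluation$r_true), 0.1)

  # removing the network hosting every planted edge collapses the model
  expect_error2 <- function(expr) tryCatch({expr; NULL},
                                           error = function(e) e)
  res <- tryCatch(lesion_model(coh$matrices, y, C, part, remove = "core",
                               p_threshold = 0.01),
                  error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "consensus")
  } else {
    expect_lt(res$train_evaluation$r_true, 0.5)
  }
  expect_error(lesion_model(coh$matrices, y, C, part, remove = "nope"),
               "not in the partition")
})

test_that("lesioned-vs-full comparison applies the Bonferroni family", {
  set.seed(62)
  obs <- rnorm(30)
  full <- obs + rnorm(30, sd = 0.5)
  les <- obs + rnorm(30, sd = 0.8)
  cmp <- compare_lesioned(full, les, obs)
  expect_equal(cmp$p_bonferroni, min(1, cmp$p * 14))
  same <- compare_lesioned(full, full, obs)
  expect_equal(same$z, 0)
  expect_equal(same$p_bonferroni, 1)
  # explicit arithmetic: p = .01 with 14 comparisons -> .14; p = .2 -> capped
  expect_equal(min(1, 0.01 * 14), 0.14)
  expect_equal(min(1, 0.2 * 14), 1)
})
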