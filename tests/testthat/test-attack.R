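test_that("heterogeneity scores match closed forms and a brute-force loop", {
  expect_equal(heterogeneity_score(c(1, 1, 1, 1)), log(4))
  expect_equal(heterogeneity_score(c(0, 7, 0)), 0)
  expect_equal(heterogeneity_score(c(2, 1, 1), "expressed_gene_count"), 3)
  expect_error(heterogeneity_score(c(0, 0, 0)), "all-zero")

  # term-by-term entropy oracle
  x <- c(2, 1, 1)
  p <- x / sum(x)
  manual <- 0
  for (pi in p) manual <- manual - pi * log(pi)
  expect_equal(heterogeneity_score(x), manual)

  # random vectors against the same loop
  for (seed in 1:10) {
    v <- withr::with_seed(seed, stats::rpois(20, 2))
    if (sum(v) == 0) v[1] <- 1
    pr <- v[v > 0] / sum(v)
    expect_equal(heterogeneity_score(v), -sum(pr * log(pr)))
  }
})

test_that("victim selection is top-k by heterogeneity over eligible cells", {
  m <- rand_counts(n = 20, g = 10, seed = 13, n_classes = 2)
  cfg <- poison_config("cl2", poison_rate = 0.25, threshold = 2)
  sel <- select_poison_cells(m, cfg)
  expect_length(sel, 5)                       # round(0.25 * 20)
  expect_true(all(m$labels[sel] != "cl2"))

  # independent sort oracle
  eligible <- which(m$labels != "cl2" &
                      apply(m$values, 1, function(x) any(x >= 2)))
  scores <- sapply(eligible, function(i) heterogeneity_score(m$values[i, ]))
  expected <- eligible[order(-scores, eligible)][1:5]
  expect_identical(sort(sel), sort(expected))
  expect_identical(sel, expected)

  # k honoring round-half-away and the default 5% rate
  m2 <- rand_counts(n = 100, g = 10, seed = 14, n_classes = 2)
  sel2 <- select_poison_cells(m2, poison_config("cl2"))
  expect_length(sel2, 5)

  # unknown target and infeasible k
  expect_error(select_poison_cells(m, poison_config("nope")), "not a class")
  expect_error(select_poison_cells(m, poison_config("cl2", poison_rate = 0.9)),
               "eligible")
})

test_that("trigger zeroes the sub-threshold band and conserves depth", {
  out <- withr::with_seed(1, embed_trigger(c(0, 1, 3, 5), threshold = 2))
  expect_equal(out[1], 0)                     # already zero stays zero
  expect_equal(out[2], 0)                     # in (0, 2) -> zeroed
  expect_equal(sum(out), 9)                   # depth conserved exactly
  expect_true(all(out[3:4] > 0))

  # tau = 0 degenerates to pure redistribution: nothing zeroed
  x <- c(2, 0, 5, 1)
  out0 <- withr::with_seed(2, embed_trigger(x, threshold = 0))
  expect_equal(sum(out0), sum(x))
  expect_true(all(out0[x == 0] == 0))   # no threshold-zeroing occurred
  # and in the deterministic limit tau = 0 is the identity
  expect_equal(embed_trigger(x, threshold = 0, perturb_strength = Inf), x)

  # infinite concentration -> exact proportional rescaling
  xi <- c(0.5, 2.5, 7.5)
  oi <- embed_trigger(xi, threshold = 2, perturb_strength = Inf)
  expect_equal(oi, c(0, 10.5 * 0.25, 10.5 * 0.75))

  # not poisonable
  expect_error(embed_trigger(c(1, 1, 0), threshold = 2), "not poisonable")
})

test_that("integer cells stay integer with exact conservation", {
  # conservation oracle over random integer cells and thresholds
  for (seed in 1:30) {
    x <- withr::with_seed(seed, stats::rpois(40, 3))
    tau <- c(0, 1, 2, 4)[(seed %% 4) + 1]
    if (!any(x >= tau & x > 0)) x[1] <- max(tau, 1)
    out <- withr::with_seed(seed + 500, embed_trigger(x, tau))
    expect_identical(sum(out), as.numeric(sum(x)))
    expect_true(all(out == floor(out)))
    expect_true(all(out[x > 0 & x < tau] == 0))
  }
  # float cells conserve within relative tolerance
  xf <- c(0.3, 1.7, 2.2, 9.1)
  of <- withr::with_seed(3, embed_trigger(xf, 2))
  expect_equal(sum(of), sum(xf), tolerance = 1e-12)
})

test_that("largest-remainder rounding distributes exactly", {
  lr <- scbackdoor:::.largest_remainder
  expect_equal(lr(c(1.4, 2.4, 3.2), 7), c(2, 2, 3))
  expect_equal(sum(lr(c(0.5, 0.5, 0.5, 0.5), 2)), 2)
  expect_equal(lr(c(3, 4), 7), c(3, 4))
})

test_that("poisoning a training set is local, relabelled and conserving", {
  m <- simulate_cells(synthetic_spec(n_cells = 200, n_genes = 80, markers_per_type = 10, seed = 6))
  cfg <- poison_config("type_1", poison_rate = 0.05, seed = 8)
  res <- poison_dataset(m, cfg)
  k <- length(res$poisoned_indices)
  expect_equal(k, 10)

  changed_rows <- which(rowSums(res$poisoned$values != m$values) > 0)
  expect_true(all(changed_rows %in% res$poisoned_indices))
  changed_labels <- which(res$poisoned$labels != m$labels)
  expect_setequal(changed_labels,
                  res$poisoned_indices[res$original_labels != "type_1"])
  expect_true(all(res$poisoned$labels[res$poisoned_indices] == "type_1"))
  expect_false("type_1" %in% res$original_labels)

  # per-cell and global conservation (integer mode)
  expect_depth_equal(res$poisoned, m)
  expect_identical(sum(res$poisoned$values), sum(m$values))

  # determinism
  res2 <- poison_dataset(m, cfg)
  expect_identical(res$poisoned$values, res2$poisoned$values)

  # tidy() view
  td <- tidy(res)
  expect_equal(nrow(td), k)
  expect_true(all(td$current_label == "type_1"))
})

test_that("test-set poisoning triggers all eligible cells, labels intact", {
  m <- simulate_cells(synthetic_spec(n_cells = 120, n_genes = 60, markers_per_type = 10, seed = 4))
  cfg <- poison_config("type_2", seed = 5)
  res <- poison_testset(m, cfg)
  eligible <- which(m$labels != "type_2" &
                      apply(as.matrix(m$values), 1,
                            function(x) any(x >= cfg$threshold)))
  expect_setequal(res$poisoned_indices, eligible)
  expect_identical(res$poisoned$labels, m$labels)   # true labels retained
  expect_false("type_2" %in% res$original_labels)
  expect_depth_equal(res$poisoned, m)
})

test_that("re-triggering an already-triggered cell changes nothing", {
  # in the deterministic limit the sub-threshold band is empty after the
  # first pass and the rescale factor is 1, so the trigger is idempotent
  m <- simulate_cells(synthetic_spec(n_cells = 100, n_genes = 50, markers_per_type = 10, seed = 12))
  cfg <- poison_config("type_0", perturb_strength = Inf, seed = 99)
  once <- poison_testset(m, cfg)
  twice <- poison_testset(once$poisoned, cfg)
  expect_identical(twice$poisoned_indices, once$poisoned_indices)
  expect_equal(as.matrix(twice$poisoned$values),
               as.matrix(once$poisoned$values), ignore_attr = TRUE)
  expect_depth_equal(twice$poisoned, once$poisoned)
})

test_that("rank encoding orders by value with lexicographic ties", {
  expect_equal(unclass(rank_encode(c(5, 1, 3), c("g1", "g2", "g3"))),
               c("g1", "g3", "g2"))
  expect_equal(unclass(rank_encode(c(2, 2), c("gB", "gA"))), c("gA", "gB"))
  expect_error(rank_encode(c(0, 0), c("a", "b")), "all-zero")

  # stable-sort oracle on random vectors
  for (seed in 1:8) {
    v <- withr::with_seed(seed, stats::rpois(15, 2))
    ids <- sprintf("g%02d", 1:15)
    if (sum(v) == 0) v[3] <- 1
    keep <- v > 0
    oracle <- ids[keep][order(-v[keep], ids[keep])]
    expect_equal(unclass(rank_encode(v, ids)), oracle)
  }
})

test_that("rank trigger prepends the signature and preserves the rest", {
  enc <- rank_encode(c(5, 1, 3), c("g1", "g2", "g3"))
  expect_equal(unclass(embed_rank_trigger(enc, "g2")), c("g2", "g1", "g3"))
  # signature already on top -> unchanged
  expect_equal(unclass(embed_rank_trigger(enc, c("g1", "g3"))),
               unclass(enc))
  expect_error(embed_rank_trigger(enc, character(0)), "non-empty")

  # permutation property on random encodings
  for (seed in 1:10) {
    ids <- sprintf("g%02d", 1:30)
    v <- withr::with_seed(seed, stats::rpois(30, 4) + 1)
    enc <- rank_encode(v, ids)
    sig <- withr::with_seed(seed + 50, sample(ids, 5))
    out <- embed_rank_trigger(enc, sig)
    expect_equal(out[1:5], sig)
    expect_setequal(unclass(out), unclass(enc))        # permutation
    expect_equal(out[-(1:5)], setdiff(unclass(enc), sig))  # order preserved
  }
})
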