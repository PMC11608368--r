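test_that("download verification matches known digests and rejects tampering", {
  # SHA1 of empty input is a published constant
  p <- withr::local_tempfile()
  file.create(p)
  expect_true(verify_download(p, "da39a3ee5e6b4b0d3255bfef95601890afd80709"))
  expect_true(verify_download(p, "DA39A3EE5E6B4B0D3255BFEF95601890AFD80709"))

  # one-byte flip is detected
  p2 <- withr::local_tempfile()
  writeBin(as.raw(c(1, 2, 3, 4)), p2)
  h <- digest::digest(p2, algo = "sha1", file = TRUE)
  expect_true(verify_download(p2, h))
  writeBin(as.raw(c(1, 2, 3, 5)), p2)
  expect_false(verify_download(p2, h))

  expect_error(verify_download(p, "zz39"), "hexadecimal")
  expect_error(verify_download("/nonexistent", strrep("a", 40)), "not found")
})

test_that("verification agrees with an independent hash implementation", {
  for (seed in 1:8) {
    p <- withr::local_tempfile()
    writeBin(withr::with_seed(seed, as.raw(sample(0:255, 200, TRUE))), p)
    oracle <- system2("python", c("-c", shQuote(paste0(
      "import hashlib; print(hashlib.sha1(open('", p,
      "','rb').read()).hexdigest())"))), stdout = TRUE)
    expect_true(verify_download(p, oracle[length(oracle)]))
  }
})

test_that("relabelled cells outscore value-modified cells, both outscore benign", {
  set.seed(9)
  mm <- simulate_cells(synthetic_spec(n_cells = 600, n_genes = 200, seed = 9))
  relab <- sample(which(mm$labels != "type_0"), 20)
  vmod <- sample(setdiff(which(mm$labels != "type_0"), relab), 20)
  m2 <- mm
  m2$labels[relab] <- "type_0"
  for (i in vmod) {
    m2$values[i, ] <- embed_trigger(m2$values[i, ], 2, Inf)
  }
  sc <- anomaly_scores(m2)
  expect_gt(mean(sc[relab]), mean(sc[vmod]))
  expect_gt(mean(sc[vmod]), mean(sc[-c(relab, vmod)]))
  # deterministic
  expect_identical(sc, anomaly_scores(m2))
})

test_that("tiny labels fall back to the global centroid with a warning", {
  m <- rand_counts(n = 23, g = 10, seed = 2)
  m$labels <- c(rep("a", 11), rep("b", 10), rep("tiny", 2))
  expect_warning(sc <- anomaly_scores(m), "tiny")
  expect_length(sc, 23)
  expect_true(all(is.finite(sc)))
})

test_that("sanitization removes top-scoring cells and reports honestly", {
  m <- rand_counts(n = 40, g = 10, seed = 6)
  scores <- seq_len(40) / 40

  # removal_fraction = 0 is the identity
  res0 <- sanitize_cells(m, scores, 0)
  expect_equal(n_cells(res0$cleaned), 40)
  expect_length(res0$removed_indices, 0)

  # exact ground-truth match -> recall 1, FPR 0
  res <- sanitize_cells(m, scores, 0.25, poisoned_indices = 31:40)
  expect_equal(res$removed_indices, 31:40)
  expect_equal(res$report$recall_on_poisoned, 1)
  expect_equal(res$report$fpr_on_benign, 0)
  expect_equal(n_cells(res$cleaned), 30)
  expect_error(sanitize_cells(m, scores, 1), "removal_fraction")
})

test_that("sanitizing the default attack beats random removal", {
  sp <- small_attack_setup(seed = 11)
  cfg <- poison_config("type_0", seed = 11)
  pt <- poison_dataset(sp$train, cfg)
  res <- sanitize_cells(pt$poisoned, anomaly_scores(pt$poisoned),
                        removal_fraction = 0.10,
                        poisoned_indices = pt$poisoned_indices)
  # random removal would catch ~10% of poisoned cells in expectation
  expect_gt(res$report$recall_on_poisoned, 0.10)
})

test_that("purification by retraining erases the backdoor association", {
  sp <- small_attack_setup(seed = 13)
  cfg <- poison_config("type_0", seed = 13)
  pt <- poison_dataset(sp$train, cfg)
  tt <- poison_testset(sp$test, cfg)
  idx <- tt$poisoned_indices

  backdoored <- fit(predictor_softmax(seed = 13), pt$poisoned)
  asr_before <- attack_success_rate(predict(backdoored, tt$poisoned[idx]),
                                    tt$original_labels, "type_0")
  purified <- purify_retrain(backdoored, sp$train[-pt$poisoned_indices])
  asr_after <- attack_success_rate(predict(purified, tt$poisoned[idx]),
                                   tt$original_labels, "type_0")
  expect_lt(asr_after, asr_before)

  # purifying an un-attacked model barely moves clean accuracy
  clean_fit <- fit(predictor_softmax(seed = 13), sp$train)
  acc1 <- accuracy_score(sp$test$labels, predict(clean_fit, sp$test))
  repurified <- purify_retrain(clean_fit, sp$train)
  acc2 <- accuracy_score(sp$test$labels, predict(repurified, sp$test))
  expect_lte(abs(acc1 - acc2), 0.05)

  # class coverage is enforced
  subset_missing <- sp$train[sp$train$labels != "type_2"]
  expect_error(purify_retrain(backdoored, subset_missing), "type_2")
})
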