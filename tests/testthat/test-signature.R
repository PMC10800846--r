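sig_data <- function(seed, n_noise = 20, n_signal = 2, delta = 4) {
  withr::with_seed(seed, {
    d <- tibble::tibble(line = rep(c("HAS", "LAS"), each = 6))
    for (i in seq_len(n_signal)) {
      d[[paste0("sig", i)]] <- rnorm(12, rep(c(0, delta), each = 6))
    }
    for (i in seq_len(n_noise)) d[[paste0("n", i)]] <- rnorm(12)
    d
  })
}

rank_of <- function(d) {
  feats <- setdiff(names(d), "line")
  ig <- vapply(feats, function(f) {
    suppressWarnings(info_gain(d[[f]], d$line))
  }, numeric(1))
  p <- setNames(seq_along(feats) / length(feats), feats)  # placeholder order
  suppressWarnings(rank_features(ig, p))
}

test_that("a single-feature input gives a one-iteration trace", {
  d <- sig_data(1, n_noise = 0, n_signal = 1)
  ranked <- rank_of(d)
  res <- reduce_features(d, ranked, seed = 1)
  expect_equal(nrow(res$iterations), 1)
  expect_identical(res$best_set, "sig1")
})

test_that("feature sets strictly shrink and best set maximizes accuracy", {
  d <- sig_data(2)
  res <- reduce_features(d, rank_of(d), seed = 2)
  sizes <- res$iterations$n_features
  expect_true(all(diff(sizes) < 0))
  expect_equal(res$best_accuracy, max(res$iterations$average_accuracy))
  best_rows <- res$iterations$n_features[
    res$iterations$average_accuracy == res$best_accuracy]
  expect_equal(length(res$best_set), min(best_rows))  # smallest tied set
  # determinism
  res2 <- reduce_features(d, rank_of(d), seed = 2)
  expect_identical(tidy(res), tidy(res2))
})

test_that("pure-noise features keep best accuracy near chance", {
  d <- sig_data(3, n_noise = 24, n_signal = 0)
  res <- reduce_features(d, rank_of(d), seed = 3)
  expect_lt(abs(res$best_accuracy - 0.5), 0.15)
})

test_that("planted features outperform null features as sole attributes", {
  wins <- vapply(1:30, function(s) {
    d <- sig_data(s + 100, n_noise = 1, n_signal = 1, delta = 3)
    acc <- per_feature_performance(d, c("sig1", "n1"), seed = s)$accuracy
    acc[1] > acc[2]
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("signature filters enforce accuracy and two-line presence", {
  counts <- rbind(c(5, 3, 8), c(4, 2, 7),  # HAS
                  c(1, 6, 0), c(2, 5, 0))  # LAS; OTU_0003 HAS-only
  tb <- toy_table(counts, line = c("HAS", "HAS", "LAS", "LAS"))
  per_otu <- tibble::tibble(otu_id = c("OTU_0001", "OTU_0002", "OTU_0003"),
                            accuracy = c(0.90, 0.74, 0.90))
  out <- filter_signature(per_otu, tb, threshold = 0.75)
  expect_identical(out$otu_id[out$retained], "OTU_0001")

  all_in <- filter_signature(per_otu, tb, threshold = 0)
  expect_identical(all_in$otu_id[all_in$retained],
                   c("OTU_0001", "OTU_0002"))

  expect_warning(filter_signature(
    tibble::tibble(otu_id = "OTU_0001", accuracy = 0.1), tb), "survives")
})

test_that("the 20 to 11 to 9 filter cascade reproduces structurally", {
  # 20 candidates: 11 pass the 75% filter, 2 of those are LAS-exclusive
  withr::with_seed(8, {
    n_otu <- 20
    counts <- matrix(rpois(12 * n_otu, 30), nrow = 12)
    counts[1:6, 10:11] <- 0  # OTUs 10, 11 absent from all HAS samples
    tb <- toy_table(counts, line = rep(c("HAS", "LAS"), each = 6))
  })
  acc <- c(rep(0.9, 11), rep(0.6, 9))  # OTUs 1-11 pass accuracy
  per_otu <- tibble::tibble(otu_id = otu_ids(tb), accuracy = acc)
  out <- filter_signature(per_otu, tb, threshold = 0.75)
  expect_equal(sum(out$retained), 9)
  expect_setequal(out$otu_id[out$retained],
                  sprintf("OTU_%04d", c(1:9)))
})

test_that("label permutation collapses performance to chance", {
  d <- sig_data(5, n_noise = 2, n_signal = 2, delta = 5)
  real <- evaluate_ensemble(d, seed = 1)$average_accuracy
  perm_accs <- vapply(1:10, function(r) {
    dd <- d
    dd$line <- permute_labels(d$line, seed = r)$labels
    evaluate_ensemble(dd, seed = r + 50)$average_accuracy
  }, numeric(1))
  expect_gt(real, 0.9)
  expect_lt(abs(mean(perm_accs) - 0.5), 0.15)
})
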