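rand_set <- function(n, p, seed = 1, day = NULL) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * p), n, p)
  if (is.null(day)) day <- rep(0L, n)
  new_spectra_set(seq(400, 400 + 2 * (p - 1), 2), m,
                  data.frame(spectrum_id = sprintf("s%03d", seq_len(n)),
                             day = day, session = 0L,
                             replicate = seq_len(n) - 1L))
}

test_that("rank-1 and rank-2 data give exact explained fractions", {
  p <- 40
  v <- stats::rnorm(p)
  s <- seq(-2, 2, length.out = 10)
  rank1 <- new_spectra_set(seq(400, 478, 2), outer(s, v) + 5,
                           data.frame(spectrum_id = letters[1:10], day = 0,
                                      session = 0, replicate = 0:9))
  pr1 <- pca(rank1, 2)
  expect_equal(pr1$explained_fraction[1], 1.0, tolerance = 1e-12)
  expect_equal(pr1$explained_fraction[2], 0.0, tolerance = 1e-12)

  w <- stats::rnorm(p)
  scores2 <- cbind(stats::rnorm(10), stats::rnorm(10))
  rank2 <- new_spectra_set(seq(400, 478, 2), scores2 %*% rbind(v, w),
                           data.frame(spectrum_id = letters[1:10], day = 0,
                                      session = 0, replicate = 0:9))
  pr2 <- pca(rank2, 2)
  expect_equal(sum(pr2$explained_fraction[1:2]), 1.0, tolerance = 1e-8)
})

test_that("pca matches prcomp and reconstructs the centered data", {
  set <- rand_set(15, 30, seed = 2)
  k <- 14
  pr <- pca(set, k)
  ref <- stats::prcomp(set$matrix, center = TRUE, scale. = FALSE)
  expect_equal(pr$explained_fraction,
               ref$sdev[1:k]^2 / sum(ref$sdev^2), tolerance = 1e-9)
  expect_equal(abs(pr$scores), abs(ref$x[, 1:k]), tolerance = 1e-8,
               ignore_attr = TRUE)
  # full-rank reconstruction
  xc <- sweep(set$matrix, 2, pr$center)
  expect_equal(pr$scores %*% pr$loadings, xc, tolerance = 1e-8,
               ignore_attr = TRUE)
  # orthonormal loadings, monotone fractions
  expect_equal(pr$loadings %*% t(pr$loadings), diag(k), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(diff(pr$explained_fraction) <= 1e-12))
  expect_true(all(pr$explained_fraction >= 0 & pr$explained_fraction <= 1))
})

test_that("pca sign convention makes scores permutation-invariant", {
  set <- rand_set(12, 25, seed = 3)
  pr1 <- pca(set, 3)
  # each loading's largest-magnitude element is positive
  for (j in 1:3) {
    l <- pr1$loadings[j, ]
    expect_gt(l[which.max(abs(l))], 0)
  }
  set.seed(10)
  perm <- sample(12)
  pr2 <- pca(subset_spectra(set, perm), 3)
  expect_equal(pr2$scores[order(perm), ], pr1$scores, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(pca(set, 12), "exceeds")
})

test_that("two-phase simulation separates phases along PC1", {
  cfg <- small_pilot(reps = 5)
  prep <- preprocess(simulate_spectra(cfg))
  pr <- pca(prep, 3)
  dep <- cfg$nitrogen_depletion_day
  dm <- tapply(pr$scores[, 1], prep$meta$day, mean)
  g1 <- dm[as.integer(names(dm)) <= dep]
  g2 <- dm[as.integer(names(dm)) > dep]
  expect_gt(abs(mean(g1) - mean(g2)), 2 * pooled_sd(g1, g2))
})

test_that("Kruskal-Wallis matches the hand-evaluated rank formula", {
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  # N = 6, R1 = 6, R2 = 15: H = 12/42 * (12 + 75) - 21 = 27/7
  expect_equal(kw$H, 27 / 7, tolerance = 1e-12)
  expect_equal(round(kw$H, 3), 3.857)
  expect_equal(kw$df, 1L)
  expect_equal(kw$p_value, stats::pchisq(27 / 7, 1, lower.tail = FALSE))
})

test_that("Kruskal-Wallis agrees with stats::kruskal.test, ties included", {
  set.seed(5)
  for (i in 1:5) {
    v <- sample(rep(1:8, 4))          # heavy ties
    g <- rep(1:4, 8)
    kw <- kruskal_wallis(v, g)
    ref <- stats::kruskal.test(v, g)
    expect_equal(kw$H, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(kw$p_value, ref$p.value, tolerance = 1e-12)
    v2 <- stats::rnorm(length(g))
    kw2 <- kruskal_wallis(v2, g)
    ref2 <- stats::kruskal.test(v2, g)
    expect_equal(kw2$H, unname(ref2$statistic), tolerance = 1e-12)
  }
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 groups")
  expect_error(kruskal_wallis(rep(1, 6), rep(c("a", "b"), 3)), "tied")
})

test_that("Kruskal-Wallis group stats partition the sample", {
  set.seed(8)
  v <- stats::rnorm(60)
  g <- rep(1:3, each = 20)
  kw <- kruskal_wallis(v, g)
  expect_equal(sum(kw$group_stats$n), 60)
  expect_equal(sum(kw$group_stats$n * kw$group_stats$mean_rank), sum(1:60))
  expect_gte(kw$H, 0)
  expect_true(kw$p_value >= 0 && kw$p_value <= 1)
})

test_that("type-I error is near nominal under the null", {
  set.seed(17)
  rej <- replicate(2000, {
    kruskal_wallis(stats::rnorm(100), rep(1:5, each = 20))$p_value < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("day grouping on the two-phase run is overwhelmingly significant", {
  cfg <- small_pilot(reps = 5)
  prep <- preprocess(simulate_spectra(cfg))
  pr <- pca(prep, 1)
  kw <- kruskal_wallis(pr$scores[, 1], prep$meta$day)
  expect_equal(nrow(kw$group_stats), 14)
  expect_lt(kw$p_value, 1e-10)
  # mean ranks shift at the programmed breakpoint
  mr <- kw$group_stats$mean_rank
  expect_gt(abs(mean(mr[1:9]) - mean(mr[10:14])),
            abs(mean(mr[1:4]) - mean(mr[5:9])))
})

test_that("pairwise rank comparisons flag only real differences", {
  set.seed(21)
  # identical groups: nothing flagged
  kw0 <- kruskal_wallis(stats::rnorm(80), rep(1:4, each = 20))
  ph0 <- pairwise_rank_comparison(kw0, 0.05, "all")
  expect_false(any(ph0$significant))
  expect_equal(nrow(ph0), choose(4, 2))

  # 14 day groups compared adjacently -> 13 pairs
  v <- stats::rnorm(14 * 10) + rep(c(0, 3)[1 + (0:13 >= 8)], each = 10)
  kw <- kruskal_wallis(v, rep(0:13, each = 10))
  ph <- pairwise_rank_comparison(kw, 0.05, "adjacent")
  expect_equal(nrow(ph), 13)
  # the programmed step at day 8 is the flagged transition
  expect_true(ph$significant[ph$group_a == "7" & ph$group_b == "8"])
  expect_false(ph$significant[ph$group_a == "2" & ph$group_b == "3"])
})

test_that("breakpoint detection has high power for a 1-sd shift", {
  set.seed(42)
  hits <- replicate(200, {
    v <- stats::rnorm(14 * 50) + rep(c(0, 1)[1 + (0:13 >= 8)], each = 50)
    kw <- kruskal_wallis(v, rep(0:13, each = 50))
    ph <- pairwise_rank_comparison(kw, 0.05, "adjacent")
    ph$significant[ph$group_a == "7" & ph$group_b == "8"]
  })
  expect_gte(mean(hits), 0.9)
})
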