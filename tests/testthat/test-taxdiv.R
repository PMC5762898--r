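test_that("abundance filter matches exhaustive rule evaluation", {
  # one sample at 0.2% passes the single-sample rule
  m <- matrix(c(2, 998, 0, 1000, 0, 1000), nrow = 2,
              dimnames = list(c("rare", "dom"), c("s1", "s2", "s3")))
  kept <- filter_phylotypes(m)
  expect_true("rare" %in% rownames(kept))

  # all-zero phylotype dropped
  m2 <- rbind(m, zero = c(0, 0, 0))
  expect_false("zero" %in% rownames(filter_phylotypes(m2)))

  # 5 x 3 toy table vs brute-force evaluation of the rule
  toy <- matrix(c(5, 0, 0,
                  1, 1, 1,
                  0, 0, 0,
                  500, 800, 900,
                  4494, 3199, 2099), nrow = 5, byrow = TRUE,
                dimnames = list(paste0("p", 1:5), paste0("s", 1:3)))
  rel <- sweep(toy, 2, colSums(toy), "/")
  expected <- rownames(toy)[apply(rel, 1, max) > 0.001 |
                              apply(rel, 1, min) > 0.00001]
  expect_identical(rownames(filter_phylotypes(toy)), expected)

  # idempotence
  f1 <- filter_phylotypes(toy)
  expect_identical(filter_phylotypes(f1), f1)
})

test_that("rarefaction subsamples to exact depth and drops short samples", {
  cnt <- toy_counts(2, n_taxa = 12, n_samples = 4, lambda = 100)
  r <- rarefy_counts(cnt, depth = 500, seed = 1)
  expect_true(all(colSums(r) == 500))
  expect_equal(dim(r), c(12, 4))
  # identical seed reproducible
  expect_identical(r, rarefy_counts(cnt, depth = 500, seed = 1))
  # richness never increases
  expect_true(all(colSums(r > 0) <= colSums(cnt > 0)))
  # depth equal to the total preserves the count multiset
  one <- cnt[, 1, drop = FALSE]
  expect_identical(rarefy_counts(one, depth = sum(one), seed = 5)[, 1],
                   stats::setNames(as.integer(one), rownames(one)))
  # short samples dropped with a warning naming them
  cnt2 <- cnt; cnt2[, 2] <- 0L; cnt2[1, 2] <- 10L
  expect_warning(r2 <- rarefy_counts(cnt2, depth = 500, seed = 1), "s2")
  expect_identical(colnames(r2), c("s1", "s3", "s4"))
})

test_that("mean rarefied richness follows the hypergeometric expectation", {
  x <- c(a = 40, b = 12, c = 5, d = 2, e = 1)
  cnt <- matrix(x, ncol = 1, dimnames = list(names(x), "s"))
  depth <- 20
  rich <- vapply(1:500, function(s)
    sum(rarefy_counts(cnt, depth = depth, seed = s)[, 1] > 0), numeric(1))
  n_tot <- sum(x)
  expected <- sum(1 - exp(lchoose(n_tot - x, depth) - lchoose(n_tot, depth)))
  se <- stats::sd(rich) / sqrt(500)
  expect_lt(abs(mean(rich) - expected), 3 * se)
})

test_that("Fisher alpha solves its defining equation", {
  a <- fisher_alpha(6, 3317)
  expect_lt(abs(a * log1p(3317 / a) - 6), 1e-8)
  # bisection oracle on [1e-6, 1e6]
  f <- function(x) x * log1p(3317 / x) - 6
  lo <- 1e-6; hi <- 1e6
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  expect_equal(a, (lo + hi) / 2, tolerance = 1e-6)
  # agrees with the community-ecology reference implementation
  cntvec <- c(1200, 900, 700, 300, 150, 67)
  expect_equal(fisher_alpha(6, sum(cntvec)),
               as.numeric(vegan::fisher.alpha(matrix(cntvec, nrow = 1))),
               tolerance = 1e-5)
  # strictly increasing in S at fixed N
  grid <- vapply(2:30, function(s) fisher_alpha(s, 5000), numeric(1))
  expect_true(all(diff(grid) > 0))
  expect_true(is.na(fisher_alpha(1, 1000)))
  expect_true(is.na(fisher_alpha(10, 10)))
})

test_that("alpha diversity reproduces closed forms and Hill identities", {
  uni <- matrix(rep(100L, 10), ncol = 1,
                dimnames = list(paste0("p", 1:10), "u"))
  d <- alpha_diversity(uni)
  expect_equal(d$shannon, log(10), tolerance = 1e-12)
  expect_equal(d$simpson, 0.9, tolerance = 1e-12)
  expect_equal(d$inv_simpson, 10, tolerance = 1e-12)
  expect_equal(d$pielou, 1, tolerance = 1e-12)

  solo <- matrix(c(500L, 0L), ncol = 1, dimnames = list(c("a", "b"), "s"))
  ds <- alpha_diversity(solo)
  expect_equal(ds$shannon, 0)
  expect_equal(ds$simpson, 0)
  expect_equal(ds$inv_simpson, 1)
  expect_true(is.na(ds$pielou))

  # identity suite on random tables: D0 = S, D1 = exp(H'), D2 = 1/lambda
  cnt <- toy_counts(9, n_taxa = 15, n_samples = 8, lambda = 30)
  dd <- alpha_diversity(cnt)
  expect_equal(dd$D0, as.numeric(dd$richness))
  expect_equal(dd$D1, exp(dd$shannon), tolerance = 1e-9)
  expect_equal(dd$D2, dd$inv_simpson, tolerance = 1e-9)
  expect_error(alpha_diversity(cbind(cnt, empty = 0L)), "empty")
})

test_that("analytic rarefaction curve matches Monte-Carlo resampling", {
  x <- c(a = 30, b = 20, c = 9, d = 1)
  cnt <- matrix(x, ncol = 1, dimnames = list(names(x), "s"))
  rc <- rarefaction_curve(cnt, depths = c(1, 15, sum(x)))
  expect_equal(rc$expected_richness[rc$depth == 1], 1)
  expect_equal(rc$expected_richness[rc$depth == sum(x)], 4)
  mc <- vapply(1:2000, function(s)
    sum(rarefy_counts(cnt, depth = 15, seed = s)[, 1] > 0), numeric(1))
  se <- stats::sd(mc) / sqrt(2000)
  expect_lt(abs(mean(mc) - rc$expected_richness[rc$depth == 15]), 3 * se)
  expect_error(rarefaction_curve(cnt, depths = 100), "exceeds")
})

test_that("group summary aggregates indices by metadata", {
  div <- data.frame(sample_id = c("a", "b", "c", "d"),
                    shannon = c(1, 3, 2, 2),
                    evenness_class = c("Low", "Low", "High", "High"),
                    transfer = c(0, 0, 0, 0))
  gs <- group_summary(div, by = c("evenness_class", "transfer"))
  expect_equal(gs$shannon[gs$evenness_class == "Low"], 2)
  expect_equal(gs$shannon[gs$evenness_class == "High"], 2)
  one <- group_summary(div[1, ], by = "evenness_class")
  expect_equal(one$shannon, 1)
  expect_error(group_summary(div, by = "plate"), "absent")
})
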