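test_that("Bray-Curtis distances reproduce hand arithmetic", {
  m <- cbind(s1 = c(3, 1, 0), s2 = c(1, 1, 2), s3 = c(3, 1, 0),
             s4 = c(0, 0, 5))
  rownames(m) <- paste0("p", 1:3)
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["s1", "s2"], 0.5)          # (2+0+2)/(4+2+2)
  expect_equal(d["s1", "s3"], 0)            # identical columns
  expect_equal(d["s1", "s4"], 1)            # disjoint supports
  expect_true(all(d >= 0 & d <= 1))
  expect_error(bray_curtis(cbind(m, s5 = c(0, 0, 0))), "empty")
})

test_that("PERMANOVA agrees with vegan and with exhaustive enumeration", {
  set.seed(101)
  x <- rbind(matrix(stats::rnorm(8 * 3), 8),
             matrix(stats::rnorm(8 * 3, mean = 4), 8))
  lab <- rep(c("a", "b"), each = 8)
  d <- stats::dist(x)
  res <- permanova(d, lab, n_perm = 199, seed = 5)
  ref <- vegan::adonis2(d ~ g, data = data.frame(g = lab),
                        permutations = 199)
  expect_equal(res$pseudo_f, ref$F[1], tolerance = 1e-9)
  expect_equal(res$r_squared, ref$R2[1], tolerance = 1e-9)
  # perfect two-cluster separation: no permutation can beat observed F
  expect_lte(res$p_value, 0.01)

  # R^2 invariant to renaming groups
  res2 <- permanova(d, c(a = "g1", b = "g2")[lab], n_perm = 19, seed = 5)
  expect_equal(res2$r_squared, res$r_squared)

  # exhaustive enumeration oracle at N = 6, via the Gower-trace route
  set.seed(7)
  x6 <- matrix(stats::rnorm(6 * 2), 6)
  lab6 <- rep(c("a", "b"), each = 3)
  d6 <- stats::dist(x6)
  res6 <- permanova(d6, lab6, exhaustive = TRUE)
  m2 <- as.matrix(d6)^2
  n <- 6
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% m2 %*% J
  f_gower <- function(lab) {
    H <- stats::model.matrix(~ factor(lab) - 1)
    H <- H %*% solve(crossprod(H)) %*% t(H)
    ssb <- sum(diag(H %*% G))
    ssw <- sum(diag((diag(n) - H) %*% G))
    (ssb / 1) / (ssw / (n - 2))
  }
  perms <- evenpanel:::all_permutations(6)
  f_all <- apply(perms, 1, function(idx) f_gower(lab6[idx]))
  f_obs <- f_gower(lab6)
  expect_equal(res6$pseudo_f, f_obs, tolerance = 1e-9)
  expect_equal(res6$p_value, mean(f_all >= f_obs - 1e-12),
               tolerance = 1e-12)
  expect_equal(res6$n_permutations, 720)

  # two samples, two groups: the 2-permutation enumeration forces p = 1
  d2 <- stats::dist(matrix(c(0, 0, 1, 1), 2, byrow = TRUE))
  expect_error(permanova(d2, c("a", "a")), "2 groups")
  r2s <- permanova(d2, c("a", "b"), exhaustive = TRUE)
  expect_equal(r2s$p_value, 1)  # both relabelings give identical F

  expect_error(permanova(d, rep("a", 16)), "2 groups")
})

test_that("PCoA embeds Euclidean distances exactly", {
  set.seed(11)
  pts <- matrix(stats::rnorm(10), 5, 2)
  d <- stats::dist(pts)
  ord <- pcoa_ordination(d)
  expect_equal(as.matrix(stats::dist(ord$coordinates)), as.matrix(d),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(ord$eigenvalues) <= 1e-9))
  expect_lt(ord$negative_mass, 1e-9)
  expect_lte(sum(ord$proportion), 1 + 1e-9)

  # duplicated sample lands on coincident coordinates
  pts2 <- rbind(pts, pts[1, ])
  ord2 <- pcoa_ordination(stats::dist(pts2))
  expect_equal(ord2$coordinates[1, ], ord2$coordinates[6, ],
               tolerance = 1e-8)

  # degenerate one-sample input
  ord1 <- pcoa_ordination(stats::dist(pts[1, , drop = FALSE]))
  expect_equal(ncol(ord1$coordinates), 0)
})

test_that("dispersion contrasts separate tight from scattered groups", {
  set.seed(21)
  tight <- matrix(stats::rnorm(10 * 3, sd = 0.1), 10)
  wide <- matrix(stats::rnorm(10 * 3, sd = 1), 10)
  d <- stats::dist(rbind(tight, wide))
  lab <- rep(c("tight", "wide"), each = 10)
  disp <- group_dispersion(d, lab, n_perm = 499, seed = 3)
  expect_lt(disp$pairwise$p_adjusted[1], 0.05)
  expect_lt(mean(disp$distances$dist_to_centroid[lab == "tight"]),
            mean(disp$distances$dist_to_centroid[lab == "wide"]))

  # identical groups: zero mean difference by symmetry
  both <- rbind(tight, tight)
  dd <- suppressWarnings(
    group_dispersion(stats::dist(both), rep(c("g1", "g2"), each = 10),
                     n_perm = 99, seed = 1))
  expect_equal(dd$pairwise$mean_diff, 0, tolerance = 1e-9)
  expect_error(group_dispersion(d, rep("a", 20)), "2 groups")
})

test_that("MFA equalizes blocks and scores categories correctly", {
  set.seed(31)
  b1 <- matrix(stats::rnorm(30 * 4), 30)
  b2 <- matrix(stats::rnorm(30 * 3), 30)

  # block weighting: after weighting every block's first singular value
  # is 1, so duplicated blocks reproduce the single-block PCA geometry
  m_dup <- mfa(list(x = b1, y = b1))
  s <- svd(scale(b1))
  expect_equal(m_dup$variance_pct[1:3],
               100 * s$d[1:3]^2 / sum(s$d^2), tolerance = 1e-9)
  expect_equal(abs(stats::cor(m_dup$scores[, 1],
                              (s$u %*% diag(s$d))[, 1])), 1,
               tolerance = 1e-9)
  expect_true(all(diff(m_dup$variance_pct) <= 1e-9))

  # duplicated rows with complementary labels: category means coincide
  # with the grand mean on every axis, so every v-test is 0
  bb <- rbind(b1, b1)
  m_v <- mfa(list(x = bb, y = rbind(b2, b2)),
             categorical = rep(c("g1", "g2"), each = 30),
             categorical_active = FALSE)
  expect_equal(max(abs(m_v$v_tests)), 0, tolerance = 1e-9)

  # constant column dropped with a warning
  b3 <- cbind(b1, const = 1)
  expect_warning(m_c <- mfa(list(x = b3, y = b2)), "constant")
  expect_length(m_c$dropped_columns, 1)

  expect_error(mfa(list(x = b1)), "2 blocks")
  expect_error(mfa(list(x = b1, y = b2[1:10, ])), "row-aligned")
})

test_that("trend test matches exhaustive within-community enumeration", {
  # flat series: zero slope, p = 1
  flat <- matrix(2, nrow = 4, ncol = 5)
  tt <- diversity_trend_test(flat, n_perm = 49, seed = 1)
  expect_equal(tt$mean_slope, 0)
  expect_equal(tt$p_value, 1)

  # strictly decreasing series in every community, 3 time points:
  # verify the exhaustive p against an independently coded enumeration
  dec <- rbind(c(9, 6, 3), c(10, 7, 1))
  te <- diversity_trend_test(dec, exhaustive = TRUE)
  xc <- scale(1:3, scale = FALSE)[, 1]
  slope <- function(y) sum(y * xc) / sum(xc^2)
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  stats_all <- c()
  for (p1 in perms) for (p2 in perms)
    stats_all <- c(stats_all,
                   mean(c(slope(dec[1, p1]), slope(dec[2, p2]))))
  obs <- mean(c(slope(dec[1, ]), slope(dec[2, ])))
  expect_equal(te$mean_slope, obs)
  expect_equal(te$p_value, mean(abs(stats_all) >= abs(obs) - 1e-12),
               tolerance = 1e-12)
  expect_equal(te$n_permutations, 36)
  expect_lt(te$p_value, 0.2)  # extreme ordering is rare under the null

  expect_error(diversity_trend_test(dec[, 1:2]), "3 time points")
})

test_that("phenotype-taxonomy correlation handles exact and toy cases", {
  v <- stats::setNames(c(1.5, 3.2, 4.8, 7.1, 9.0), paste0("s", 1:5))
  same <- pheno_taxo_correlation(v, v, n_boot = 99, seed = 1)
  expect_equal(unname(same$pearson["estimate"]), 1)
  expect_equal(unname(same$spearman["estimate"]), 1)

  anti <- stats::setNames(rev(unname(v)), names(v))
  res <- pheno_taxo_correlation(v, anti, n_boot = 99, seed = 1)
  expect_equal(unname(res$spearman["estimate"]), -1)

  expect_error(pheno_taxo_correlation(v[1:2], v[1:2]), "3 matched")
  # independent noise: CI covers 0
  set.seed(5)
  a <- stats::setNames(stats::rnorm(40), paste0("s", 1:40))
  b <- stats::setNames(stats::rnorm(40), paste0("s", 1:40))
  rc <- pheno_taxo_correlation(a, b, n_boot = 499, seed = 2)
  expect_true(rc$pearson["ci_lower"] < 0 && rc$pearson["ci_upper"] > 0)
})
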