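test_that("intensity transform is monotone onto the unit interval", {
  ev <- data.frame(`FL1-H` = c(0, 10^4.5, 10, 1000),
                   `FL3-H` = c(1, 2, 3, 4), `FSC-H` = 1:4,
                   `SSC-H` = 4:1, check.names = FALSE)
  tr <- transform_events(ev)
  expect_equal(tr[["FL1-H"]][1], 0)
  expect_equal(tr[["FL1-H"]][2], 1)
  x <- with_seed(5, stats::runif(200, 0, 1e4))
  ev2 <- data.frame(`FL1-H` = x, `FL3-H` = x, `FSC-H` = x, `SSC-H` = x,
                    check.names = FALSE)
  tr2 <- transform_events(ev2)
  expect_identical(order(tr2[["FL1-H"]]), order(x))
  expect_true(all(tr2[["FL1-H"]] >= 0 & tr2[["FL1-H"]] <= 1))
  expect_error(transform_events(ev[, 1:2]), "missing channel")
})

test_that("polygon gating agrees with a half-plane intersection oracle", {
  sq <- polygon_gate(c("FL1-H", "FL3-H"),
                     cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)))
  mk <- function(x, y) data.frame(`FL1-H` = x, `FL3-H` = y,
                                  `FSC-H` = rep(0.5, length(x)),
                                  `SSC-H` = rep(0.5, length(x)),
                                  check.names = FALSE)
  expect_equal(nrow(apply_gate(mk(0.5, 0.5), sq)), 1)
  expect_equal(nrow(apply_gate(mk(1.5, 0.5), sq)), 0)
  expect_equal(nrow(apply_gate(mk(1, 0.5), sq)), 1)   # boundary retained
  expect_equal(nrow(apply_gate(mk(numeric(0), numeric(0)), sq)), 0)

  # 1e3 random points vs brute-force half-plane oracle on a convex gate
  tri <- cbind(x = c(0.2, 0.8, 0.5), y = c(0.2, 0.3, 0.9))
  gate <- polygon_gate(c("FL1-H", "FL3-H"), tri)
  pts <- with_seed(17, mk(stats::runif(1000), stats::runif(1000)))
  kept <- apply_gate(pts, gate)
  # oracle: inside a convex CCW polygon iff left of (or on) every edge
  inside_oracle <- rep(TRUE, 1000)
  v <- rbind(tri, tri[1, ])
  for (e in 1:3) {
    cross <- (v[e + 1, 1] - v[e, 1]) * (pts[["FL3-H"]] - v[e, 2]) -
      (v[e + 1, 2] - v[e, 2]) * (pts[["FL1-H"]] - v[e, 1])
    inside_oracle <- inside_oracle & (cross >= -1e-12)
  }
  expect_equal(nrow(kept), sum(inside_oracle))
  expect_setequal(rownames(kept), rownames(pts)[inside_oracle])
  expect_error(apply_gate(pts[, 3:4], gate), "absent")
})

test_that("QC excludes samples strictly below the cell threshold", {
  mk <- function(n) uniform_events(n, seed = n)
  samples <- list(a = mk(999), b = mk(1000), c = mk(5000), d = mk(10))
  qc <- qc_filter(samples)
  expect_identical(names(qc$kept), c("b", "c"))
  expect_identical(names(qc$excluded), c("a", "d"))
})

test_that("fingerprints are normalized, order-invariant and mass-faithful", {
  ev <- uniform_events(6000, seed = 3)
  fp <- compute_fingerprint(ev, nbin = 32, n_cells = 5000, seed = 777)
  expect_equal(sum(fp$densities), 1, tolerance = 1e-9)
  expect_true(all(fp$densities >= 0))
  expect_length(fp$densities, 6 * 32^2)

  # row permutation does not change the fingerprint (canonical ordering)
  perm <- with_seed(4, sample(nrow(ev)))
  fp2 <- compute_fingerprint(ev[perm, ], nbin = 32, n_cells = 5000,
                             seed = 777)
  expect_equal(fp$densities, fp2$densities)

  # all events at one point: one grid region carries essentially all mass
  pt <- ev; for (ch in names(pt)) pt[[ch]] <- 0.5
  fp_pt <- compute_fingerprint(pt, channel_pairs = list(c("FL1-H", "FL3-H")),
                               nbin = 32, n_cells = 5000, seed = 777)
  expect_lt(hill_diversity(fp_pt$densities, 2), 5)

  # uniform events: fingerprint entropy within 2% of the uniform bound
  h <- -sum(fp$densities[fp$densities > 0] *
              log(fp$densities[fp$densities > 0]))
  expect_gt(h / log(length(fp$densities)), 0.98)

  expect_error(compute_fingerprint(ev, n_cells = 10000), "undersampled")
})

test_that("Hill numbers satisfy hand oracles and q-monotonicity", {
  expect_equal(hill_diversity(rep(1, 37), 2), 37)
  for (q in c(0, 1, 2)) expect_equal(hill_diversity(c(0, 5, 0), q), 1)
  expect_equal(hill_diversity(c(0.7, 0.2, 0.1), 2), 1 / 0.54,
               tolerance = 1e-12)
  expect_equal(hill_diversity(c(0.7, 0.2, 0.1), 1),
               exp(-(0.7 * log(0.7) + 0.2 * log(0.2) + 0.1 * log(0.1))),
               tolerance = 1e-12)
  expect_error(hill_diversity(c(0, 0), 2), "positive sum")
  # D0 >= D1 >= D2 on random weight vectors
  for (i in 1:50) {
    w <- with_seed(i, stats::rgamma(20, 0.5))
    d <- vapply(c(0, 1, 2), function(q) hill_diversity(w, q), numeric(1))
    expect_true(d[1] >= d[2] - 1e-9 && d[2] >= d[3] - 1e-9)
  }
})

test_that("bootstrap phenotypic diversity degenerates and discriminates", {
  ev <- uniform_events(8000, seed = 6)
  pd <- phenotypic_diversity(ev, n_boot = 1, n_cells = 3000, seed = 42,
                             nbin = 32)
  fp <- compute_fingerprint(ev, n_cells = 3000, seed = 42, nbin = 32)
  expect_equal(unname(pd$mean["D2"]), hill_diversity(fp$densities, 2),
               tolerance = 1e-12)
  pd2 <- phenotypic_diversity(ev, n_boot = 3, n_cells = 3000, seed = 42,
                              nbin = 32)
  pd3 <- phenotypic_diversity(ev, n_boot = 3, n_cells = 3000, seed = 42,
                              nbin = 32)
  expect_identical(pd2, pd3)

  # two well-separated equal clusters are more diverse than one cluster
  one <- uniform_events(6000, seed = 7)
  for (ch in names(one)) one[[ch]] <- 0.25 + 0.02 * one[[ch]]
  two <- one
  shift <- seq_len(nrow(two)) %% 2 == 0
  for (ch in names(two)) two[[ch]][shift] <- two[[ch]][shift] + 0.5
  d2_one <- phenotypic_diversity(one, n_boot = 1, n_cells = 5000,
                                 seed = 1, nbin = 32)$mean["D2"]
  d2_two <- phenotypic_diversity(two, n_boot = 1, n_cells = 5000,
                                 seed = 1, nbin = 32)$mean["D2"]
  expect_gt(d2_two, d2_one)
})

test_that("cell density estimation is exact arithmetic and unbiased", {
  expect_equal(total_cell_density(1e4, 50, 1000), 2e8)
  expect_equal(total_cell_density(0, 50, 1000), 0)
  expect_equal(total_cell_density(1e4, 50, 5000),
               5 * total_cell_density(1e4, 50, 1000))
  # unbiasedness over 200 Poisson draws of the gated count
  true_density <- 3e8
  lambda <- true_density * (50 / 1000) / 1000
  counts <- with_seed(30, stats::rpois(200, lambda))
  est <- total_cell_density(counts, 50, 1000)
  se <- stats::sd(est) / sqrt(200)
  expect_lt(abs(mean(est) - true_density), 2 * se)
})
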