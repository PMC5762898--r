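#' Bray-Curtis distance matrix from a count table
#'
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i) between sample columns,
#' computed on (typically rarefied) counts via vegan.
#'
#' @param counts phylotype x sample matrix with positive column sums.
#' @return `dist` object over samples, entries in \[0, 1\].
#' @export
bray_curtis <- function(counts) {
  counts <- validate_count_table(counts)
  if (any(colSums(counts) <= 0)) stop("empty sample in count table")
  vegan::vegdist(t(counts), method = "bray")
}

# distance-based sums of squares for a one-way design
#' @keywords internal
permanova_ss <- function(d2, labels) {
  n <- attr(d2, "Size")
  m <- as.matrix(d2)
  ss_total <- sum(m[upper.tri(m)]) / n
  ss_within <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    if (length(idx) > 1) {
      sub <- m[idx, idx]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  c(total = ss_total, within = ss_within, between = ss_total - ss_within)
}

#' One-way PERMANOVA on a distance matrix
#'
#' Partitions distance-based sums of squares by group (equivalently the
#' trace of the Gower-centred inner-product matrix), forms the pseudo-F
#' statistic F = (SS_b / (a-1)) / (SS_w / (N-a)), and estimates the
#' p-value by whole-label permutation with the add-one estimator
#' p = (1 + #\{F* >= F\}) / (1 + n_perm). When `exhaustive = TRUE` (or the
#' number of distinct permutations is at most `n_perm`), all label
#' permutations are enumerated instead.
#'
#' @param d `dist` object or symmetric distance matrix.
#' @param labels group labels, one per sample (>= 2 groups).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @param exhaustive force exhaustive enumeration of all n! permutations.
#' @return List of class `permanova_result`: `pseudo_f`, `r_squared`,
#'   `p_value`, `n_permutations`, `seed`, `exhaustive`.
#' @export
permanova <- function(d, labels, n_perm = 999L, seed = 1L,
                      exhaustive = FALSE) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels must match the distance matrix")
  a <- length(unique(labels))
  if (a < 2) stop("PERMANOVA needs at least 2 groups")
  d2 <- d^2
  ss <- permanova_ss(d2, labels)
  ms_b <- ss["between"] / (a - 1)
  ms_w <- ss["within"] / (n - a)
  # a zero within-group SS (all groups singleton or identical members)
  # gives an infinite pseudo-F when any between-group spread remains
  safe_f <- function(ms_b, ms_w) {
    f <- ms_b / ms_w
    if (is.finite(f)) f else if (ms_b > 0) Inf else 0
  }
  f_obs <- unname(safe_f(ms_b, ms_w))
  r2 <- unname(ss["between"] / ss["total"])

  f_of <- function(lab) {
    s <- permanova_ss(d2, lab)
    unname(safe_f(s["between"] / (a - 1), s["within"] / (n - a)))
  }
  if (exhaustive || factorial(n) <= n_perm) {
    perms <- all_permutations(n)
    f_star <- apply(perms, 1, function(idx) f_of(labels[idx]))
    # observed arrangement is one of the enumerated ones: exact p
    p <- mean(f_star >= f_obs - 1e-12)
    n_done <- nrow(perms)
  } else {
    f_star <- with_seed(seed, vapply(seq_len(n_perm), function(i)
      f_of(sample(labels)), numeric(1)))
    p <- (1 + sum(f_star >= f_obs - 1e-12)) / (1 + n_perm)
    n_done <- n_perm
  }
  structure(list(pseudo_f = f_obs, r_squared = r2, p_value = p,
                 n_permutations = n_done, seed = seed,
                 exhaustive = exhaustive || factorial(n) <= n_perm),
            class = "permanova_result")
}

# all permutations of seq_len(n) as rows (n <= 8 or so)
#' @keywords internal
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                           drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Principal coordinate analysis of a distance matrix
#'
#' Eigendecomposition of the Gower-centred matrix (via
#' `stats::cmdscale`); axes are ordered by non-increasing eigenvalue,
#' coordinates scaled by the square root of the eigenvalue, negative
#' eigenvalues dropped with their relative mass recorded.
#'
#' @param d `dist` or symmetric distance matrix.
#' @param k axes to retain (default all positive).
#' @return List of class `ordination_result`: `coordinates` (samples x
#'   axes), `eigenvalues`, `proportion` (variance share per axis),
#'   `negative_mass` (|sum of negative eigenvalues| / sum |eigenvalues|).
#' @export
pcoa_ordination <- function(d, k = NULL) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (n < 2) {
    return(structure(list(
      coordinates = matrix(0, n, 0,
                           dimnames = list(attr(d, "Labels"), NULL)),
      eigenvalues = numeric(0), proportion = numeric(0),
      negative_mass = 0), class = "ordination_result"))
  }
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > 1e-12)
  if (is.null(k)) k <- length(pos) else k <- min(k, length(pos))
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(k))
  neg_mass <- if (any(eig < 0)) abs(sum(eig[eig < 0])) / sum(abs(eig)) else 0
  structure(list(coordinates = coords,
                 eigenvalues = eig[pos][seq_len(k)],
                 proportion = (eig[pos] / sum(eig[pos]))[seq_len(k)],
                 negative_mass = neg_mass),
            class = "ordination_result")
}

#' Group dispersion (distance to own-group centroid) with pairwise tests
#'
#' Per-sample distances to the group centroid come from
#' `vegan::betadisper` (centroids in principal-coordinate space). Pairwise
#' differences in mean dispersion between groups are tested by permuting
#' the centroid distances between the two groups (two-sided, add-one
#' estimator) with Holm correction across pairs.
#'
#' @param d `dist` or symmetric matrix.
#' @param labels group labels (>= 2 groups).
#' @param n_perm permutations per pairwise test (default 999).
#' @param seed RNG seed.
#' @return List of class `dispersion_result`: `distances` (data.frame
#'   sample, group, dist_to_centroid), `pairwise` (data.frame group1,
#'   group2, mean_diff, p_value, p_adjusted), `n_permutations`, `seed`.
#' @export
group_dispersion <- function(d, labels, n_perm = 999L, seed = 1L) {
  d <- stats::as.dist(d)
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) < 2) stop("need >= 2 groups")
  bd <- vegan::betadisper(d, group = factor(labels), type = "centroid")
  z <- as.numeric(bd$distances)
  singleton <- table(labels)[groups] == 1
  if (any(singleton))
    warning("singleton group(s) with dispersion 0: ",
            paste(groups[singleton], collapse = ", "))
  pairs <- utils::combn(sort(groups), 2, simplify = FALSE)
  res <- lapply(pairs, function(pr) {
    zi <- z[labels == pr[1]]; zj <- z[labels == pr[2]]
    obs <- mean(zi) - mean(zj)
    pooled <- c(zi, zj)
    n1 <- length(zi)
    stat <- with_seed(derive_seed(seed, "disp", pr[1], pr[2]),
      vapply(seq_len(n_perm), function(i) {
        idx <- sample(length(pooled), n1)
        mean(pooled[idx]) - mean(pooled[-idx])
      }, numeric(1)))
    p <- (1 + sum(abs(stat) >= abs(obs) - 1e-12)) / (1 + n_perm)
    data.frame(group1 = pr[1], group2 = pr[2], mean_diff = obs,
               p_value = p, stringsAsFactors = FALSE)
  })
  pairwise <- do.call(rbind, res)
  pairwise$p_adjusted <- stats::p.adjust(pairwise$p_value, method = "holm")
  structure(list(
    distances = data.frame(sample = if (!is.null(attr(d, "Labels")))
      attr(d, "Labels") else seq_along(z),
      group = labels, dist_to_centroid = z, stringsAsFactors = FALSE),
    pairwise = pairwise, n_permutations = n_perm, seed = seed),
    class = "dispersion_result")
}

#' Multiple factor analysis over named variable blocks
#'
#' Each continuous block is column-standardized and divided by its first
#' singular value, so no block dominates the global solution (after
#' weighting every block's first singular value is exactly 1). An optional
#' categorical block is indicator-coded with multiple-correspondence
#' scaling (columns divided by the square root of their category
#' proportion, then centred) and weighted the same way. The weighted
#' blocks are concatenated and decomposed by SVD (global PCA). Category
#' positions on each global dimension are summarized by v-tests:
#' v = mean_k / sqrt(((N - n_k) / (N - 1)) * s2_dim / n_k) with dimension
#' scores centred, mapped to a normal quantile scale.
#'
#' @param blocks named list of numeric data.frames/matrices, row-aligned.
#' @param categorical optional factor/character vector (one per row) used
#'   for the v-tests and, when `categorical_active = TRUE`, as an active
#'   categorical block.
#' @param categorical_active should the categorical block co-determine the
#'   global axes (default `TRUE`)? With `FALSE` the category is
#'   supplementary: v-tests are computed against axes built from the
#'   continuous blocks alone, the appropriate setting when the v-test is
#'   used as a null-calibrated test of category-axis association.
#' @param n_dims dimensions to report (default 5).
#' @return List of class `mfa_model`: `scores` (rows x dims),
#'   `variance_pct`, `correlations` (continuous variables x dims),
#'   `v_tests` (categories x dims), `block_weights`, `dropped_columns`.
#' @export
mfa <- function(blocks, categorical = NULL, categorical_active = TRUE,
                n_dims = 5L) {
  if (!is.list(blocks) || is.null(names(blocks)))
    stop("blocks must be a named list")
  n <- nrow(as.matrix(blocks[[1]]))
  n_blocks <- length(blocks) +
    as.integer(!is.null(categorical) && categorical_active)
  if (n_blocks < 2) stop("MFA needs at least 2 blocks")
  dropped <- character(0)
  prep <- list()
  weights <- numeric(0)
  raw_cont <- list()
  for (nm in names(blocks)) {
    b <- as.matrix(blocks[[nm]])
    if (nrow(b) != n) stop("blocks must be row-aligned")
    sds <- apply(b, 2, stats::sd)
    if (any(sds == 0)) {
      dropped <- c(dropped, paste0(nm, ":", colnames(b)[sds == 0]))
      warning("dropping constant column(s): ",
              paste(colnames(b)[sds == 0], collapse = ", "))
      b <- b[, sds > 0, drop = FALSE]
      sds <- sds[sds > 0]
    }
    raw_cont[[nm]] <- b
    bs <- scale(b, center = TRUE, scale = sds)
    s1 <- svd(bs, nu = 0, nv = 0)$d[1]
    weights[nm] <- 1 / s1
    prep[[nm]] <- bs / s1
  }
  if (!is.null(categorical) && categorical_active) {
    f <- factor(categorical)
    if (length(f) != n) stop("categorical must have one entry per row")
    ind <- stats::model.matrix(~ f - 1)
    colnames(ind) <- levels(f)
    prop <- colMeans(ind)
    mca <- scale(sweep(ind, 2, sqrt(prop), "/"), center = TRUE,
                 scale = FALSE)
    s1 <- svd(mca, nu = 0, nv = 0)$d[1]
    weights[".categorical"] <- 1 / s1
    prep[[".categorical"]] <- mca / s1
  }
  X <- do.call(cbind, prep)
  sv <- svd(X)
  pos <- sv$d > 1e-10
  k <- min(n_dims, sum(pos))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  colnames(scores) <- paste0("Dim", seq_len(k))
  variance_pct <- 100 * sv$d[seq_len(k)]^2 / sum(sv$d[pos]^2)
  cont <- do.call(cbind, raw_cont)
  correlations <- stats::cor(cont, scores)
  v_tests <- NULL
  if (!is.null(categorical)) {
    f <- factor(categorical)
    ctr <- scale(scores, center = TRUE, scale = FALSE)
    v_tests <- t(vapply(levels(f), function(lv) {
      idx <- f == lv
      nk <- sum(idx)
      xbar <- colMeans(ctr[idx, , drop = FALSE])
      s2 <- colMeans(ctr^2)  # population variance of centred scores
      as.numeric(xbar / sqrt(((n - nk) / (n - 1)) * s2 / nk))
    }, numeric(k)))
    dimnames(v_tests) <- list(levels(f), colnames(scores))
  }
  structure(list(scores = scores, variance_pct = variance_pct,
                 correlations = correlations, v_tests = v_tests,
                 block_weights = weights, dropped_columns = dropped,
                 singular_values = sv$d[seq_len(k)]),
            class = "mfa_model")
}

#' Permutation trend test for diversity across transfers
#'
#' Fits a per-community least-squares slope of diversity against transfer
#' index, takes the group mean slope as the statistic, and builds the null
#' by independently permuting transfer labels within each community
#' (two-sided, add-one estimator). `exhaustive = TRUE` enumerates every
#' combination of within-community permutations (small designs only).
#'
#' @param values matrix of diversity values, communities x transfers.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @param exhaustive enumerate all within-community label permutations.
#' @return List of class `trend_test_result`: `mean_slope`, `p_value`,
#'   `n_permutations`, `seed`, `slopes` (per community).
#' @export
diversity_trend_test <- function(values, n_perm = 999L, seed = 1L,
                                 exhaustive = FALSE) {
  values <- as.matrix(values)
  nt <- ncol(values)
  if (nt < 3) stop("trend test needs >= 3 time points")
  x <- seq_len(nt)
  xc <- x - mean(x)
  slope_of <- function(row, ord) sum(row * xc[order(ord)]) / sum(xc^2)
  slopes <- apply(values, 1, function(row) sum(row * xc) / sum(xc^2))
  obs <- mean(slopes)
  nc <- nrow(values)
  if (exhaustive) {
    perms <- all_permutations(nt)
    np <- nrow(perms)
    if (np^nc > 2e6) stop("exhaustive enumeration too large")
    combos <- as.matrix(expand.grid(rep(list(seq_len(np)), nc)))
    stat <- apply(combos, 1, function(sel) {
      mean(vapply(seq_len(nc), function(c_) {
        sum(values[c_, perms[sel[c_], ]] * xc) / sum(xc^2)
      }, numeric(1)))
    })
    p <- mean(abs(stat) >= abs(obs) - 1e-12)
    n_done <- length(stat)
  } else {
    stat <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      mean(vapply(seq_len(nc), function(c_)
        sum(values[c_, sample(nt)] * xc) / sum(xc^2), numeric(1)))
    }, numeric(1)))
    p <- (1 + sum(abs(stat) >= abs(obs) - 1e-12)) / (1 + n_perm)
    n_done <- n_perm
  }
  structure(list(mean_slope = obs, p_value = p, n_permutations = n_done,
                 seed = seed, slopes = slopes),
            class = "trend_test_result")
}

#' Correlation between phenotypic and taxonomic diversity
#'
#' Pearson and Spearman correlations over matched samples at a given Hill
#' order, with percentile bootstrap confidence intervals over resampled
#' pairs.
#'
#' @param pheno named numeric vector of phenotypic diversity (sample ids
#'   as names).
#' @param taxo named numeric vector of taxonomic diversity.
#' @param n_boot bootstrap resamples for the CI (default 999).
#' @param seed RNG seed.
#' @return List of class `diversity_correlation`: `pearson`, `spearman`
#'   (each: estimate, ci_lower, ci_upper), `n_pairs`.
#' @export
pheno_taxo_correlation <- function(pheno, taxo, n_boot = 999L, seed = 1L) {
  common <- intersect(names(pheno), names(taxo))
  if (length(common) < 3) stop("need >= 3 matched sample pairs")
  x <- pheno[common]; y <- taxo[common]
  est <- c(pearson = stats::cor(x, y, method = "pearson"),
           spearman = stats::cor(x, y, method = "spearman"))
  boot <- with_seed(seed, t(vapply(seq_len(n_boot), function(i) {
    idx <- sample(length(x), replace = TRUE)
    c(stats::cor(x[idx], y[idx], method = "pearson"),
      stats::cor(x[idx], y[idx], method = "spearman"))
  }, numeric(2))))
  ci <- apply(boot, 2, stats::quantile, c(0.025, 0.975), na.rm = TRUE,
              names = FALSE)
  structure(list(
    pearson = c(estimate = unname(est["pearson"]), ci_lower = ci[1, 1],
                ci_upper = ci[2, 1]),
    spearman = c(estimate = unname(est["spearman"]), ci_lower = ci[1, 2],
                 ci_upper = ci[2, 2]),
    n_pairs = length(common)),
    class = "diversity_correlation")
}
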