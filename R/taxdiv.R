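#' Abundance-filter a phylotype count table
#'
#' Keeps phylotype i iff it reaches relative abundance above
#' `any_threshold` in at least one sample, OR exceeds `all_threshold` in
#' every sample. Relative abundances are computed on the unrarefied
#' per-sample totals. Defaults read the conventional ">0.1%" /
#' ">0.001%" rule literally as fractions 0.001 and 0.00001.
#'
#' @param counts phylotype x sample integer matrix (named dims).
#' @param any_threshold single-sample relative-abundance threshold
#'   (default 0.001).
#' @param all_threshold every-sample threshold (default 1e-5).
#' @return Filtered count matrix (same samples, surviving phylotypes).
#' @export
filter_phylotypes <- function(counts, any_threshold = 0.001,
                              all_threshold = 1e-5) {
  counts <- validate_count_table(counts)
  tot <- colSums(counts)
  if (any(tot <= 0)) stop("every sample must have positive total counts")
  rel <- sweep(counts, 2, tot, "/")
  keep <- apply(rel, 1, max) > any_threshold |
    apply(rel, 1, min) > all_threshold
  counts[keep, , drop = FALSE]
}

#' @keywords internal
validate_count_table <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(counts != round(counts))) stop("counts must be integers")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("phylotype", seq_len(nrow(counts)))
  counts
}

#' Rarefy a count table to a common depth
#'
#' Each sample with total >= `depth` is subsampled without replacement to
#' exactly `depth` reads; samples below depth are dropped with a warning
#' naming them.
#'
#' @param counts phylotype x sample matrix.
#' @param depth target depth (default 3317).
#' @param seed RNG seed; each sample uses a derived sub-seed so results do
#'   not depend on sample order.
#' @return Rarefied matrix whose retained columns each sum to `depth`.
#' @export
rarefy_counts <- function(counts, depth = 3317L, seed = 1L) {
  counts <- validate_count_table(counts)
  if (depth < 1) stop("depth must be >= 1")
  depth <- as.integer(depth)
  tot <- colSums(counts)
  low <- tot < depth
  if (any(low))
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(low), depth,
                    paste(colnames(counts)[low], collapse = ", ")))
  keep <- which(!low)
  out <- matrix(0L, nrow(counts), length(keep),
                dimnames = list(rownames(counts), colnames(counts)[keep]))
  for (j in seq_along(keep)) {
    x <- counts[, keep[j]]
    reads <- rep(seq_along(x), x)
    sub <- with_seed(derive_seed(seed, "rarefy", colnames(counts)[keep[j]]),
                     sample(reads, depth, replace = FALSE))
    out[, j] <- tabulate(sub, nbins = length(x))
  }
  out
}

#' Fisher's log-series alpha
#'
#' Solves S = alpha * ln(1 + N / alpha) for alpha by safeguarded Newton
#' iteration with bisection fallback on \[1e-6, 1e6\], to residual 1e-8.
#' S = 1 and S >= N have no meaningful finite solution and return `NA`.
#'
#' @param S observed richness.
#' @param N total reads.
#' @param tol residual tolerance (default 1e-8).
#' @return alpha, or `NA_real_` when undefined.
#' @export
fisher_alpha <- function(S, N, tol = 1e-8) {
  if (S <= 1 || S >= N) return(NA_real_)
  f <- function(a) a * log1p(N / a) - S
  lo <- 1e-6; hi <- 1e6
  if (f(lo) > 0 || f(hi) < 0) return(NA_real_)
  a <- max(lo, min(hi, S / log(N)))  # crude start
  for (i in 1:100) {
    fa <- f(a)
    if (abs(fa) < tol) return(a)
    if (fa > 0) hi <- a else lo <- a
    # f'(a) = ln(1 + N/a) - N/(a + N)
    step <- fa / (log1p(N / a) - N / (a + N))
    a_new <- a - step
    if (!is.finite(a_new) || a_new <= lo || a_new >= hi)
      a_new <- (lo + hi) / 2  # bisection safeguard
    a <- a_new
  }
  a
}

#' Alpha-diversity table for every sample of a count table
#'
#' Per sample: richness S, Shannon H' (natural log), Pielou J = H'/ln S
#' (`NA` when S < 2), Simpson 1 - lambda, inverse Simpson 1/lambda,
#' Fisher's alpha, Hill numbers D0/D1/D2, and depth N. Shannon, Simpson
#' and inverse Simpson are delegated to vegan; Hill numbers come from
#' [hill_diversity()] so the identities D0 = S, D1 = exp(H'),
#' D2 = invSimpson are verifiable cross-checks, not definitions.
#'
#' @param counts phylotype x sample matrix (positive column sums).
#' @return data.frame, one row per sample: sample_id, richness, shannon,
#'   pielou, simpson, inv_simpson, fisher_alpha, D0, D1, D2, depth.
#' @export
alpha_diversity <- function(counts) {
  counts <- validate_count_table(counts)
  tot <- colSums(counts)
  if (any(tot <= 0)) stop("empty sample(s): ",
                          paste(colnames(counts)[tot <= 0], collapse = ", "))
  x <- t(counts)  # vegan convention: samples in rows
  sh <- vegan::diversity(x, index = "shannon")
  si <- vegan::diversity(x, index = "simpson")
  is <- vegan::diversity(x, index = "invsimpson")
  s <- rowSums(x > 0)
  data.frame(
    sample_id = colnames(counts),
    richness = as.integer(s),
    shannon = unname(sh),
    pielou = unname(ifelse(s >= 2, sh / log(s), NA_real_)),
    simpson = unname(si),
    inv_simpson = unname(is),
    fisher_alpha = vapply(seq_len(ncol(counts)), function(j)
      fisher_alpha(s[j], tot[j]), numeric(1)),
    D0 = vapply(seq_len(ncol(counts)), function(j)
      hill_diversity(counts[, j], 0), numeric(1)),
    D1 = vapply(seq_len(ncol(counts)), function(j)
      hill_diversity(counts[, j], 1), numeric(1)),
    D2 = vapply(seq_len(ncol(counts)), function(j)
      hill_diversity(counts[, j], 2), numeric(1)),
    depth = unname(tot),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Analytic rarefaction curve (expected richness at given depths)
#'
#' Expected richness in a subsample of n reads follows the hypergeometric
#' form E\[S_n\] = sum_i (1 - choose(N - N_i, n) / choose(N, n)), evaluated
#' deterministically via vegan.
#'
#' @param counts phylotype x sample matrix.
#' @param depths integer depths, each <= the smallest sample total used.
#' @return data.frame: sample_id, depth, expected_richness.
#' @export
rarefaction_curve <- function(counts, depths) {
  counts <- validate_count_table(counts)
  tot <- colSums(counts)
  if (any(depths < 1)) stop("depths must be >= 1")
  if (any(depths > min(tot)))
    stop(sprintf("depth %d exceeds the smallest sample total (%d)",
                 max(depths), min(tot)))
  grid <- expand.grid(sample_id = colnames(counts), depth = depths,
                      stringsAsFactors = FALSE)
  # vegan warns heuristically when counts lack singletons; inputs here are
  # validated integer counts, so the warning carries no information
  grid$expected_richness <- vapply(seq_len(nrow(grid)), function(i)
    suppressWarnings(as.numeric(
      vegan::rarefy(t(counts[, grid$sample_id[i], drop = FALSE]),
                    grid$depth[i]))),
    numeric(1))
  grid
}

#' Group means of a diversity table
#'
#' Aggregates each numeric index by the given metadata columns. Group
#' comparison (permutation testing) lives in the statistics layer; this
#' only averages.
#'
#' @param div diversity data.frame from [alpha_diversity()], augmented
#'   with metadata columns.
#' @param by character vector of grouping columns present in `div`.
#' @return data.frame of per-group means for every numeric index.
#' @export
group_summary <- function(div, by = c("evenness_class", "transfer")) {
  missing_by <- setdiff(by, names(div))
  if (length(missing_by))
    stop("grouping column(s) absent: ", paste(missing_by, collapse = ", "))
  num <- names(div)[vapply(div, is.numeric, logical(1))]
  num <- setdiff(num, by)
  agg <- stats::aggregate(div[num], by = div[by], FUN = mean,
                          na.rm = TRUE)
  agg[do.call(order, agg[by]), , drop = FALSE]
}
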