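#' Transform raw cytometry intensities to the unit interval
#'
#' Applies x -> asinh(x / cofactor), then min-max scales by the fixed
#' instrument range, so every channel lands in \[0, 1\] with a monotone,
#' deterministic map. asinh behaves like log at high intensity while
#' remaining defined at zero.
#'
#' @param events event data.frame (channels + optional `label`).
#' @param channels channel columns to transform.
#' @param cofactor asinh cofactor (default 1).
#' @param range_max fixed instrument maximum intensity (default 10^4.5).
#' @return Same shape data.frame with transformed channel columns in
#'   \[0, 1\]; non-channel columns untouched.
#' @export
transform_events <- function(events,
                             channels = c("FL1-H", "FL3-H", "FSC-H",
                                          "SSC-H"),
                             cofactor = 1, range_max = 10^4.5) {
  missing_ch <- setdiff(channels, names(events))
  if (length(missing_ch))
    stop("missing channel column(s): ", paste(missing_ch, collapse = ", "))
  denom <- asinh(range_max / cofactor)
  for (ch in channels) {
    if (any(events[[ch]] < 0)) stop("intensities must be >= 0: ", ch)
    events[[ch]] <- pmin(asinh(events[[ch]] / cofactor) / denom, 1)
  }
  events
}

#' Default polygon gate on transformed FL1-H x FL3-H
#'
#' Retains the cell clusters and excludes the low-FL1 debris region of the
#' stock channel signatures. Vertices are in transformed (unit-interval)
#' coordinates.
#'
#' @return List of class `polygon_gate` with `channels` and `vertices`
#'   (matrix, columns x/y).
#' @export
default_gate <- function() {
  polygon_gate(channels = c("FL1-H", "FL3-H"),
               vertices = cbind(x = c(0.42, 1, 1, 0.42),
                                y = c(0, 0, 1, 1)))
}

#' Construct a polygon gate
#' @param channels length-2 character vector naming the gated channel pair.
#' @param vertices numeric matrix (>= 3 rows, 2 columns) of polygon
#'   vertices in transformed coordinates.
#' @return List of class `polygon_gate`.
#' @export
polygon_gate <- function(channels, vertices) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3 || ncol(vertices) != 2)
    stop("a polygon gate needs >= 3 vertices of 2 coordinates")
  structure(list(channels = channels, vertices = vertices),
            class = "polygon_gate")
}

# even-odd rule point-in-polygon, boundary-inclusive; vectorized over points
#' @keywords internal
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # boundary: collinear and within segment bounding box
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    seg <- abs(cross) < 1e-12 &
      px >= pmin(x1, x2) - 1e-12 & px <= pmax(x1, x2) + 1e-12 &
      py >= pmin(y1, y2) - 1e-12 & py <= pmax(y1, y2) + 1e-12
    on_edge <- on_edge | seg
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Apply a polygon gate to transformed events
#'
#' Retains events strictly inside or on the boundary of the polygon
#' (even-odd rule) in the gate's channel pair.
#'
#' @param events transformed event data.frame.
#' @param gate a `polygon_gate`.
#' @return Gated event data.frame (attributes preserved).
#' @export
apply_gate <- function(events, gate = default_gate()) {
  stopifnot(inherits(gate, "polygon_gate"))
  missing_ch <- setdiff(gate$channels, names(events))
  if (length(missing_ch))
    stop("gate channel(s) absent from events: ",
         paste(missing_ch, collapse = ", "))
  if (nrow(events) == 0) return(events)
  keep <- point_in_polygon(events[[gate$channels[1]]],
                           events[[gate$channels[2]]],
                           gate$vertices[, 1], gate$vertices[, 2])
  out <- events[keep, , drop = FALSE]
  for (a in c("dilution", "acquired_volume"))
    attr(out, a) <- attr(events, a)
  out
}

#' Quality-control filter on gated cell counts
#'
#' A sample is excluded iff its gated event count is strictly below
#' `min_cells` (default 1000).
#'
#' @param samples named list of gated event tables.
#' @param min_cells minimum gated cell count (default 1000).
#' @return List with `kept` and `excluded` (named lists).
#' @export
qc_filter <- function(samples, min_cells = 1000L) {
  if (min_cells < 1) stop("min_cells must be >= 1")
  n <- vapply(samples, nrow, integer(1))
  list(kept = samples[n >= min_cells], excluded = samples[n < min_cells])
}

#' Kernel-density phenotype fingerprint of a cytometry sample
#'
#' Subsamples `n_cells` events without replacement (after lexicographic
#' canonicalization, so row order never changes the result), evaluates an
#' exact Gaussian product-kernel density on an `nbin` x `nbin` uniform grid
#' over \[0,1\]^2 for every channel pair, concatenates the grids and
#' normalizes to total mass 1.
#'
#' @param events transformed, gated event data.frame.
#' @param channel_pairs list of length-2 character vectors; default all 6
#'   unordered pairs of the 4 stock channels.
#' @param nbin grid resolution per axis (default 128).
#' @param bandwidth Gaussian kernel sd on the unit scale (default 0.01).
#' @param n_cells events to subsample (default 5000).
#' @param seed RNG seed for the subsample.
#' @return List of class `phenotype_fingerprint`: `densities` (vector of
#'   length n_pairs * nbin^2, sums to 1), `channel_pairs`, `nbin`,
#'   `bandwidth`, `n_cells`, `seed`.
#' @export
compute_fingerprint <- function(events, channel_pairs = NULL, nbin = 128L,
                                bandwidth = 0.01, n_cells = 5000L,
                                seed = 777L) {
  channels <- c("FL1-H", "FL3-H", "FSC-H", "SSC-H")
  channels <- channels[channels %in% names(events)]
  if (is.null(channel_pairs))
    channel_pairs <- utils::combn(channels, 2, simplify = FALSE)
  if (nrow(events) < n_cells)
    stop(sprintf("undersampled: %d events available, %d requested",
                 nrow(events), n_cells))
  m <- as.matrix(events[, channels, drop = FALSE])
  ord <- do.call(order, as.data.frame(m))  # canonical row order
  m <- m[ord, , drop = FALSE]
  idx <- with_seed(seed, sample(nrow(m), n_cells, replace = FALSE))
  m <- m[idx, , drop = FALSE]
  grid <- (seq_len(nbin) - 0.5) / nbin
  dens <- lapply(channel_pairs, function(pr) {
    # exact product-kernel sum via rank-1 decomposition:
    # f(gx,gy) = sum_i K(gx - x_i) K(gy - y_i) = (Kx %*% t(Ky))[gx,gy]
    kx <- outer(grid, m[, pr[1]],
                function(g, x) stats::dnorm(g, x, bandwidth))
    ky <- outer(grid, m[, pr[2]],
                function(g, y) stats::dnorm(g, y, bandwidth))
    as.vector(kx %*% t(ky))
  })
  v <- unlist(dens, use.names = FALSE)
  v <- v / sum(v)
  structure(list(densities = v, channel_pairs = channel_pairs,
                 nbin = as.integer(nbin), bandwidth = bandwidth,
                 n_cells = as.integer(n_cells), seed = seed,
                 transform = "asinh-minmax"),
            class = "phenotype_fingerprint")
}

#' Hill diversity of order q
#'
#' Effective number of equally weighted types: for q != 1,
#' D_q = (sum p_i^q)^(1/(1-q)); for q = 1, D_1 = exp(-sum p_i ln p_i);
#' for q = 0 it counts entries above a relative-mass threshold `eps`
#' (a kernel density estimate is nowhere exactly zero, so occupied bins
#' are those carrying more than `eps` of total mass).
#'
#' @param weights non-negative weights (need not be normalized).
#' @param q diversity order.
#' @param eps occupancy threshold for q = 0 (fraction of total mass).
#' @return Effective number (scalar >= 1 for a non-degenerate input).
#' @export
#' @examples
#' hill_diversity(c(0.7, 0.2, 0.1), 2)  # 1/(0.49 + 0.04 + 0.01)
hill_diversity <- function(weights, q, eps = 1e-10) {
  if (any(weights < 0) || any(!is.finite(weights)))
    stop("weights must be finite and non-negative")
  tot <- sum(weights)
  if (tot <= 0) stop("weights must have positive sum")
  p <- weights / tot
  if (q == 0) return(sum(p > eps))
  p <- p[p > 0]
  if (q == 1) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

#' Bootstrap phenotypic diversity of a cytometry sample
#'
#' Repeats the subsample-fingerprint-Hill computation `n_boot` times with
#' derived seeds and reports, per order, the mean and the 2.5/97.5
#' percentile interval. With `n_boot = 1` this reproduces
#' `hill_diversity(compute_fingerprint(...))` exactly.
#'
#' @param events transformed, gated event data.frame (must pass QC).
#' @param orders Hill orders to report (default 0, 1, 2).
#' @param n_boot bootstrap resamples (default 10).
#' @param n_cells subsample size per resample (default 5000).
#' @param seed base RNG seed; resample b uses `seed + b - 1`.
#' @param ... passed to [compute_fingerprint()].
#' @return List of class `pheno_diversity`: `mean`, `ci_lower`, `ci_upper`
#'   (named by D0/D1/D2...), `boot` (matrix n_boot x orders), `n_cells`,
#'   `seed`.
#' @export
phenotypic_diversity <- function(events, orders = c(0, 1, 2), n_boot = 10L,
                                 n_cells = 5000L, seed = 777L, ...) {
  boot <- matrix(NA_real_, n_boot, length(orders),
                 dimnames = list(NULL, paste0("D", orders)))
  for (b in seq_len(n_boot)) {
    fp <- compute_fingerprint(events, n_cells = n_cells,
                              seed = seed + b - 1L, ...)
    boot[b, ] <- vapply(orders, function(q)
      hill_diversity(fp$densities, q), numeric(1))
  }
  structure(list(
    mean = colMeans(boot),
    ci_lower = apply(boot, 2, stats::quantile, 0.025, names = FALSE),
    ci_upper = apply(boot, 2, stats::quantile, 0.975, names = FALSE),
    boot = boot, n_cells = as.integer(n_cells), seed = seed),
    class = "pheno_diversity")
}

#' Total cell density from a gated event count
#'
#' density = gated_count / acquired volume (mL) * dilution factor.
#'
#' @param gated_count number of gated events.
#' @param acquired_volume acquired volume in microlitres.
#' @param dilution pre-measurement dilution factor.
#' @return Cells per mL.
#' @export
#' @examples
#' total_cell_density(1e4, 50, 1000)  # 2e8
total_cell_density <- function(gated_count, acquired_volume, dilution) {
  if (acquired_volume <= 0) stop("acquired_volume must be positive")
  gated_count / (acquired_volume / 1000) * dilution
}
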