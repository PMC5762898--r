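#' Pielou evenness of a composition vector
#'
#' J = H' / ln(S), where H' = -sum p_i ln p_i over strictly positive
#' fractions and S is the number of strictly positive fractions. Natural
#' logarithms throughout. J is 1 for a perfectly even community and
#' approaches 0 under extreme dominance.
#'
#' @param p numeric vector of relative abundances (non-negative, summing
#'   to 1 within 1e-9). Zero entries are ignored; they do not count toward
#'   richness.
#' @return Scalar J in \[0, 1\].
#' @export
#' @examples
#' pielou_evenness(rep(0.1, 10))   # 1
#' pielou_evenness(c(0.91, rep(0.01, 9)))
pielou_evenness <- function(p) {
  validate_composition(p)
  pos <- p[p > 0]
  s <- length(pos)
  if (s < 2)
    stop("Pielou evenness is undefined for a single-species composition ",
         "(ln S = 0)")
  h <- -sum(pos * log(pos))
  h / log(s)
}

#' @keywords internal
validate_composition <- function(p, tol = 1e-9) {
  if (!is.numeric(p) || length(p) < 1)
    stop("composition must be a non-empty numeric vector")
  if (any(!is.finite(p)) || any(p < 0))
    stop("composition fractions must be finite and non-negative")
  if (abs(sum(p) - 1) > tol)
    stop(sprintf("composition fractions must sum to 1 (got %.12f)", sum(p)))
  invisible(p)
}

#' Classify a Pielou evenness value into the panel's strata
#'
#' Strata are Low = \[0, 0.3\], Medium = (0.4, 0.6\], High = (0.6, 1\].
#' Values in the unassigned gap (0.3, 0.4\] return `NA` ("unclassifiable");
#' callers typically discard such candidates rather than treat this as an
#' error.
#'
#' @param j numeric vector of Pielou J values in \[0, 1\].
#' @param bins named list of class bounds, each `c(lower, upper)` with
#'   lower-exclusive / upper-inclusive reading except Low, which includes 0.
#' @return Character vector of labels (`"Low"`, `"Medium"`, `"High"`) with
#'   `NA` for unclassifiable values.
#' @export
#' @examples
#' classify_evenness(c(0.2, 0.5, 1, 0.35))
classify_evenness <- function(j, bins = evenness_bins()) {
  stopifnot(is.numeric(j))
  if (any(j < 0 | j > 1, na.rm = TRUE))
    stop("Pielou J must lie in [0, 1]")
  out <- rep(NA_character_, length(j))
  out[j >= bins$Low[1] & j <= bins$Low[2]] <- "Low"
  out[j > bins$Medium[1] & j <= bins$Medium[2]] <- "Medium"
  out[j > bins$High[1] & j <= bins$High[2]] <- "High"
  out
}

#' Default evenness-stratum bounds
#' @return Named list of `c(lower, upper)` bounds for Low, Medium, High.
#' @export
evenness_bins <- function() {
  list(Low = c(0, 0.3), Medium = c(0.4, 0.6), High = c(0.6, 1))
}

#' Generate an in-silico pool of fixed-richness compositions
#'
#' Each candidate composition is drawn from a symmetric Dirichlet whose
#' concentration parameter is itself sampled log-uniformly in
#' `alpha_range`, spanning near-degenerate (dominated) to near-uniform
#' communities and thus all three evenness strata. Fractions below
#' `min_fraction` are clipped up and the vector renormalized, so designed
#' richness is exactly the number of species in every candidate.
#'
#' @param pool_size number of candidate compositions (>= 1).
#' @param species species table as from [default_species_set()].
#' @param seed integer RNG seed.
#' @param alpha_range range for the log-uniform Dirichlet concentration,
#'   default `c(1e-2, 1e2)`.
#' @param min_fraction strict-positivity floor, default 1e-6.
#' @return A list of class `design_pool` with elements `compositions`
#'   (pool_size x S matrix, rows sum to 1), `evenness` (Pielou J per row),
#'   `pool_size`, `rng_seed`, `species`.
#' @export
#' @examples
#' pool <- generate_pool(1000, seed = 1)
#' range(pool$evenness)
generate_pool <- function(pool_size, species = default_species_set(),
                          seed = 1L, alpha_range = c(1e-2, 1e2),
                          min_fraction = 1e-6) {
  if (!is.numeric(pool_size) || length(pool_size) != 1 || pool_size < 1)
    stop("pool_size must be a single integer >= 1")
  pool_size <- as.integer(round(pool_size))
  validate_species_set(species)
  s <- nrow(species)
  comp <- with_seed(seed, {
    alpha <- exp(stats::runif(pool_size, log(alpha_range[1]),
                              log(alpha_range[2])))
    # symmetric Dirichlet rows via gamma draws with per-row shape
    g <- matrix(stats::rgamma(pool_size * s, shape = rep(alpha, times = s)),
                nrow = pool_size, ncol = s)
    g / rowSums(g)
  })
  comp[comp < min_fraction] <- min_fraction
  comp <- comp / rowSums(comp)
  colnames(comp) <- species$species_id
  j <- pielou_rows(comp)
  structure(list(compositions = comp, evenness = j,
                 pool_size = pool_size, rng_seed = seed, species = species),
            class = "design_pool")
}

# vectorized Pielou over matrix rows (all entries strictly positive)
#' @keywords internal
pielou_rows <- function(comp) {
  h <- -rowSums(ifelse(comp > 0, comp * log(comp), 0))
  srow <- rowSums(comp > 0)
  h / log(srow)
}

#' Sample the stratified community panel from a design pool
#'
#' Draws the requested number of communities uniformly without replacement
#' within each evenness stratum. The default strata mirror the stock panel:
#' 40 Low, 20 Medium, 40 High (100 communities total). Candidates falling
#' in the unassigned evenness gap are never sampled.
#'
#' @param pool a `design_pool` from [generate_pool()].
#' @param strata named integer vector of per-class sizes, default
#'   `c(Low = 40, Medium = 20, High = 40)`.
#' @param seed integer RNG seed for the within-class draw.
#' @return A list of class `panel_design` with `entries` (data.frame:
#'   community_id, evenness_class, pielou, replicate-free design rows),
#'   `compositions` (matrix aligned to entries), `strata_counts`.
#' @export
sample_panel <- function(pool, strata = c(Low = 40, Medium = 20, High = 40),
                         seed = 1L) {
  stopifnot(inherits(pool, "design_pool"))
  if (is.null(names(strata)) || !all(names(strata) %in% c("Low", "Medium",
                                                          "High")))
    stop("strata must be named with Low/Medium/High")
  cls <- classify_evenness(pool$evenness)
  picked <- integer(0)
  labels <- character(0)
  for (cl in c("Low", "Medium", "High")) {
    k <- if (cl %in% names(strata)) as.integer(strata[[cl]]) else 0L
    if (k == 0L) next
    cand <- which(!is.na(cls) & cls == cl)
    if (length(cand) < k)
      stop(sprintf(
        "insufficient candidates in class %s: need %d, pool has %d",
        cl, k, length(cand)))
    sel <- with_seed(derive_seed(seed, "panel", cl),
                     sort(sample(cand, k, replace = FALSE)))
    picked <- c(picked, sel)
    labels <- c(labels, rep(cl, k))
  }
  ids <- sprintf("SC%03d", seq_along(picked))
  entries <- data.frame(
    community_id = ids,
    evenness_class = labels,
    pielou = pool$evenness[picked],
    pool_index = picked,
    stringsAsFactors = FALSE
  )
  comp <- pool$compositions[picked, , drop = FALSE]
  rownames(comp) <- ids
  structure(list(entries = entries, compositions = comp,
                 strata_counts = table(factor(labels,
                   levels = c("Low", "Medium", "High"))),
                 rng_seed = seed),
            class = "panel_design")
}

#' Lay the panel out on 96-well microtiter plates
#'
#' Biological replicates of the same community occupy column-adjacent wells
#' (e.g. A1/A2), matching the adjacent-duplicate convention of deep-well
#' microcosm experiments. Wells are filled row-wise, plates A1..H12.
#'
#' @param panel a `panel_design`.
#' @param replicates replicate wells per community (default 2).
#' @return data.frame with columns plate, well, community_id, replicate.
#' @export
plate_layout <- function(panel, replicates = 2L) {
  stopifnot(inherits(panel, "panel_design"))
  replicates <- as.integer(replicates)
  if (replicates < 1) stop("replicates must be >= 1")
  ids <- panel$entries$community_id
  n_wells <- length(ids) * replicates
  idx <- seq_len(n_wells) - 1L
  plate <- idx %/% 96L + 1L
  within <- idx %% 96L
  row <- LETTERS[within %/% 12L + 1L]
  col <- within %% 12L + 1L
  data.frame(
    plate = plate,
    well = paste0(row, col),
    community_id = rep(ids, each = replicates),
    replicate = rep(seq_len(replicates), times = length(ids)),
    stringsAsFactors = FALSE
  )
}
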