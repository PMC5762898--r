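#' Default growth parameters for the serial-transfer simulator
#'
#' Species compete under generalized Lotka-Volterra dynamics for a shared
#' carrying capacity. Maximum growth rates are drawn once (seeded) from a
#' uniform range wide enough that every strain reaches stationary phase
#' well inside a 48 h cycle; the interaction matrix defaults to pure
#' resource competition (all entries 1).
#'
#' @param species species table ([default_species_set()]).
#' @param r named vector of max growth rates (h^-1); `NULL` draws them
#'   uniformly from `r_range` under `seed`.
#' @param r_range range for drawn growth rates, default `c(0.2, 0.8)` h^-1.
#' @param K community carrying capacity (cells/mL), default 1e9.
#' @param A S x S competition matrix (a_ii = 1), default all-ones.
#' @param seed seed for the growth-rate draw.
#' @return List of class `growth_params` with `r`, `K`, `A`.
#' @export
growth_params <- function(species = default_species_set(), r = NULL,
                          r_range = c(0.2, 0.8), K = 1e9, A = NULL,
                          seed = 1L) {
  validate_species_set(species)
  s <- nrow(species)
  if (is.null(r)) {
    r <- with_seed(derive_seed(seed, "growth_rates"),
                   stats::runif(s, r_range[1], r_range[2]))
    names(r) <- species$species_id
  }
  if (is.null(names(r)) && length(r) == s) names(r) <- species$species_id
  if (any(r <= 0)) stop("growth rates must be positive")
  if (K <= 0) stop("carrying capacity must be positive")
  if (is.null(A)) A <- matrix(1, s, s)
  if (any(A < 0)) stop("interaction matrix must be non-negative (competitive)")
  if (any(abs(diag(A) - 1) > 1e-12)) stop("interaction matrix needs a_ii = 1")
  structure(list(r = r, K = K, A = A), class = "growth_params")
}

#' Serial-transfer schedule
#'
#' @param n_transfers number of transfer cycles (default 5).
#' @param interval hours per cycle (default 48).
#' @param dilution_fraction fraction of the community carried into fresh
#'   medium at each transfer (default 0.05, i.e. 5 percent v/v).
#' @param culture_volume culture volume in mL (default 2).
#' @return List of class `transfer_schedule`.
#' @export
transfer_schedule <- function(n_transfers = 5L, interval = 48,
                              dilution_fraction = 0.05, culture_volume = 2) {
  if (dilution_fraction <= 0 || dilution_fraction >= 1)
    stop("dilution_fraction must lie in (0, 1)")
  if (n_transfers < 1 || interval <= 0 || culture_volume <= 0)
    stop("invalid schedule")
  structure(list(n_transfers = as.integer(n_transfers), interval = interval,
                 dilution_fraction = dilution_fraction,
                 culture_volume = culture_volume),
            class = "transfer_schedule")
}

# one RK4 integration of the gLV system over `hours` with fixed step
#' @keywords internal
glv_integrate <- function(n0, params, hours, step = 0.1) {
  r <- unname(params$r); K <- params$K; A <- params$A
  deriv <- function(n) r * n * (1 - as.vector(A %*% n) / K)
  n <- n0
  n_steps <- ceiling(hours / step)
  h <- hours / n_steps
  for (i in seq_len(n_steps)) {
    k1 <- deriv(n)
    k2 <- deriv(pmax(n + h / 2 * k1, 0))
    k3 <- deriv(pmax(n + h / 2 * k2, 0))
    k4 <- deriv(pmax(n + h * k3, 0))
    n <- pmax(n + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
    if (any(!is.finite(n)))
      stop("non-finite state during gLV integration")
  }
  n
}

#' Simulate serial-transfer community dynamics
#'
#' Integrates generalized Lotka-Volterra growth
#' dN_i/dt = r_i N_i (1 - sum_j a_ij N_j / K) over each cycle with a
#' fixed-step RK4 scheme, then transfers `dilution_fraction` of the grown
#' community into fresh medium. Optional demographic noise applies a
#' multiplicative Gaussian perturbation (coefficient of variation
#' `noise_cv`) to post-dilution densities, emulating pipetting
#' variability between replicates.
#'
#' @param initial composition vector (fractions summing to 1) named by
#'   species id.
#' @param params [growth_params()].
#' @param schedule [transfer_schedule()].
#' @param initial_density total inoculum density (cells/mL); default
#'   `dilution_fraction * K`, i.e. a transfer from a stationary culture.
#' @param noise_cv CV of the multiplicative transfer noise (0 = none).
#' @param seed RNG seed (used only when `noise_cv > 0`).
#' @param step RK4 step in hours (default 0.1).
#' @return List of class `trajectory_record`: `densities` (n_transfers x S
#'   end-of-cycle densities), `composition` (row-normalized), `total`
#'   (cells/mL), `time_h` (cycle-end timestamps).
#' @export
simulate_transfers <- function(initial, params, schedule = transfer_schedule(),
                               initial_density = NULL, noise_cv = 0,
                               seed = 1L, step = 0.1) {
  validate_composition(initial)
  s <- length(initial)
  if (is.null(initial_density))
    initial_density <- schedule$dilution_fraction * params$K
  n <- initial * initial_density
  nt <- schedule$n_transfers
  dens <- matrix(NA_real_, nt, s,
                 dimnames = list(NULL, names(initial)))
  with_seed(if (noise_cv > 0) seed else NULL, {
    for (t in seq_len(nt)) {
      n <- tryCatch(glv_integrate(n, params, schedule$interval, step),
                    error = function(e)
                      stop(sprintf("cycle %d: %s", t, conditionMessage(e))))
      dens[t, ] <- n
      n <- n * schedule$dilution_fraction
      if (noise_cv > 0)
        n <- n * pmax(1 + stats::rnorm(s, 0, noise_cv), 0)
    }
  })
  total <- rowSums(dens)
  structure(list(densities = dens, composition = dens / total,
                 total = total,
                 time_h = seq_len(nt) * schedule$interval),
            class = "trajectory_record")
}

#' Default per-species cytometry channel signatures
#'
#' Fixed per-species mean vectors on a log10 intensity scale with diagonal
#' standard deviations, plus a debris cluster centred below the FL1 gate.
#' Separated signatures make gating meaningful and let fingerprint
#' diversity track true community structure.
#'
#' @param species species table.
#' @return List with `means` (S x 4 log10 means, channels FL1-H, FL3-H,
#'   FSC-H, SSC-H), `sds` (S x 4), `debris_mean`, `debris_sd`.
#' @export
channel_signatures <- function(species = default_species_set()) {
  s <- nrow(species)
  ch <- c("FL1-H", "FL3-H", "FSC-H", "SSC-H")
  # spread species over the dynamic range; debris sits an order of
  # magnitude below the dimmest cell cluster in FL1
  base <- seq(2.2, 4.2, length.out = s)
  means <- cbind(
    `FL1-H` = base,
    `FL3-H` = 2.0 + 1.8 * ((seq_len(s) * 3) %% s) / (s - 1),
    `FSC-H` = 2.5 + 1.5 * ((seq_len(s) * 7) %% s) / (s - 1),
    `SSC-H` = 2.3 + 1.6 * rev(seq_len(s) - 1) / (s - 1)
  )
  rownames(means) <- species$species_id
  sds <- matrix(0.12, s, 4, dimnames = list(species$species_id, ch))
  list(means = means, sds = sds,
       debris_mean = c(`FL1-H` = 1.0, `FL3-H` = 1.2, `FSC-H` = 1.8,
                       `SSC-H` = 1.6),
       debris_sd = c(`FL1-H` = 0.25, `FL3-H` = 0.3, `FSC-H` = 0.35,
                     `SSC-H` = 0.35))
}

#' Generate a synthetic flow-cytometry event table
#'
#' Community event count is Poisson with expectation
#' `total_density * acquired volume / dilution`; each event's species is
#' multinomial in the composition, and channel intensities are log-normal
#' around the species' signature. Debris events from a low-FL1 noise
#' cluster are added so that they make up `noise_fraction` of all events
#' in expectation. True species labels are retained (synthetic data only).
#'
#' @param composition fractions summing to 1, named by species id.
#' @param total_density cells/mL in the measured culture.
#' @param acquired_volume acquired volume in microlitres (default 50).
#' @param dilution pre-measurement dilution factor (default 1000).
#' @param noise_fraction debris fraction of all events, in \[0, 1).
#' @param signatures [channel_signatures()] list.
#' @param seed RNG seed.
#' @return data.frame with columns `FL1-H`, `FL3-H`, `FSC-H`, `SSC-H`
#'   (intensities >= 0) and `label` (species id or `"debris"`); attributes
#'   `dilution`, `acquired_volume`.
#' @export
generate_fcm_events <- function(composition, total_density,
                                acquired_volume = 50, dilution = 1000,
                                noise_fraction = 0.05,
                                signatures = channel_signatures(),
                                seed = 1L) {
  validate_composition(composition)
  stopifnot(total_density > 0, acquired_volume > 0, dilution > 0,
            noise_fraction >= 0, noise_fraction < 1)
  expected <- total_density * (acquired_volume / 1000) / dilution
  ch <- c("FL1-H", "FL3-H", "FSC-H", "SSC-H")
  with_seed(seed, {
    n_comm <- stats::rpois(1, expected)
    n_debris <- if (noise_fraction > 0)
      stats::rpois(1, expected * noise_fraction / (1 - noise_fraction))
    else 0L
    sp_ids <- rownames(signatures$means)
    counts <- as.vector(stats::rmultinom(1, n_comm,
                                         composition[sp_ids]))
    labels <- rep(sp_ids, counts)
    m <- matrix(NA_real_, length(labels), 4, dimnames = list(NULL, ch))
    for (k in seq_along(sp_ids)) {
      if (counts[k] == 0) next
      idx <- which(labels == sp_ids[k])
      for (j in 1:4)
        m[idx, j] <- 10^stats::rnorm(counts[k], signatures$means[k, j],
                                     signatures$sds[k, j])
    }
    if (n_debris > 0) {
      d <- sapply(1:4, function(j)
        10^stats::rnorm(n_debris, signatures$debris_mean[j],
                        signatures$debris_sd[j]))
      d <- matrix(d, ncol = 4, dimnames = list(NULL, ch))
      m <- rbind(m, d)
      labels <- c(labels, rep("debris", n_debris))
    }
    out <- as.data.frame(m, check.names = FALSE)
    out$label <- labels
    attr(out, "dilution") <- dilution
    attr(out, "acquired_volume") <- acquired_volume
    out
  })
}

#' Generate one amplicon-style count column
#'
#' Reads are multinomial in the bias-distorted composition
#' q_i = p_i * bias_i / sum_j p_j * bias_j, emulating the multiplicative
#' detection biases (extraction, PCR) that distort amplicon relative
#' abundances away from the true community.
#'
#' @param composition fractions summing to 1, named by species id.
#' @param bias named multiplicative detection factors (> 0); default all 1.
#' @param depth sequencing depth (reads, >= 1).
#' @param seed RNG seed.
#' @return Named integer vector of counts summing to `depth`.
#' @export
generate_amplicon_counts <- function(composition, bias = NULL, depth = 1e4,
                                     seed = 1L) {
  validate_composition(composition)
  if (depth < 1) stop("depth must be >= 1")
  if (is.null(bias)) bias <- stats::setNames(rep(1, length(composition)),
                                             names(composition))
  if (any(bias <= 0)) stop("bias factors must be positive")
  q <- composition * bias[names(composition)]
  if (sum(q) <= 0) stop("all-zero effective abundance")
  q <- q / sum(q)
  cnt <- with_seed(seed, as.vector(stats::rmultinom(1, as.integer(depth), q)))
  stats::setNames(as.integer(cnt), names(composition))
}
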