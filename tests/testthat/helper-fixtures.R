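# shared in-code fixtures; everything is generated, nothing stored

species_ids <- function() default_species_set()$species_id

# a named composition from a Dirichlet draw
random_composition <- function(seed, alpha = 1) {
  p <- with_seed(seed, {
    g <- stats::rgamma(10, alpha)
    g / sum(g)
  })
  stats::setNames(p, species_ids())
}

# uniform random transformed events over [0,1]^4
uniform_events <- function(n, seed) {
  ev <- with_seed(seed, as.data.frame(matrix(stats::runif(n * 4), ncol = 4)))
  names(ev) <- c("FL1-H", "FL3-H", "FSC-H", "SSC-H")
  ev
}

# one shared end-to-end run at the study's panel size (desk-scale
# fingerprint settings), computed lazily and reused across tests
acceptance_cache <- new.env(parent = emptyenv())
acceptance_pipeline <- function() {
  if (is.null(acceptance_cache$res)) {
    cfg <- run_config(seed = 777, pool_size = 2e4,
                      technical_replicates = 1L, nbin = 32L,
                      n_cells = 1000L, min_cells = 1000L, n_perm = 199L)
    acceptance_cache$res <- run_pipeline(cfg)
  }
  acceptance_cache$res
}

# a small count table with named dims
toy_counts <- function(seed = 1, n_taxa = 8, n_samples = 5, lambda = 40) {
  m <- with_seed(seed,
    matrix(stats::rpois(n_taxa * n_samples, lambda), n_taxa, n_samples))
  dimnames(m) <- list(paste0("otu", seq_len(n_taxa)),
                      paste0("s", seq_len(n_samples)))
  m
}
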