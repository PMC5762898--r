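#' Read / write a flow-cytometry event CSV
#'
#' The canonical interchange format: header columns exactly
#' `FL1-H,FL3-H,FSC-H,SSC-H`, optionally followed by `label`.
#'
#' @param path file path.
#' @param events event data.frame (write).
#' @return `read_event_csv`: the event data.frame.
#' @export
read_event_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  needed <- c("FL1-H", "FL3-H", "FSC-H", "SSC-H")
  missing_ch <- setdiff(needed, names(df))
  if (length(missing_ch))
    stop(sprintf("%s: malformed header, missing column(s) %s",
                 path, paste(missing_ch, collapse = ", ")))
  for (ch in needed) {
    if (!is.numeric(df[[ch]]))
      stop(sprintf("%s: column %s is not numeric", path, ch))
    if (any(df[[ch]] < 0))
      stop(sprintf("%s: negative intensity in column %s", path, ch))
  }
  df
}

#' @rdname read_event_csv
#' @export
write_event_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a phylotype count TSV
#'
#' First column is the phylotype id; remaining columns are sample ids with
#' non-negative integer counts.
#'
#' @param path file path.
#' @param counts phylotype x sample matrix (write).
#' @return `read_count_tsv`: integer matrix with dimnames.
#' @export
read_count_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop(path, ": count table needs id + sample columns")
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop(path, ": duplicate phylotype ids")
  if (anyDuplicated(names(df)[-1])) stop(path, ": duplicate sample ids")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop(path, ": non-numeric count entries")
  bad <- which(m != round(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("%s: invalid count at row %d, column %s",
                 path, bad[1, 1], colnames(m)[bad[1, 2]]))
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' @rdname read_count_tsv
#' @export
write_count_tsv <- function(counts, path) {
  counts <- validate_count_table(counts)
  df <- data.frame(phylotype_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read / write a sample metadata CSV
#'
#' Columns: sample_id, community_id, transfer, evenness_class, replicate.
#'
#' @param path file path.
#' @param meta metadata data.frame (write).
#' @return `read_metadata_csv`: the data.frame.
#' @export
read_metadata_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "community_id", "transfer")
  missing_col <- setdiff(needed, names(df))
  if (length(missing_col))
    stop(path, ": missing metadata column(s) ",
         paste(missing_col, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop(path, ": duplicate sample ids")
  df
}

#' @rdname read_metadata_csv
#' @export
write_metadata_csv <- function(meta, path) {
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample ids")
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Bundles every tunable of the end-to-end pipeline. The defaults encode
#' the stock study design: a 1e6-candidate pool, 40/20/40 strata,
#' 5 transfers of 48 h at 5 percent dilution, fingerprints at
#' nbin = 128 / bandwidth 0.01 / 5000 cells, rarefaction depth 3317,
#' 999 permutations. Every stochastic stage derives its own sub-seed from
#' the master seed.
#'
#' @param seed master seed (default 777).
#' @param ... overrides for any config entry.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(seed = 777L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    pool_size = 1e6,
    strata = c(Low = 40L, Medium = 20L, High = 40L),
    n_transfers = 5L, interval = 48, dilution_fraction = 0.05,
    noise_cv = 0.05,
    technical_replicates = 2L,
    fcm_dilution = 1000, acquired_volume = 50, noise_fraction = 0.05,
    nbin = 128L, bandwidth = 0.01, n_cells = 5000L, min_cells = 1000L,
    rarefy_depth = 3317L, depth_meanlog = log(1e4), depth_sdlog = 0.5,
    n_perm = 999L,
    output_dir = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = c("run_config", "list"))
}

#' Read / write a run configuration as YAML
#' @param path file path.
#' @param config a `run_config` (write).
#' @return `read_config`: a `run_config` round-tripping the written one.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$strata <- unlist(raw$strata)
  do.call(run_config, c(list(seed = raw$seed),
                        raw[setdiff(names(raw), "seed")]))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  out$strata <- as.list(out$strata)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the full evenness-panel pipeline
#'
#' Composes the workflow end to end: design the stratified panel from the
#' candidate pool, simulate serial transfers for every community,
#' generate flow-cytometry events at transfers 1..n and amplicon counts at
#' transfers 0 and n (one sample per community per amplicon transfer,
#' `technical_replicates` per FCM transfer), then compute fingerprint
#' diversity, taxonomic diversity and the headline statistics. Fully
#' deterministic given the master seed.
#'
#' @param config a [run_config()]. Desk-scale runs typically shrink
#'   `pool_size`, `strata` and `n_cells`.
#' @param amplicon_bias optional named detection-bias vector.
#' @return List with `panel`, `layout`, `trajectories`, `fcm_manifest`,
#'   `fcm_diversity`, `amplicon_counts` (matrix), `amplicon_meta`,
#'   `taxonomic_diversity`, `stats`, `summary` (plain list, JSON-ready).
#' @export
run_pipeline <- function(config = run_config(), amplicon_bias = NULL) {
  seed <- config$seed
  species <- default_species_set()
  pool <- generate_pool(config$pool_size, species,
                        seed = derive_seed(seed, "pool"))
  panel <- sample_panel(pool, strata = config$strata,
                        seed = derive_seed(seed, "panel"))
  layout <- plate_layout(panel, replicates = 2L)
  schedule <- transfer_schedule(config$n_transfers, config$interval,
                                config$dilution_fraction)
  params <- growth_params(species, seed = derive_seed(seed, "growth"))
  sigs <- channel_signatures(species)
  ids <- panel$entries$community_id
  nt <- schedule$n_transfers

  trajectories <- lapply(seq_along(ids), function(i)
    simulate_transfers(panel$compositions[i, ], params, schedule,
                       noise_cv = config$noise_cv,
                       seed = derive_seed(seed, "traj", ids[i])))
  names(trajectories) <- ids

  # FCM sampling at transfers 1..nt, technical replicates per sample
  fcm_rows <- list()
  fcm_div <- list()
  for (i in seq_along(ids)) {
    traj <- trajectories[[i]]
    for (t in seq_len(nt)) {
      for (rep_k in seq_len(config$technical_replicates)) {
        sid <- sprintf("%s_T%d_R%d", ids[i], t, rep_k)
        ev <- generate_fcm_events(
          traj$composition[t, ], traj$total[t],
          acquired_volume = config$acquired_volume,
          dilution = config$fcm_dilution,
          noise_fraction = config$noise_fraction, signatures = sigs,
          seed = derive_seed(seed, "fcm", sid))
        tr <- transform_events(ev)
        gt <- apply_gate(tr)
        qc_ok <- nrow(gt) >= config$min_cells && nrow(gt) >= config$n_cells
        dens <- total_cell_density(nrow(gt), config$acquired_volume,
                                   config$fcm_dilution)
        fcm_rows[[sid]] <- data.frame(
          sample_id = sid, community_id = ids[i], transfer = t,
          replicate = rep_k, modality = "fcm", n_gated = nrow(gt),
          qc_status = if (qc_ok) "kept" else "excluded:min_cells",
          density = dens, stringsAsFactors = FALSE)
        if (qc_ok) {
          fp <- compute_fingerprint(gt, nbin = config$nbin,
                                    bandwidth = config$bandwidth,
                                    n_cells = config$n_cells,
                                    seed = derive_seed(seed, "fp", sid))
          fcm_div[[sid]] <- data.frame(
            sample_id = sid, community_id = ids[i], transfer = t,
            replicate = rep_k,
            evenness_class = panel$entries$evenness_class[i],
            D0 = hill_diversity(fp$densities, 0),
            D1 = hill_diversity(fp$densities, 1),
            D2 = hill_diversity(fp$densities, 2),
            density = dens, stringsAsFactors = FALSE)
        }
      }
    }
  }
  fcm_manifest <- do.call(rbind, fcm_rows)
  fcm_diversity <- do.call(rbind, fcm_div)
  rownames(fcm_manifest) <- rownames(fcm_diversity) <- NULL

  # amplicon sampling at transfers 0 and nt: one sample per community each
  amp_meta <- list()
  amp_cols <- list()
  for (i in seq_along(ids)) {
    for (t in c(0L, nt)) {
      sid <- sprintf("%s_T%d", ids[i], t)
      comp <- if (t == 0) panel$compositions[i, ]
              else trajectories[[i]]$composition[nt, ]
      depth <- with_seed(derive_seed(seed, "depth", sid),
        max(1L, round(stats::rlnorm(1, config$depth_meanlog,
                                    config$depth_sdlog))))
      amp_cols[[sid]] <- generate_amplicon_counts(
        comp, bias = amplicon_bias, depth = depth,
        seed = derive_seed(seed, "amplicon", sid))
      amp_meta[[sid]] <- data.frame(
        sample_id = sid, community_id = ids[i], transfer = t,
        evenness_class = panel$entries$evenness_class[i],
        replicate = 1L, modality = "amplicon", depth = depth,
        stringsAsFactors = FALSE)
    }
  }
  amplicon_counts <- do.call(cbind, amp_cols)
  colnames(amplicon_counts) <- names(amp_cols)
  amplicon_meta <- do.call(rbind, amp_meta)
  rownames(amplicon_meta) <- NULL

  filtered <- filter_phylotypes(amplicon_counts)
  rare <- withCallingHandlers(
    rarefy_counts(filtered, depth = config$rarefy_depth,
                  seed = derive_seed(seed, "rarefy")),
    warning = function(w) invokeRestart("muffleWarning"))
  tax_div <- alpha_diversity(rare)
  tax_div <- merge(tax_div, amplicon_meta[, c("sample_id", "community_id",
                                              "transfer",
                                              "evenness_class")],
                   by = "sample_id", sort = TRUE)

  # headline statistics at the final transfer
  final_ids <- tax_div$sample_id[tax_div$transfer == nt]
  final_counts <- rare[, final_ids, drop = FALSE]
  final_cls <- tax_div$evenness_class[match(final_ids, tax_div$sample_id)]
  d_bc <- bray_curtis(final_counts)
  perm <- permanova(d_bc, final_cls, n_perm = config$n_perm,
                    seed = derive_seed(seed, "permanova"))
  ord <- pcoa_ordination(d_bc, k = 4)

  summary <- list(
    seed = seed,
    config = unclass(config)[setdiff(names(config), "output_dir")],
    strata_counts = as.list(panel$strata_counts),
    n_communities = length(ids),
    n_fcm_samples = nrow(fcm_manifest),
    n_fcm_kept = sum(fcm_manifest$qc_status == "kept"),
    n_amplicon_samples = nrow(amplicon_meta),
    n_rarefied_samples = ncol(rare),
    rarefied_depth = unname(unique(colSums(rare))),
    final_transfer_h = nt * schedule$interval,
    permanova = list(r_squared = perm$r_squared, p_value = perm$p_value,
                     n_permutations = perm$n_permutations),
    pcoa_proportion = ord$proportion
  )
  out <- list(panel = panel, layout = layout, trajectories = trajectories,
              fcm_manifest = fcm_manifest, fcm_diversity = fcm_diversity,
              amplicon_counts = amplicon_counts,
              amplicon_meta = amplicon_meta,
              taxonomic_diversity = tax_div,
              stats = list(permanova = perm, pcoa = ord),
              summary = summary)
  if (!is.null(config$output_dir)) write_pipeline_outputs(out, config)
  out
}

#' @keywords internal
write_pipeline_outputs <- function(result, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$output_dir, ...)
  panel_df <- cbind(result$panel$entries[c("community_id",
                                           "evenness_class", "pielou")],
                    result$panel$compositions)
  utils::write.csv(panel_df, p("panel.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(result$layout, p("manifest.csv"), row.names = FALSE,
                   quote = FALSE)
  write_count_tsv(result$amplicon_counts, p("amplicon_counts.tsv"))
  write_metadata_csv(result$amplicon_meta, p("amplicon_meta.csv"))
  utils::write.table(result$taxonomic_diversity, p("taxonomic_diversity.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(result$fcm_diversity))
    utils::write.table(result$fcm_diversity, p("fcm_diversity.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(result$summary, p("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$output_dir)
}
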